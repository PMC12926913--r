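# Shared fixtures: the packaged registry and its profiles, loaded once.
.fixture_env <- new.env()

shared_registry <- function() {
  if (is.null(.fixture_env$registry))
    .fixture_env$registry <- load_registry()
  .fixture_env$registry
}

shared_profiles <- function() {
  polcensus:::registry_profiles(shared_registry())
}

# minimal polymerase annotation stub for rule-level tests
stub_annotation <- function(protein_id, family, group, fragment = FALSE,
                            flags = list(), architecture = character(0)) {
  f <- utils::modifyList(list(
    polymerase_active = TRUE, php_active = FALSE, dnaq_active = FALSE,
    exo53_active = FALSE, clamp_motif = FALSE, recA_NT = FALSE,
    imuBC_domain = FALSE), flags)
  structure(list(protein_id = protein_id, genome_id = "stub",
                 family = family, group = group, fragment = fragment,
                 architecture = architecture, flags = f,
                 contig_id = "c1", gene_index = 1L),
            class = "polymerase_annotation")
}

# annotate a simulated genome and return complement + flat protein table
annotate_sim <- function(sim, options = list()) {
  cc <- annotate_genome(sim$proteins, sim$features, shared_registry(),
                        options = options)
  list(complement = cc, table = polcensus:::complement_protein_table(cc))
}
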