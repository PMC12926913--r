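# Synthetic proteomes with planted ground truth. Genes are sampled from the
# registry anchors: background point mutations are applied outside motif
# columns (so active-site status is exactly controlled), then motif toggles
# rewrite the motif columns (intact = canonical residues, broken = a
# disallowed residue at the first motif position). Decoys are
# composition-preserving shuffles of anchors.

#' Construct a planted-gene specification
#'
#' @param group registry group id.
#' @param motifs named character vector over the group's exact-set motifs,
#'   values `"intact"`/`"broken"`; unspecified motifs follow the group's
#'   expectation (required/typical = intact, absent = broken).
#' @param interaction named logical vector over `RecA_NT` / `CLAMP`.
#' @param fragment emit a <200-residue fragment.
#' @param operon optional integer block id; genes sharing a block are placed
#'   at adjacent gene indices.
#' @return a `gene_plan` list.
#' @export
gene_plan <- function(group, motifs = NULL, interaction = NULL,
                      fragment = FALSE, operon = NA_integer_) {
  structure(list(group = group, motifs = motifs, interaction = interaction,
                 fragment = fragment, operon = operon),
            class = "gene_plan")
}

# all planted-truth-relevant positions of a group anchor
group_protected_positions <- function(registry, group) {
  expected <- group_expected_motifs(registry, group)
  pos <- integer(0)
  for (mid in names(expected))
    pos <- c(pos, motif_positions(registry, group, mid))
  pos <- c(pos, motif_positions(registry, group, "CLAMP"),
           motif_positions(registry, group, "RecA_NT"))
  sort(unique(pos))
}

#' Simulate one planted gene
#'
#' Uses the current RNG state; callers control reproducibility with
#' `set.seed()` / [with_seed()].
#'
#' @param registry a `pol_registry`.
#' @param group registry group id.
#' @inheritParams gene_plan
#' @param mutation_rate per-residue substitution probability outside
#'   protected motif columns.
#' @return list with `sequence` and `truth` (group, family, motif statuses,
#'   interaction flags, fragment).
#' @export
simulate_gene <- function(registry, group, motifs = NULL, interaction = NULL,
                          fragment = FALSE, mutation_rate = 0) {
  grow <- registry$groups[registry$groups$group_id == group, , drop = FALSE]
  if (nrow(grow) == 0) stop("unknown group in plan: ", group)
  anchor <- group_anchor(registry, group)
  expected <- group_expected_motifs(registry, group)
  exact_ids <- names(expected)[vapply(names(expected), function(m)
    registry$motifs$mode[registry$motifs$motif_id == m] == "exact", TRUE)]
  if (length(motifs)) {
    bad <- setdiff(names(motifs), exact_ids)
    if (length(bad))
      stop("group ", group, " does not carry motif(s): ",
           paste(bad, collapse = ", "))
  }
  has_reca_seg <- length(motif_positions(registry, group, "RecA_NT")) > 0
  has_clamp <- length(motif_positions(registry, group, "CLAMP")) > 0
  iwant <- function(key) {
    if (is.null(interaction) || !(key %in% names(interaction))) return(NA)
    isTRUE(interaction[[key]])
  }
  if (isTRUE(iwant("RecA_NT")) && !has_reca_seg)
    stop("group ", group, " has no RecA-NT segment to plant")
  if (isTRUE(iwant("CLAMP")) && !has_clamp)
    stop("group ", group, " has no clamp site to plant")

  protect <- group_protected_positions(registry, group)
  chars <- strsplit(mutate_aa_seq(anchor, mutation_rate, protect), "")[[1]]

  motif_status <- stats::setNames(character(length(exact_ids)), exact_ids)
  for (mid in exact_ids) {
    want <- if (!is.null(motifs) && mid %in% names(motifs)) motifs[[mid]]
            else if (expected[[mid]] == "absent") "broken" else "intact"
    pos <- motif_positions(registry, group, mid)
    allowed <- parse_pattern(
      registry$motifs$pattern[registry$motifs$motif_id == mid])
    chars[pos] <- vapply(allowed, `[[`, "", 1)
    # broken = disallowed residue at a central motif position (N is not
    # allowed in any packaged exact motif; central so the local alignment
    # still covers the column and the call reads inactive, not undetermined)
    if (want != "intact") chars[pos[ceiling(length(pos) / 2)]] <- "N"
    motif_status[mid] <- if (want == "intact") "active" else "inactive"
  }
  inter_truth <- c(RecA_NT = NA, CLAMP = NA)
  if (has_reca_seg) {
    on <- if (!is.na(iwant("RecA_NT"))) iwant("RecA_NT") else TRUE
    if (!on) {
      pos <- motif_positions(registry, group, "RecA_NT")
      chars[pos] <- sample(chars[pos]) # scramble the segment
    }
    inter_truth["RecA_NT"] <- on
  } else inter_truth["RecA_NT"] <- FALSE
  if (has_clamp) {
    on <- if (!is.na(iwant("CLAMP"))) iwant("CLAMP") else TRUE
    pos <- motif_positions(registry, group, "CLAMP")
    if (!on) chars[pos[5]] <- "A" # QxxLF requires the final F
    inter_truth["CLAMP"] <- on
  } else inter_truth["CLAMP"] <- FALSE

  seq <- paste(chars, collapse = "")
  if (fragment) seq <- substr(seq, 1, 180)
  list(sequence = seq,
       truth = list(group = group, family = grow$family_id,
                    kind = grow$kind, motif_status = motif_status,
                    interaction = inter_truth, fragment = fragment))
}

#' Simulate a genome with planted polymerase genes
#'
#' @param plan list with `genome_id`, `genes` (list of [gene_plan()]s),
#'   `decoys` (count of shuffled-anchor decoy proteins), `mutation_rate`.
#' @param registry a `pol_registry`.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @return list with `proteins` (list of `protein_record`s), `features`
#'   (data.frame) and `truth` (per-protein planted truth plus the expected
#'   replication system).
#' @export
simulate_genome <- function(plan, registry, seed = 1L) {
  defaults <- list(genome_id = "sim", genes = list(), decoys = 2,
                   mutation_rate = 0)
  for (nm in names(defaults))
    if (is.null(plan[[nm]])) plan[[nm]] <- defaults[[nm]]
  with_seed(seed, {
    genes <- plan$genes
    ## order: operon blocks first (members adjacent), then loose genes
    blocks <- vapply(genes, function(g) as.integer(
      if (is.null(g$operon) || is.na(g$operon)) NA_integer_ else g$operon),
      0L)
    genes <- genes[order(ifelse(is.na(blocks), 1e6, blocks))]
    sims <- lapply(genes, function(g)
      simulate_gene(registry, g$group, g$motifs, g$interaction, g$fragment,
                    plan$mutation_rate))
    ## decoys: shuffles of random polymerase anchors
    pol_groups <- registry$groups$group_id[registry$groups$kind ==
                                             "polymerase"]
    decoys <- lapply(seq_len(plan$decoys), function(i)
      shuffle_aa_seq(group_anchor(registry, sample(pol_groups, 1))))
    seqs <- c(lapply(sims, `[[`, "sequence"), decoys)
    n <- length(seqs)
    ids <- sprintf("%s_p%02d", plan$genome_id, seq_len(n))
    proteins <- vector("list", n)
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      start <- (i - 1L) * 1500L + 1L
      end <- start + 3L * nchar(seqs[[i]]) + 2L
      proteins[[i]] <- structure(list(
        protein_id = ids[i], genome_id = plan$genome_id,
        sequence = seqs[[i]], contig_id = "c1", gene_index = i,
        strand = "+", start = start, end = end), class = "protein_record")
      feats[[i]] <- data.frame(protein_id = ids[i], contig = "c1",
                               gene_index = i, strand = "+",
                               start = start, end = end,
                               stringsAsFactors = FALSE)
    }
    truth_rows <- lapply(seq_along(sims), function(i) {
      tr <- sims[[i]]$truth
      data.frame(protein_id = ids[i], group = tr$group, family = tr$family,
                 kind = tr$kind,
                 motif_status = paste(paste0(names(tr$motif_status), ":",
                                             tr$motif_status),
                                      collapse = ","),
                 recA_NT = tr$interaction[["RecA_NT"]],
                 clamp = tr$interaction[["CLAMP"]],
                 fragment = tr$fragment, stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, c(truth_rows, list(
      data.frame(protein_id = character(0), group = character(0),
                 family = character(0), kind = character(0),
                 motif_status = character(0), recA_NT = logical(0),
                 clamp = logical(0), fragment = logical(0),
                 stringsAsFactors = FALSE))))
    planted <- vapply(genes, function(g) g$group, "")
    frag <- vapply(genes, function(g) isTRUE(g$fragment), TRUE)
    list(proteins = proteins, features = do.call(rbind, feats),
         truth = list(proteins = truth,
                      replication_system = expected_replication_system(
                        planted[!frag])))
  })
}

# expected replication system implied by the planted (non-fragment) groups
expected_replication_system <- function(groups) {
  has <- function(g) g %in% groups
  if (!has("DnaE1") && !has("DnaE3")) return(NA_character_)
  if (has("PolC") && has("DnaE3")) return("PolC+DnaE3")
  if (has("PolC") && has("DnaE1")) return("PolC+DnaE1")
  "DnaE1-only"
}

#' Genome plan carrying exactly one mutasome complex type
#'
#' Planted genes include a DnaE1 replicative background plus the components
#' of the requested complex type, colocalized in one operon block.
#' @param complex_id one of the registry's 11 complex type ids.
#' @return plan list for [simulate_genome()].
#' @export
complex_plan <- function(complex_id) {
  comp <- switch(complex_id,
    "PolY-RecA" = list(gene_plan("PolY-core", operon = 1),
                       gene_plan(".RecA", operon = 1)),
    "UmuC-UmuD2-RecA" = list(gene_plan("UmuC", operon = 1),
                             gene_plan(".UmuD", operon = 1),
                             gene_plan(".RecA")),
    "YqjW-YqjX-RecA" = list(gene_plan("YqjW", operon = 1),
                            gene_plan(".YqjX", operon = 1),
                            gene_plan(".RecA")),
    "ImuA-ImuB-DnaE2" = list(gene_plan("DnaE2A", operon = 1),
                             gene_plan(".ImuA", operon = 1),
                             gene_plan("ImuB1", operon = 1)),
    "DnaE2B-PolY-RecA" = list(gene_plan("DnaE2B", operon = 1),
                              gene_plan("PolY-core", operon = 1),
                              gene_plan(".RecA")),
    "DnaE2B-iPolY-RecA" = list(gene_plan("DnaE2B", operon = 1),
                               gene_plan("scDinB2-like", operon = 1),
                               gene_plan(".RecA")),
    "DnaE2B-PolY-ImuBC-RecA" = list(gene_plan("DnaE2B", operon = 1),
                                    gene_plan("PolY-core", operon = 1),
                                    gene_plan(".ImuBC-solo", operon = 1),
                                    gene_plan(".RecA")),
    "DnaE2B-ImuBC" = list(gene_plan("DnaE2B", operon = 1),
                          gene_plan(".ImuBC-solo", operon = 1)),
    "DnaE2X-iPolY-ImuBC-RecA" = list(gene_plan("DnaE2X", operon = 1),
                                     gene_plan("gbDinB2-like", operon = 1),
                                     gene_plan(".ImuBC-solo", operon = 1),
                                     gene_plan(".RecA")),
    "PolY-ImuBC" = list(gene_plan("PolY-core",
                                  interaction = c(RecA_NT = FALSE),
                                  operon = 1),
                        gene_plan(".ImuBC-solo", operon = 1)),
    "UmuC-SRAP" = list(gene_plan("UmuC", operon = 1),
                       gene_plan(".SRAP", operon = 1)),
    stop("unknown complex type: ", complex_id))
  list(genome_id = paste0("sim_", gsub("[^A-Za-z0-9]", "_", complex_id)),
       genes = c(list(gene_plan("DnaE1")), comp), decoys = 2,
       mutation_rate = 0)
}

#' Simulate a cohort of genomes with a configurable enrichment effect
#'
#' Each genome gets a replicative background (DnaE1 + PolA1), environment
#' metadata, and (with class-dependent probability) the focal feature gene
#' (a solo Y-family polymerase lacking the RecA-NT motif). The feature's
#' presence odds between the two environment classes follow the configured
#' odds ratio: `p1 = OR * odds0 / (1 + OR * odds0)` with baseline prevalence
#' `p0` in the reference class.
#'
#' @param config list: `n_genomes`, `seed`, `mutation_rate` (0),
#'   `odds_ratio` (1), `baseline_prev` (0.3), `class_split` (0.5),
#'   `variable` (`"oxygen"` or `"temperature"`), `decoys` (2),
#'   `sequences` (TRUE; FALSE skips sequence emission for fast
#'   metadata-level replicates).
#' @return list with `genomes` (per-genome simulations, when `sequences`),
#'   `metadata` (data.frame), `truth` (feature flags, env classes, planted
#'   plans, configured odds ratio).
#' @export
simulate_cohort <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_genomes = 20, seed = 1L, mutation_rate = 0, odds_ratio = 1,
    baseline_prev = 0.3, class_split = 0.5, variable = "oxygen",
    decoys = 2, sequences = TRUE, registry = NULL), config)
  if (cfg$baseline_prev <= 0 || cfg$baseline_prev >= 1)
    stop("baseline_prev must be in (0,1)")
  n <- cfg$n_genomes
  if (n == 0) {
    return(list(genomes = list(),
                metadata = data.frame(genome_id = character(0),
                                      phylum = character(0),
                                      size_bp = integer(0),
                                      gc_percent = numeric(0),
                                      oxygen_labels = character(0),
                                      growth_temp_c = numeric(0),
                                      gram = character(0),
                                      stringsAsFactors = FALSE),
                truth = list(feature = logical(0), env = character(0),
                             odds_ratio = cfg$odds_ratio)))
  }
  o0 <- cfg$baseline_prev / (1 - cfg$baseline_prev)
  p1 <- cfg$odds_ratio * o0 / (1 + cfg$odds_ratio * o0)
  n1 <- max(1, round(n * (1 - cfg$class_split)))
  if (round(p1 * n1) >= n1) {
    max_or <- ((n1 - 0.5) / 0.5) / o0
    stop(sprintf(
      "odds ratio %.3g infeasible for class size %d at baseline %.2f; maximal feasible OR ~ %.3g",
      cfg$odds_ratio, n1, cfg$baseline_prev, max_or))
  }
  with_seed(cfg$seed, {
    gids <- sprintf("g%03d", seq_len(n))
    env <- ifelse(stats::runif(n) < cfg$class_split, "class0", "class1")
    p <- ifelse(env == "class0", cfg$baseline_prev, p1)
    feature <- stats::runif(n) < p
    gseeds <- sample.int(.Machine$integer.max - 1L, n)
    phyla <- sample(c("Proteobacteria", "Firmicutes", "Actinobacteria",
                      "Bacteroidetes"), n, replace = TRUE)
    size_bp <- round(stats::rlnorm(n, log(4e6), 0.3))
    metadata <- data.frame(
      genome_id = gids, phylum = phyla, size_bp = size_bp,
      gc_percent = round(stats::runif(n, 30, 70), 1),
      oxygen_labels = if (cfg$variable == "oxygen")
        ifelse(env == "class0", "anaerobe", "aerobe")
      else sample(c("aerobe", "anaerobe"), n, replace = TRUE),
      growth_temp_c = if (cfg$variable == "temperature")
        ifelse(env == "class0", 30, 55)
      else stats::runif(n, 25, 40),
      gram = sample(c("positive", "negative"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    genomes <- list()
    if (cfg$sequences) {
      registry <- if (is.null(cfg$registry)) load_registry() else cfg$registry
      for (i in seq_len(n)) {
        genes <- list(gene_plan("DnaE1"), gene_plan("PolA1"))
        if (feature[i]) genes <- c(genes, list(gene_plan("DinP")))
        plan <- list(genome_id = gids[i], genes = genes,
                     decoys = cfg$decoys, mutation_rate = cfg$mutation_rate)
        genomes[[gids[i]]] <- simulate_genome(plan, registry,
                                              seed = gseeds[i])
      }
    }
    list(genomes = genomes, metadata = metadata,
         truth = list(feature = stats::setNames(feature, gids),
                      env = stats::setNames(env, gids),
                      odds_ratio = cfg$odds_ratio))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits per-genome FASTA and feature TSVs, `meta.tsv`, and truth tables
#' under `truth/`.
#' @param cohort result of [simulate_cohort()] (with sequences).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$metadata, file.path(dir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (gid in names(cohort$genomes)) {
    g <- cohort$genomes[[gid]]
    seqs <- Biostrings::AAStringSet(vapply(g$proteins, `[[`, "", "sequence"))
    names(seqs) <- vapply(g$proteins, `[[`, "", "protein_id")
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(gid, ".faa")))
    utils::write.table(g$features, file.path(dir, paste0(gid, ".features.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(g$truth$proteins,
                       file.path(dir, "truth", paste0(gid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ft <- data.frame(genome_id = names(cohort$truth$feature),
                   feature = unname(cohort$truth$feature),
                   env = unname(cohort$truth$env), stringsAsFactors = FALSE)
  utils::write.table(ft, file.path(dir, "truth", "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
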