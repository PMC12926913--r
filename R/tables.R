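# Flat tables for serialization of genome complements.

empty_protein_table <- function() {
  data.frame(genome_id = character(0), protein_id = character(0),
             family = character(0), group = character(0),
             fragment = logical(0), architecture = character(0),
             polymerase_active = logical(0), php_active = logical(0),
             dnaq_active = logical(0), exo53_active = logical(0),
             clamp_motif = logical(0), recA_NT = logical(0),
             imuBC_domain = logical(0), similarity = numeric(0),
             stringsAsFactors = FALSE)
}

complement_protein_table <- function(complement) {
  anns <- complement$polymerases
  if (!length(anns)) return(empty_protein_table())
  do.call(rbind, lapply(anns, function(a) {
    data.frame(genome_id = a$genome_id, protein_id = a$protein_id,
               family = a$family, group = a$group, fragment = a$fragment,
               architecture = paste(a$architecture, collapse = ","),
               polymerase_active = a$flags$polymerase_active,
               php_active = a$flags$php_active,
               dnaq_active = a$flags$dnaq_active,
               exo53_active = a$flags$exo53_active,
               clamp_motif = a$flags$clamp_motif,
               recA_NT = a$flags$recA_NT,
               imuBC_domain = a$flags$imuBC_domain,
               similarity = if (is.null(a$similarity)) NA_real_
                            else a$similarity,
               stringsAsFactors = FALSE)
  }))
}

empty_genome_table <- function() {
  data.frame(genome_id = character(0), n_polymerases = integer(0),
             n_A = integer(0), n_B = integer(0), n_C = integer(0),
             n_X = integer(0), n_Y = integer(0),
             replication_system = character(0),
             n_active_proofreaders = integer(0),
             exo53_status = character(0), n_complexes = integer(0),
             stringsAsFactors = FALSE)
}

complement_genome_row <- function(complement) {
  fam <- complement$counts$family
  n_of <- function(f) fam$n[fam$family == f]
  data.frame(genome_id = complement$genome_id,
             n_polymerases = complement$counts$total,
             n_A = n_of("A"), n_B = n_of("B"), n_C = n_of("C"),
             n_X = n_of("X"), n_Y = n_of("Y"),
             replication_system = complement$replication_system$system,
             n_active_proofreaders = sum(complement$proofreaders$active),
             exo53_status = complement$exo53_status,
             n_complexes = nrow(complement$complexes),
             stringsAsFactors = FALSE)
}

complement_complex_table <- function(complement) {
  complement$complexes
}
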