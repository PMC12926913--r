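# Per-genome integration: family/group assignment for every protein,
# motif-derived flags, replication-system typing, proofreader census,
# 5'-3' exonuclease complementation, and mutasome complex typing.

#' Annotate a genome's polymerase complement
#'
#' Runs the full pipeline for one genome: domain scanning, family assignment,
#' anchored group clustering, motif calling, replication-system typing,
#' proofreader census, 5'-3' exonuclease complementation and mutasome
#' complex typing.
#'
#' @param proteins list of `protein_record`s (see [read_proteome()]).
#' @param features optional feature data.frame from [read_features()]; when
#'   supplied it overrides the gene context carried by `proteins`.
#' @param registry a `pol_registry`.
#' @param options list: `tau` (domain-scan threshold, 0.3), `edge_threshold`
#'   (clustering, 0.45), `homology_threshold` (validated-DnaQ admission,
#'   0.5), `window` (colocalization, 5), `assume_recA` (FALSE),
#'   `require_colocalization` (FALSE), `x_as_undetermined` (FALSE),
#'   `external_hits` (data.frame in [scan_domains()] format, bypasses the
#'   scanner), `model_scores` (data.frame of structure-model scores).
#' @return a `genome_complement`: list with `genome_id`, `polymerases`
#'   (per-protein annotation list), `accessory` (accessory-protein table),
#'   `replication_system`, `proofreaders`, `exo53_status`, `complexes`,
#'   `counts`.
#' @export
annotate_genome <- function(proteins, features = NULL, registry,
                            options = list()) {
  opt <- utils::modifyList(list(
    tau = 0.3, edge_threshold = 0.45, homology_threshold = 0.5,
    window = 5, assume_recA = FALSE, require_colocalization = FALSE,
    x_as_undetermined = FALSE, external_hits = NULL, model_scores = NULL
  ), options)
  if (!length(proteins)) stop("no proteins supplied")
  genome_id <- proteins[[1]]$genome_id
  if (!is.null(features)) {
    for (i in seq_along(proteins)) {
      f <- features[features$protein_id == proteins[[i]]$protein_id, ,
                    drop = FALSE]
      if (nrow(f) == 1) {
        proteins[[i]]$contig_id <- f$contig
        proteins[[i]]$gene_index <- f$gene_index
        proteins[[i]]$strand <- f$strand
        proteins[[i]]$start <- f$start
        proteins[[i]]$end <- f$end
      }
    }
  }
  profiles <- registry_profiles(registry)
  dom_profiles <- profiles[registry$domains$domain_id]

  ## 1. domain scan + family assignment
  per <- list()
  for (p in proteins) {
    hits <- if (!is.null(opt$external_hits)) {
      h <- opt$external_hits
      h <- h[h$protein_id == p$protein_id, , drop = FALSE]
      attr(h, "mappings") <- rep(list(NULL), nrow(h))
      h
    } else scan_domains(p, dom_profiles, tau = opt$tau)
    fam <- assign_family(hits)
    per[[p$protein_id]] <- list(protein = p, hits = hits,
                                family = fam$family,
                                family_margin = fam$margin)
  }

  ## 2. group assignment per family by anchored clustering
  for (famid in c("A", "B", "C", "X", "Y")) {
    ids <- names(per)[vapply(per, function(x)
      identical(x$family, famid), TRUE)]
    if (!length(ids)) next
    seqs <- stats::setNames(
      vapply(ids, function(i) per[[i]]$protein$sequence, ""), ids)
    ga <- cluster_groups(seqs, registry, famid,
                         edge_threshold = opt$edge_threshold)
    for (j in seq_len(nrow(ga))) {
      pid <- ga$protein_id[j]
      per[[pid]]$group <- ga$group_id[j]
      per[[pid]]$similarity <- ga$similarity[j]
    }
  }
  ## DnaE1/DnaE3 disambiguation with auxiliary evidence on small margins
  for (pid in names(per)) {
    x <- per[[pid]]
    if (is.null(x$group) || !(x$group %in% c("DnaE1", "DnaE3"))) next
    am <- anchor_group_margin(x$protein$sequence, registry,
                              c("DnaE1", "DnaE3"))
    per[[pid]]$group_margin <- am$margin
    if (am$margin < 0.05) per[[pid]]$dnae_ambiguous <- TRUE
  }

  ## 3. non-polymerase proteins: solo-PHP (PolX-like) and accessory groups
  acc_rows <- list()
  for (pid in names(per)) {
    x <- per[[pid]]
    if (!is.na(x$family)) next
    if (nrow(x$hits) == 0) next
    cand_groups <- accessory_candidate_groups(registry, x$hits$domain_id)
    if (!length(cand_groups)) next
    sims <- vapply(cand_groups, function(g)
      max(similarity_to_refs(x$protein$sequence,
                             registry$alignments[[paste0("grp_", g)]])), 0)
    best <- names(which.max(sims))
    if (sims[best] < opt$edge_threshold) next
    if (best == "PolX-like") {
      per[[pid]]$family <- "X"
      per[[pid]]$group <- "PolX-like"
      per[[pid]]$similarity <- unname(sims[best])
    } else {
      per[[pid]]$accessory_group <- best
      acc_rows[[length(acc_rows) + 1]] <- data.frame(
        protein_id = pid, group_id = best,
        similarity = unname(sims[best]),
        contig = x$protein$contig_id,
        gene_index = x$protein$gene_index, stringsAsFactors = FALSE)
    }
  }
  accessory <- if (length(acc_rows)) do.call(rbind, acc_rows) else
    data.frame(protein_id = character(0), group_id = character(0),
               similarity = numeric(0), contig = character(0),
               gene_index = integer(0), stringsAsFactors = FALSE)

  ## 4. motif calls and flags for polymerase proteins
  annotations <- list()
  for (pid in names(per)) {
    x <- per[[pid]]
    if (is.na(x$family)) next
    ann <- annotate_polymerase(x, registry, profiles, opt)
    ## resolve flagged DnaE ambiguity with PHP/clamp signatures
    if (isTRUE(x$dnae_ambiguous)) {
      ann$group <- if (isTRUE(ann$flags$php_active)) "DnaE1" else "DnaE3"
      ann$group_note <- "DnaE1/DnaE3 margin < 0.05; typed by PHP signature"
    }
    annotations[[pid]] <- ann
  }

  ## 5. accessory motif calls needed downstream (standalone DnaQ / FEN)
  acc_calls <- accessory_motif_calls(per, accessory, registry, profiles, opt)

  ## 6. genome-level typing
  repl <- classify_replication_system(annotations)
  proof <- census_proofreaders(annotations, accessory, acc_calls, registry,
                               per, opt)
  exo53 <- check_exo53_complementation(annotations, accessory, acc_calls)
  complement <- structure(list(
    genome_id = genome_id,
    polymerases = annotations,
    accessory = accessory,
    accessory_calls = acc_calls,
    replication_system = repl,
    proofreaders = proof,
    exo53_status = exo53,
    complexes = NULL,
    counts = complement_counts(annotations)
  ), class = "genome_complement")
  complement$complexes <- type_complexes(complement, registry, options = opt)
  complement
}

# accessory/solo groups whose expected domains overlap the protein's hits
accessory_candidate_groups <- function(registry, hit_domains) {
  gs <- registry$groups
  cand <- character(0)
  for (i in seq_len(nrow(gs))) {
    if (gs$kind[i] != "accessory" && gs$group_id[i] != "PolX-like") next
    doms <- strsplit(gs$expected_domains[i], ",", fixed = TRUE)[[1]]
    if (length(intersect(doms, hit_domains))) cand <- c(cand, gs$group_id[i])
  }
  cand
}

# Full annotation of one polymerase protein.
annotate_polymerase <- function(x, registry, profiles, opt) {
  p <- x$protein
  hits <- x$hits
  maps <- attr(hits, "mappings")
  group <- if (!is.null(x$group)) x$group else "unassigned-novel"
  grow <- registry$groups[registry$groups$group_id == group, , drop = FALSE]

  mapping_for_domain <- function(domain_id) {
    k <- which(hits$domain_id == domain_id)
    if (!length(k) || is.null(maps[[k[1]]])) return(NULL)
    anchor_align(hits[k[1], , drop = FALSE], profiles[[domain_id]],
                 mapping = maps[[k[1]]])
  }

  calls <- list()
  expected <- if (nrow(grow)) group_expected_motifs(registry, group)
              else stats::setNames(character(0), character(0))
  for (mid in names(expected)) {
    mrow <- registry$motifs[registry$motifs$motif_id == mid, ]
    if (mrow$mode != "exact") next
    mp <- mapping_for_domain(mrow$domain_id)
    calls[[mid]] <- if (is.null(mp))
      motif_call_row(p$protein_id, mid, "undetermined")
    else call_active_site(p, mrow, mp, opt$x_as_undetermined)
  }
  ## catalytic-site call through the family core hit
  corehit <- family_core_domain[[x$family]]
  catid <- family_cat_motif[[x$family]]
  if (is.null(calls[[catid]]) && corehit %in% hits$domain_id) {
    mp <- mapping_for_domain(corehit)
    if (!is.null(mp))
      calls[[catid]] <- call_polymerase_activity(p, x$family, mp, registry,
                                                 opt$x_as_undetermined)
  }
  inter <- if (nrow(grow))
    detect_interaction_motifs(p, grow[1, ], registry, hits = hits)
  else motif_call_row(p$protein_id, "none", "undetermined")[0, ]

  status_of <- function(mid) {
    if (!is.null(calls[[mid]])) return(calls[[mid]]$status)
    k <- which(inter$motif_id == mid)
    if (length(k)) inter$status[k[1]] else "undetermined"
  }
  dnaq_motif <- intersect(c("DEDDh", "DEDDy"), names(expected))
  flags <- list(
    polymerase_active = identical(status_of(catid), "active"),
    php_active = identical(status_of("PHP_AS"), "active"),
    dnaq_active = length(dnaq_motif) > 0 &&
      identical(status_of(dnaq_motif[1]), "active"),
    exo53_active = identical(status_of("FEN_AS"), "active"),
    clamp_motif = identical(status_of("CLAMP"), "present"),
    recA_NT = identical(status_of("RecA_NT"), "present"),
    imuBC_domain = "ImuB-C" %in% hits$domain_id
  )
  arch <- hits[order(hits$q_start), , drop = FALSE]
  structure(list(
    protein_id = p$protein_id, genome_id = p$genome_id,
    family = x$family, group = group,
    fragment = any(hits$fragment[is_core_domain(hits$domain_id)]),
    architecture = arch$domain_id,
    hits = hits, motif_calls = c(calls, list(interaction = inter)),
    flags = flags, similarity = x$similarity,
    contig_id = p$contig_id, gene_index = p$gene_index
  ), class = "polymerase_annotation")
}

# Active-site calls for accessory standalone proteins (DnaQ DEDDh, FEN).
accessory_motif_calls <- function(per, accessory, registry, profiles, opt) {
  rows <- list()
  for (i in seq_len(nrow(accessory))) {
    pid <- accessory$protein_id[i]
    x <- per[[pid]]
    for (mid in c("DEDDh", "FEN_AS")) {
      mrow <- registry$motifs[registry$motifs$motif_id == mid, ]
      k <- which(x$hits$domain_id == mrow$domain_id)
      if (!length(k)) next
      maps <- attr(x$hits, "mappings")
      if (is.null(maps[[k[1]]])) next
      mp <- anchor_align(x$hits[k[1], , drop = FALSE],
                         profiles[[mrow$domain_id]], mapping = maps[[k[1]]])
      rows[[length(rows) + 1]] <- cbind(
        call_active_site(x$protein, mrow, mp, opt$x_as_undetermined),
        group_id = accessory$group_id[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), motif_id = character(0),
               status = character(0), matched = character(0),
               positions = character(0), evidence = numeric(0),
               group_id = character(0), stringsAsFactors = FALSE)
}

#' Classify the replication system of a genome
#'
#' Types the combination of replicative C-family alpha subunits: PolC with
#' DnaE3, PolC with DnaE1, or DnaE-only. DnaE2 never counts as replicative.
#' A complement without any DnaE-type subunit is an error (every bacterial
#' genome carries DnaE1 or DnaE3).
#'
#' @param annotations list of `polymerase_annotation`s (or a
#'   `genome_complement`).
#' @return list with `system` (one of `DnaE1-only`, `PolC+DnaE1`,
#'   `PolC+DnaE3`) and `evidence` (contributing protein ids).
#' @export
classify_replication_system <- function(annotations) {
  if (inherits(annotations, "genome_complement"))
    annotations <- annotations$polymerases
  anns <- Filter(function(a) a$family == "C" && !a$fragment, annotations)
  grp <- vapply(anns, function(a) a$group, "")
  ids <- vapply(anns, function(a) a$protein_id, "")
  has <- function(g) any(grp == g)
  ev <- function(gs) unname(ids[grp %in% gs])
  if (!has("DnaE1") && !has("DnaE3"))
    stop("no replicative C-family polymerase (DnaE1/DnaE3) in complement")
  if (has("PolC") && has("DnaE3"))
    return(list(system = "PolC+DnaE3", evidence = ev(c("PolC", "DnaE3"))))
  if (has("PolC") && has("DnaE1"))
    return(list(system = "PolC+DnaE1", evidence = ev(c("PolC", "DnaE1"))))
  list(system = "DnaE1-only", evidence = ev(c("DnaE1", "DnaE3")))
}

#' Census of candidate proofreading exonucleases
#'
#' Lists intrinsic PHP and DnaQ domains of the replicative C-family subunits
#' with their active-site status, and admits standalone DEDDh proteins as
#' DnaQ subunits only if they are close homologs of a validated reference
#' (normalized similarity at or above the homology threshold) or carry a
#' passing structure-model score; all other standalone candidates are
#' rejected (conservative rule).
#'
#' @param annotations polymerase annotations (or a `genome_complement`, in
#'   which case the remaining arguments are taken from it).
#' @param accessory accessory-protein table.
#' @param acc_calls accessory active-site calls.
#' @param registry a `pol_registry`.
#' @param per internal per-protein state (sequences for similarity).
#' @param opt options list (uses `homology_threshold`, `model_scores`).
#' @return data.frame: `carrier`, `kind` (`PHP` / `DnaQ-domain` /
#'   `DnaQ-subunit`), `active`.
#' @export
census_proofreaders <- function(annotations, accessory = NULL,
                                acc_calls = NULL, registry = NULL,
                                per = NULL, opt = list()) {
  if (inherits(annotations, "genome_complement")) {
    cc <- annotations
    accessory <- cc$accessory
    acc_calls <- cc$accessory_calls
    annotations <- cc$polymerases
  }
  opt <- utils::modifyList(list(homology_threshold = 0.5,
                                model_scores = NULL), opt)
  rows <- list()
  for (a in annotations) {
    if (a$family != "C" || a$fragment) next
    if (!(a$group %in% c("PolC", "DnaE1", "DnaE3"))) next
    if ("PHP" %in% a$architecture)
      rows[[length(rows) + 1]] <- data.frame(
        carrier = a$protein_id, kind = "PHP", active = a$flags$php_active,
        stringsAsFactors = FALSE)
    if ("DnaQ-exo" %in% a$architecture)
      rows[[length(rows) + 1]] <- data.frame(
        carrier = a$protein_id, kind = "DnaQ-domain",
        active = a$flags$dnaq_active, stringsAsFactors = FALSE)
  }
  ## standalone candidates
  if (!is.null(accessory) && nrow(accessory)) {
    stand <- accessory[accessory$group_id %in%
                         c(".DnaQ-solo", ".DnaQ-like"), , drop = FALSE]
    vrefs <- registry$alignments[["validated_DnaQ"]]
    for (i in seq_len(nrow(stand))) {
      pid <- stand$protein_id[i]
      seqv <- if (!is.null(per)) per[[pid]]$protein$sequence else NULL
      sim <- if (!is.null(seqv) && !is.null(vrefs))
        max(similarity_to_refs(seqv, vrefs)) else NA_real_
      admitted <- !is.na(sim) && sim >= opt$homology_threshold
      if (!admitted && !is.null(opt$model_scores)) {
        ms <- opt$model_scores
        ms <- ms[ms$protein_id == pid, , drop = FALSE]
        if (nrow(ms) &&
            any(vapply(seq_len(nrow(ms)), function(j)
              model_score_passes(ms[j, ]), TRUE)))
          admitted <- TRUE
      }
      if (!admitted) next
      act <- acc_calls$status[acc_calls$protein_id == pid &
                                acc_calls$motif_id == "DEDDh"]
      rows[[length(rows) + 1]] <- data.frame(
        carrier = pid, kind = "DnaQ-subunit",
        active = length(act) > 0 && act[1] == "active",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(carrier = character(0), kind = character(0),
               active = logical(0), stringsAsFactors = FALSE)
}

#' 5'-3' exonuclease complementation status
#'
#' `PolA1` when a Pol I ortholog carries an active FEN domain; otherwise
#' `solo` when a standalone FEN homolog with an intact active site exists;
#' otherwise `none` (the tiny-endosymbiont situation).
#'
#' @param annotations polymerase annotations (or a `genome_complement`).
#' @param accessory,acc_calls accessory table and calls when `annotations`
#'   is a plain list.
#' @return one of `"PolA1"`, `"solo"`, `"none"`.
#' @export
check_exo53_complementation <- function(annotations, accessory = NULL,
                                        acc_calls = NULL) {
  if (inherits(annotations, "genome_complement")) {
    cc <- annotations
    accessory <- cc$accessory
    acc_calls <- cc$accessory_calls
    annotations <- cc$polymerases
  }
  for (a in annotations) {
    if (a$group %in% c("PolA1") && !a$fragment && a$flags$exo53_active)
      return("PolA1")
  }
  if (!is.null(acc_calls) && nrow(acc_calls)) {
    solo <- acc_calls[acc_calls$group_id == ".FEN-solo" &
                        acc_calls$motif_id == "FEN_AS" &
                        acc_calls$status == "active", , drop = FALSE]
    if (nrow(solo)) return("solo")
  }
  "none"
}

complement_counts <- function(annotations) {
  anns <- Filter(function(a) !a$fragment, annotations)
  fam <- vapply(anns, function(a) a$family, "")
  grp <- vapply(anns, function(a) a$group, "")
  list(
    family = as.data.frame(table(family = factor(fam,
      levels = c("A", "B", "C", "X", "Y"))), responseName = "n"),
    group = if (length(grp)) as.data.frame(table(group = grp),
                                           responseName = "n")
            else data.frame(group = character(0), n = integer(0)),
    total = length(anns)
  )
}

#' @export
print.genome_complement <- function(x, ...) {
  cat("genome ", x$genome_id, ": ", x$counts$total,
      " polymerase(s); system ", x$replication_system$system,
      "; exo5'-3' ", x$exo53_status, "; ",
      nrow(x$complexes), " complex call(s)\n", sep = "")
  invisible(x)
}
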