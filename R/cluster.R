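# Group assignment by anchored similarity-graph clustering: pairwise global
# alignment similarities, thresholded into a graph, connected components
# labelled by the registry anchors they contain.

# Normalized global-alignment similarity matrix for a set of sequences:
# BLOSUM62, affine gaps, score normalized by the self-score of the shorter
# sequence of each pair.
similarity_matrix <- function(seqs, gap_open = 11, gap_ext = 1) {
  ints <- lapply(seqs, aa_to_int)
  ints <- lapply(ints, function(x) { x[x == 0L] <- 1L; x }) # X scored as Ala
  sub <- blosum62_20()
  raw <- cpp_pairwise_global(ints, sub, gap_open, gap_ext)
  self <- diag(raw)
  n <- length(seqs)
  denom <- outer(self, self, pmin)
  sim <- raw / denom
  dimnames(sim) <- list(names(seqs), names(seqs))
  sim
}

# Self-normalized similarity of one sequence to a set of references.
similarity_to_refs <- function(seq, refs, gap_open = 11, gap_ext = 1) {
  sims <- similarity_matrix(c(query = seq, refs), gap_open, gap_ext)
  sims[1, -1, drop = TRUE]
}

#' Assign proteins to groups by anchored similarity clustering
#'
#' Builds a similarity graph over the query proteins and the registry anchor
#' sequences of the given family (edges where normalized global-alignment
#' similarity is at least `edge_threshold`), takes connected components, and
#' labels: components containing anchors of exactly one group inherit that
#' group; components with anchors of several groups are resolved per protein
#' by the nearest anchor; components without anchors become
#' `"unassigned-novel"`.
#'
#' @param proteins list of `protein_record`s (or named character sequences),
#'   all previously assigned to `family_id`.
#' @param registry a `pol_registry`.
#' @param family_id the family whose groups are candidates.
#' @param edge_threshold similarity threshold for graph edges (default 0.45).
#' @return data.frame: `protein_id`, `family_id`, `group_id`,
#'   `best_anchor_id`, `similarity`, `component_id`.
#' @export
cluster_groups <- function(proteins, registry, family_id,
                           edge_threshold = 0.45) {
  if (is.list(proteins)) {
    fams <- unlist(lapply(proteins, function(p) p$family))
    if (length(fams) && !all(fams == family_id))
      stop("cluster_groups: proteins from mixed families supplied")
  }
  seqs <- protein_seq_vector(proteins)
  if (!length(seqs)) {
    return(data.frame(protein_id = character(0), family_id = character(0),
                      group_id = character(0), best_anchor_id = character(0),
                      similarity = numeric(0), component_id = integer(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- seqs[order(names(seqs))] # canonical order for tie-breaking
  groups <- family_groups(registry, family_id)
  anchors <- character(0)
  anchor_group <- character(0)
  for (g in groups) {
    aln <- registry$alignments[[paste0("grp_", g)]]
    anchors <- c(anchors, aln)
    anchor_group <- c(anchor_group, rep(g, length(aln)))
  }
  names(anchor_group) <- names(anchors)
  all_seqs <- c(seqs, anchors)
  sim <- similarity_matrix(all_seqs)
  adj <- sim >= edge_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  nq <- length(seqs)
  out <- vector("list", nq)
  for (i in seq_len(nq)) {
    pid <- names(seqs)[i]
    cid <- comp[i]
    members <- which(comp == cid)
    anchor_idx <- members[members > nq]
    if (!length(anchor_idx)) {
      out[[i]] <- data.frame(protein_id = pid, family_id = family_id,
                             group_id = "unassigned-novel",
                             best_anchor_id = NA_character_,
                             similarity = NA_real_, component_id = cid,
                             stringsAsFactors = FALSE)
      next
    }
    sims <- sim[i, anchor_idx]
    best <- anchor_idx[which.max(sims)]
    aid <- names(all_seqs)[best]
    out[[i]] <- data.frame(protein_id = pid, family_id = family_id,
                           group_id = unname(anchor_group[aid]),
                           best_anchor_id = aid,
                           similarity = max(sims), component_id = cid,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# margin (best minus second-best anchor-group similarity) for one protein,
# used for the DnaE1/DnaE3 tie rule
anchor_group_margin <- function(seq, registry, groups) {
  best <- vapply(groups, function(g) {
    aln <- registry$alignments[[paste0("grp_", g)]]
    max(similarity_to_refs(seq, aln))
  }, 0)
  ord <- order(-best)
  list(group = groups[ord[1]],
       margin = if (length(best) > 1) best[ord[1]] - best[ord[2]] else Inf)
}

protein_seq_vector <- function(proteins) {
  if (is.character(proteins)) return(proteins)
  seqs <- vapply(proteins, function(p) p$sequence, "")
  names(seqs) <- vapply(proteins, function(p) p$protein_id, "")
  seqs
}
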