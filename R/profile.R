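# Position-specific score profiles and the domain scanner. This is the
# package's lightweight substitute for iterative database searching: profiles
# are log-odds PSSMs built from the packaged reference alignments and scanned
# against query proteins by affine-gap local alignment.

#' Build a log-odds profile from a reference alignment
#'
#' Columns with more than 50% gaps are dropped as non-match columns. Sequences
#' are weighted by the Henikoff position-based scheme; per-column scores are
#' `log2((weighted frequency + pseudocount * background) / ((1 + pseudocount)
#' * background))` in bits against the Robinson-Robinson background.
#'
#' @param alignment named character vector of aligned sequences (gap `-`),
#'   all of equal length, at least two sequences.
#' @param domain_id identifier attached to hits from this profile.
#' @param pseudocount pseudocount mass (default 1).
#' @param background residue background frequencies.
#' @return a `pol_profile`: list with `domain_id`, `scores` (20 x L matrix),
#'   `consensus`, `self_score` (bits), `match_columns` (alignment columns kept).
#' @export
build_profile <- function(alignment, domain_id = "profile", pseudocount = 1,
                          background = AA_BACKGROUND) {
  if (length(alignment) < 2)
    stop("profile construction requires at least 2 aligned sequences")
  lens <- unique(nchar(alignment))
  if (length(lens) != 1)
    stop("aligned sequences have inconsistent lengths")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  gapfrac <- colMeans(mat == "-")
  keep <- which(gapfrac <= 0.5)
  if (!length(keep)) stop("no match columns in alignment")
  mat <- mat[, keep, drop = FALSE]

  ## Henikoff position-based sequence weights
  nseq <- nrow(mat)
  w <- numeric(nseq)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col %in% AA20]
    if (!length(res)) next
    tab <- table(res)
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col]))
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, nseq)
  w <- w / sum(w)

  scores <- matrix(0, nrow = 20, ncol = ncol(mat),
                   dimnames = list(AA20, NULL))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ok <- col %in% AA20
    f <- numeric(20)
    names(f) <- AA20
    if (any(ok)) {
      for (i in which(ok)) f[col[i]] <- f[col[i]] + w[i]
      f <- f / sum(f)
    }
    fr <- (f + pseudocount * background) / (1 + pseudocount)
    scores[, j] <- log2(fr / background)
  }
  consensus <- paste(AA20[apply(scores, 2, which.max)], collapse = "")
  cons_int <- aa_to_int(consensus)
  self_score <- sum(scores[cbind(cons_int, seq_len(ncol(scores)))])
  structure(list(domain_id = domain_id, scores = scores,
                 consensus = consensus, self_score = self_score,
                 match_columns = keep),
            class = "pol_profile")
}

#' @export
print.pol_profile <- function(x, ...) {
  cat("profile ", x$domain_id, ": ", ncol(x$scores), " columns, self score ",
      round(x$self_score, 1), " bits\n", sep = "")
  invisible(x)
}

# Build (and cache on the registry) profiles for all domain reference
# alignments plus the RecA-NT motif sub-alignment.
registry_profiles <- function(registry) {
  if (!is.null(registry$cache$profiles)) return(registry$cache$profiles)
  profs <- list()
  for (i in seq_len(nrow(registry$domains))) {
    id <- registry$domains$domain_id[i]
    aln <- registry$alignments[[registry$domains$reference_alignment[i]]]
    profs[[id]] <- build_profile(aln, domain_id = id)
  }
  pm <- registry$motifs[registry$motifs$mode == "profile", , drop = FALSE]
  for (i in seq_len(nrow(pm))) {
    id <- pm$motif_id[i]
    aln <- registry$alignments[[pm$profile_ref[i]]]
    profs[[id]] <- build_profile(aln, domain_id = id)
  }
  registry$cache$profiles <- profs
  profs
}

#' Scan a protein for domain hits
#'
#' Aligns each profile locally (affine gaps, open 11 / extend 1 bits) against
#' the protein. Hits with normalized score (`raw_score / self_score`) at or
#' above `tau` are retained; for each domain only the best-scoring hit is
#' kept. Polymerase-core hits on proteins shorter than 200 residues are
#' flagged `fragment = TRUE` (such proteins are excluded from downstream
#' polymerase censuses but the hit itself is recorded).
#'
#' @param protein either a `protein_record` (see [read_proteome()]) or a
#'   character amino-acid sequence.
#' @param profiles list of `pol_profile`s (e.g. from the registry).
#' @param tau normalized-score retention threshold (default 0.3).
#' @param gap_open,gap_ext affine gap penalties in bits.
#' @return data.frame of hits: `protein_id`, `domain_id`, `q_start`, `q_end`,
#'   `raw_score`, `norm_score`, `fragment`; the profile-column to query
#'   position mappings are attached as the `mappings` attribute (one integer
#'   vector per row, 0 where a column is deleted in the query).
#' @export
scan_domains <- function(protein, profiles, tau = 0.3, gap_open = 11,
                         gap_ext = 1) {
  pid <- if (is.list(protein)) protein$protein_id else "query"
  seq <- if (is.list(protein)) protein$sequence else protein
  if (!nzchar(seq)) stop("empty sequence for protein ", pid)
  qi <- aa_to_int(seq)
  plen <- nchar(seq)
  rows <- list()
  maps <- list()
  for (prof in profiles) {
    al <- cpp_pssm_local(prof$scores, qi, gap_open, gap_ext)
    if (al$score <= 0) next
    norm <- al$score / prof$self_score
    if (norm < tau) next
    hitlen <- al$q_end - al$q_start + 1
    frag <- plen < 200 && is_core_domain(prof$domain_id)
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = pid, domain_id = prof$domain_id,
      q_start = al$q_start, q_end = al$q_end,
      raw_score = al$score, norm_score = norm,
      fragment = frag, stringsAsFactors = FALSE)
    maps[[length(maps) + 1]] <- al$mapping
  }
  if (!length(rows)) {
    out <- data.frame(protein_id = character(0), domain_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      raw_score = numeric(0), norm_score = numeric(0),
                      fragment = logical(0), stringsAsFactors = FALSE)
    attr(out, "mappings") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$domain_id, -out$norm_score)
  out <- out[ord, , drop = FALSE]
  maps <- maps[ord]
  keep <- !duplicated(out$domain_id)
  out <- out[keep, , drop = FALSE]
  maps <- maps[keep]
  rownames(out) <- NULL
  attr(out, "mappings") <- maps
  out
}

is_core_domain <- function(domain_id) domain_id %in% family_core_domain

# family of a polymerase-core domain id, else NA
core_domain_family <- function(domain_id) {
  fams <- names(family_core_domain)
  hit <- fams[match(domain_id, family_core_domain)]
  hit
}

#' Assign a polymerase family from domain hits
#'
#' The family of the best non-fragment polymerase-core hit; `NA` if no core
#' domain qualifies (the protein may still be a solo PHP / accessory protein,
#' handled downstream). The margin between the best and second-best core hit
#' of a different family is recorded.
#'
#' @param hits data.frame from [scan_domains()].
#' @return list with `family` (single letter or `NA`), `margin`, `core_hit`
#'   (row of `hits` or `NULL`).
#' @export
assign_family <- function(hits) {
  core <- hits[is_core_domain(hits$domain_id) & !hits$fragment, , drop = FALSE]
  if (nrow(core) == 0)
    return(list(family = NA_character_, margin = NA_real_, core_hit = NULL))
  core <- core[order(-core$norm_score), , drop = FALSE]
  fam <- core_domain_family(core$domain_id[1])
  margin <- if (nrow(core) >= 2) core$norm_score[1] - core$norm_score[2]
            else NA_real_
  list(family = fam, margin = margin, core_hit = core[1, , drop = FALSE])
}
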