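# Motif calling: anchor proteins to reference alignments through their
# domain hits, then call active-site status (exact-set rules: any deviation,
# including deletions and by default X, means inactive) and interaction
# motifs (beta-clamp by pattern search in a group-specified region, RecA-NT
# by profile score).

#' Map reference-alignment columns to query positions
#'
#' Expands a domain hit's profile-column mapping to the full reference
#' alignment coordinate system (columns dropped as non-match columns map to
#' nothing, as do columns deleted in the query).
#'
#' @param domain_hit one-row hit data.frame from [scan_domains()] with its
#'   mapping (see `mapping` argument).
#' @param profile the `pol_profile` that produced the hit.
#' @param mapping integer vector of profile-column to query-position
#'   assignments; defaults to the mapping stored on the hit table.
#' @return integer vector over alignment columns; 0 = not aligned.
#' @export
anchor_align <- function(domain_hit, profile, mapping = NULL) {
  if (is.null(mapping)) {
    maps <- attr(domain_hit, "mappings")
    if (is.null(maps) || !length(maps))
      stop("no mapping available for domain hit")
    mapping <- maps[[1]]
  }
  aln_len <- max(profile$match_columns)
  out <- integer(aln_len)
  out[profile$match_columns] <- mapping
  out
}

motif_call_row <- function(protein_id, motif_id, status, matched = "",
                           positions = integer(0), evidence = NA_real_) {
  data.frame(protein_id = protein_id, motif_id = motif_id, status = status,
             matched = matched,
             positions = paste(positions, collapse = ","),
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Call an exact-set active-site motif
#'
#' Active iff every motif position carries an allowed residue; any deviation
#' (substitution, deletion, and by default X) makes the call inactive.
#' Undetermined iff the alignment does not cover all motif columns.
#'
#' @param protein a `protein_record` or sequence string.
#' @param motif_def one row of the registry motif table (exact mode).
#' @param mapping alignment-column to query-position vector from
#'   [anchor_align()].
#' @param x_as_undetermined treat X at a motif position as undetermined
#'   rather than a deviation.
#' @return one-row motif-call data.frame: `protein_id`, `motif_id`, `status`
#'   (`active`/`inactive`/`undetermined`), `matched`, `positions`, `evidence`.
#' @export
call_active_site <- function(protein, motif_def, mapping,
                             x_as_undetermined = FALSE) {
  pid <- if (is.list(protein)) protein$protein_id else "query"
  seq <- toupper(if (is.list(protein)) protein$sequence else protein)
  cols <- parse_int_list(motif_def$anchor_columns)
  allowed <- parse_pattern(motif_def$pattern)
  qpos <- mapping[cols]
  if (any(is.na(qpos)) || any(qpos == 0))
    return(motif_call_row(pid, motif_def$motif_id, "undetermined"))
  chars <- strsplit(seq, "")[[1]][qpos]
  matched <- paste(chars, collapse = "")
  if (x_as_undetermined && any(chars == "X"))
    return(motif_call_row(pid, motif_def$motif_id, "undetermined", matched,
                          qpos))
  ok <- mapply(function(ch, set) ch %in% set, chars, allowed)
  status <- if (all(ok)) "active" else "inactive"
  motif_call_row(pid, motif_def$motif_id, status, matched, qpos,
                 evidence = mean(ok))
}

#' Detect interaction motifs for a group-assigned protein
#'
#' Searches the beta-clamp binding motif (QxxLF) within the group-specified
#' region (`exo_loop`: inside the vestigial exonuclease domain hit;
#' `cterm_third`: the C-terminal third of the sequence) and calls the RecA-NT
#' motif by profile score against its packaged sub-alignment.
#'
#' @param protein a `protein_record` or sequence string.
#' @param group_row one row of the registry group table.
#' @param registry a `pol_registry`.
#' @param hits domain hits for the protein (needed for `exo_loop` regions).
#' @return motif-call data.frame (status `present`/`absent` per motif the
#'   group lists).
#' @export
detect_interaction_motifs <- function(protein, group_row, registry,
                                      hits = NULL) {
  pid <- if (is.list(protein)) protein$protein_id else "query"
  seq <- toupper(if (is.list(protein)) protein$sequence else protein)
  expected <- group_expected_motifs(registry, group_row$group_id)
  calls <- list()
  if ("CLAMP" %in% names(expected)) {
    region <- clamp_search_region(seq, group_row$clamp_region, hits)
    call <- search_clamp(pid, seq, region)
    calls[[length(calls) + 1]] <- call
  }
  if ("RecA_NT" %in% names(expected) || group_row$family_id == "Y") {
    calls[[length(calls) + 1]] <- call_reca_nt(pid, seq, registry)
  }
  if (!length(calls)) return(motif_call_row(pid, "none", "undetermined")[0, ])
  do.call(rbind, calls)
}

clamp_search_region <- function(seq, clamp_region, hits) {
  n <- nchar(seq)
  if (identical(clamp_region, "exo_loop") && !is.null(hits)) {
    h <- hits[hits$domain_id == "DnaQ-exo", , drop = FALSE]
    if (nrow(h)) return(c(h$q_start[1], h$q_end[1]))
  }
  if (identical(clamp_region, "cterm_third"))
    return(c(max(1L, n - floor(n / 3) + 1L), n))
  c(1L, n)
}

search_clamp <- function(pid, seq, region) {
  sub <- substr(seq, region[1], region[2])
  m <- regexpr("Q..LF", sub)
  if (m > 0) {
    start <- region[1] + as.integer(m) - 1L
    motif_call_row(pid, "CLAMP", "present",
                   substr(seq, start, start + 4L), start:(start + 4L),
                   evidence = 1)
  } else {
    motif_call_row(pid, "CLAMP", "absent")
  }
}

call_reca_nt <- function(pid, seq, registry) {
  mrow <- registry$motifs[registry$motifs$motif_id == "RecA_NT", ]
  prof <- registry_profiles(registry)[["RecA_NT"]]
  hit <- cpp_pssm_local(prof$scores, aa_to_int(seq), 11, 1)
  norm <- hit$score / prof$self_score
  if (norm >= mrow$threshold) {
    motif_call_row(pid, "RecA_NT", "present",
                   substr(seq, hit$q_start, hit$q_end),
                   c(hit$q_start, hit$q_end), evidence = norm)
  } else {
    motif_call_row(pid, "RecA_NT", "absent", evidence = norm)
  }
}

#' Call polymerase catalytic activity
#'
#' Checks the family's catalytic carboxylate columns (two palm aspartates
#' plus glutamate for Klenow-fold families, a carboxylate triad for
#' Polb-fold families). Inactive calls drive the iPolY designation in
#' Y-family.
#'
#' @param protein a `protein_record` or sequence string.
#' @param family_id polymerase family letter.
#' @param mapping alignment-column mapping of the family core-domain hit.
#' @param registry a `pol_registry`.
#' @inheritParams call_active_site
#' @return one-row motif-call data.frame for the `CAT_*` motif.
#' @export
call_polymerase_activity <- function(protein, family_id, mapping, registry,
                                     x_as_undetermined = FALSE) {
  mid <- family_cat_motif[[family_id]]
  mrow <- registry$motifs[registry$motifs$motif_id == mid, ]
  call_active_site(protein, mrow, mapping, x_as_undetermined)
}

#' Export per-group motif residue count matrices
#'
#' For each group, counts residues over the motif columns of all determined
#' calls (the tabular stand-in for motif logos).
#'
#' @param calls_by_group named list of motif-call data.frames (one per group,
#'   all for the same motif).
#' @return named list of 20 x L count matrices; groups with only
#'   undetermined calls yield an empty matrix with a warning.
#' @export
export_motif_counts <- function(calls_by_group) {
  out <- list()
  for (g in names(calls_by_group)) {
    calls <- calls_by_group[[g]]
    det <- calls[calls$status %in% c("active", "inactive", "present"), ,
                 drop = FALSE]
    if (nrow(det) == 0) {
      warning("group ", g, ": no determined calls; empty count matrix")
      out[[g]] <- matrix(0L, nrow = 20, ncol = 0, dimnames = list(AA20, NULL))
      next
    }
    L <- nchar(det$matched[1])
    cm <- matrix(0L, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
    for (s in det$matched) {
      chars <- strsplit(s, "")[[1]]
      for (j in seq_len(L)) {
        if (chars[j] %in% AA20) cm[chars[j], j] <- cm[chars[j], j] + 1L
      }
    }
    out[[g]] <- cm
  }
  out
}

#' Summarize motif prevalence within a group
#'
#' Group-level presence classes for interaction motifs: `most` when the
#' fraction of members carrying the motif is at least 0.9, `none` when at
#' most 0.1, `partial` otherwise.
#' @param calls motif-call data.frame for one group.
#' @return list with `fraction` and `class`.
#' @export
summarize_motif_prevalence <- function(calls) {
  det <- calls[calls$status %in% c("present", "absent"), , drop = FALSE]
  if (!nrow(det)) return(list(fraction = NA_real_, class = "undetermined"))
  f <- mean(det$status == "present")
  cls <- if (f >= 0.9) "most" else if (f <= 0.1) "none" else "partial"
  list(fraction = f, class = cls)
}
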