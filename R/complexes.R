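# Mutasome complex typing: match the registry decision table against the
# genome's component inventory in priority order, upgrade evidence by gene
# neighborhood, and optionally filter calls on structure-model scores.

#' Colocalization evidence for a set of genes
#'
#' `colocalized` iff all members lie on one contig with gene indices within
#' `window` of each other; otherwise `co-occurrence` (with a warning when any
#' member's gene context is unknown).
#'
#' @param member_features data.frame with columns `contig`, `gene_index`.
#' @param window maximum gene-index spread (default 5).
#' @return `"colocalized"` or `"co-occurrence"`.
#' @export
colocalize <- function(member_features, window = 5) {
  if (any(is.na(member_features$gene_index)) ||
      any(member_features$contig == "unknown")) {
    warning("unknown gene context; reporting co-occurrence")
    return("co-occurrence")
  }
  if (length(unique(member_features$contig)) > 1) return("co-occurrence")
  spread <- diff(range(member_features$gene_index))
  if (spread <= window) "colocalized" else "co-occurrence"
}

empty_complex_table <- function() {
  data.frame(genome_id = character(0), complex_id = character(0),
             members = character(0), evidence_level = character(0),
             variant = character(0), notes = character(0),
             stringsAsFactors = FALSE)
}

#' Type mutasome complexes in a genome
#'
#' Matches the registry's 11-type decision table against the genome's
#' DnaE2 polymerases, Y-family members (with their RecA-NT, ImuB-C and
#' catalytic-activity flags) and accessory partner proteins, in priority
#' order (most specific first; the PolY-RecA dimer is the fallback).
#' Every Y-family or DnaE2 protein serves in at most one call; accessory
#' partners are reusable. RecA presence is established from the proteome
#' scan unless `assume_recA` is set.
#'
#' @param complement a `genome_complement`.
#' @param registry a `pol_registry`.
#' @param recA_status optional override of RecA presence.
#' @param options list: `window`, `assume_recA`, `require_colocalization`,
#'   `model_scores`.
#' @return data.frame of complex calls: `genome_id`, `complex_id`, `members`
#'   (`role:protein_id` pairs), `evidence_level`, `variant`, `notes`.
#' @export
type_complexes <- function(complement, registry, recA_status = NULL,
                           options = list()) {
  opt <- utils::modifyList(list(window = 5, assume_recA = FALSE,
                                require_colocalization = FALSE,
                                model_scores = NULL), options)
  anns <- complement$polymerases
  acc <- complement$accessory
  genome_id <- complement$genome_id

  polys <- Filter(function(a) a$family == "Y" && !a$fragment, anns)
  dnae2 <- Filter(function(a) a$family == "C" && !a$fragment &&
                    grepl("^DnaE2", a$group), anns)
  acc_ids <- function(groups) sort(acc$protein_id[acc$group_id %in% groups])
  has_recA <- if (!is.null(recA_status)) isTRUE(recA_status)
              else isTRUE(opt$assume_recA) || length(acc_ids(".RecA")) > 0

  gene_ctx <- function(pids) {
    rows <- lapply(pids, function(pid) {
      a <- anns[[pid]]
      if (!is.null(a)) return(data.frame(contig = a$contig_id,
                                         gene_index = a$gene_index))
      k <- which(acc$protein_id == pid)
      if (length(k) && "contig" %in% names(acc))
        return(data.frame(contig = acc$contig[k[1]],
                          gene_index = acc$gene_index[k[1]]))
      data.frame(contig = "unknown", gene_index = NA_integer_)
    })
    do.call(rbind, rows)
  }

  used <- character(0)
  poly_matches <- function(comp) {
    cand <- Filter(function(a) {
      if (a$protein_id %in% used) return(FALSE)
      if (length(comp$groups) && !(a$group %in% comp$groups)) return(FALSE)
      f <- a$flags
      for (fl in comp$flags) {
        ok <- switch(fl,
          recA_NT = isTRUE(f$recA_NT),
          active = isTRUE(f$polymerase_active),
          inactive = !isTRUE(f$polymerase_active),
          imuBC = isTRUE(f$imuBC_domain),
          `-imuBC` = !isTRUE(f$imuBC_domain))
        if (!ok) return(FALSE)
      }
      TRUE
    }, polys)
    sort(vapply(cand, function(a) a$protein_id, ""))
  }
  dnae2_matches <- function(comp) {
    cand <- Filter(function(a)
      !(a$protein_id %in% used) &&
        (!length(comp$groups) || a$group %in% comp$groups), dnae2)
    sort(vapply(cand, function(a) a$protein_id, ""))
  }

  calls <- list()
  ct <- list_complex_types(registry)
  for (i in seq_len(nrow(ct))) {
    comps <- parse_complex_components(ct$required_components[i])
    repeat {
      members <- character(0)
      roles <- character(0)
      ok <- TRUE
      for (comp in comps) {
        pick <- switch(comp$role,
          poly = poly_matches(comp),
          dnae2 = dnae2_matches(comp),
          reca = if (has_recA) {
            ids <- acc_ids(".RecA")
            if (length(ids)) ids else "(assumed)"
          } else character(0),
          acc_ids(comp$groups))
        pick <- setdiff(pick, members) # one protein, one role per call
        if (!length(pick)) { ok <- FALSE; break }
        members <- c(members, pick[1])
        roles <- c(roles, comp$role)
      }
      if (!ok) break
      real <- members[members != "(assumed)"]
      ev <- suppressWarnings(colocalize(gene_ctx(real), opt$window))
      if (isTRUE(opt$require_colocalization) &&
          grepl("^DnaE2[BX]", ct$complex_id[i]) && ev != "colocalized") break
      variant <- complex_variant(ct[i, ], members, roles, anns, acc)
      call <- data.frame(genome_id = genome_id,
                         complex_id = ct$complex_id[i],
                         members = paste(paste0(roles, ":", members),
                                         collapse = ";"),
                         evidence_level = ev, variant = variant,
                         notes = "", stringsAsFactors = FALSE)
      if (!is.null(opt$model_scores)) {
        verdict <- apply_model_score_filter(opt$model_scores, call)
        if (!verdict$pass) {
          call$notes <- paste("rejected by model-score filter:",
                              verdict$reason)
          calls[[length(calls) + 1]] <- call
          used <- c(used, intersect(real, c(names(anns))))
          next
        }
      }
      calls[[length(calls) + 1]] <- call
      used <- c(used, intersect(real, names(anns)))
    }
  }
  out <- do.call(rbind, c(calls, list(empty_complex_table())))
  rownames(out) <- NULL
  out
}

# variant label: iPolY group for DnaE2B-iPolY-RecA, small-subunit class for
# the YqjW-type complex
complex_variant <- function(ct_row, members, roles, anns, acc) {
  if (ct_row$complex_id == "DnaE2B-iPolY-RecA") {
    pid <- members[roles == "poly"][1]
    return(anns[[pid]]$group)
  }
  if (ct_row$complex_id == "YqjW-YqjX-RecA") {
    pid <- members[roles == "small_subunit"][1]
    return(acc$group_id[acc$protein_id == pid][1])
  }
  ""
}

model_score_passes <- function(row) {
  ipTM <- as.numeric(row$ipTM)
  if (is.na(ipTM)) return(FALSE)
  thr <- if (identical(row$source, "v3")) 0.7 else 0.65
  if (ipTM < thr) return(FALSE)
  if (!is.null(row$global) && !is.na(suppressWarnings(as.numeric(row$global)))
      && as.numeric(row$global) <= 0.4) return(FALSE)
  if (!is.null(row$clash) && isTRUE(as.logical(row$clash))) return(FALSE)
  TRUE
}

#' Filter a complex call on structure-model confidence scores
#'
#' Pass iff ipTM is at least 0.65 (multimer-v2 source) or 0.7 (v3 source),
#' any complementary global score exceeds 0.4, and no clash is flagged.
#' Calls without a matching score row remain unfiltered (sequence evidence
#' only). Malformed score rows are skipped with a warning.
#'
#' @param model_scores data.frame with columns `genome_id`, `complex_id`,
#'   `source` (`multimer-v2`/`v3`), `pTM`, `ipTM`, `global`, `clash`.
#' @param call one-row complex-call data.frame.
#' @return list with `pass` (logical) and `reason`.
#' @export
apply_model_score_filter <- function(model_scores, call) {
  ms <- model_scores[model_scores$genome_id == call$genome_id &
                       model_scores$complex_id == call$complex_id, ,
                     drop = FALSE]
  if (nrow(ms) == 0)
    return(list(pass = TRUE, reason = "no scores supplied; unfiltered"))
  reasons <- character(0)
  for (j in seq_len(nrow(ms))) {
    row <- ms[j, ]
    ipTM <- suppressWarnings(as.numeric(row$ipTM))
    if (is.na(ipTM)) {
      warning("malformed model-score row skipped (ipTM not numeric)")
      next
    }
    thr <- if (identical(row$source, "v3")) 0.7 else 0.65
    if (ipTM < thr) {
      reasons <- c(reasons, sprintf("ipTM %.2f below %.2f (%s)", ipTM, thr,
                                    row$source))
      next
    }
    gl <- suppressWarnings(as.numeric(row$global))
    if (!is.na(gl) && gl <= 0.4) {
      reasons <- c(reasons, sprintf("global score %.2f not above 0.4", gl))
      next
    }
    if (isTRUE(as.logical(row$clash))) {
      reasons <- c(reasons, "clash flagged")
      next
    }
    return(list(pass = TRUE, reason = "model score passed"))
  }
  if (!length(reasons)) reasons <- "no interpretable score rows"
  list(pass = FALSE, reason = paste(reasons, collapse = "; "))
}
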