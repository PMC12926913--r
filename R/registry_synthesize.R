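# Deterministic construction of the packaged registry. Anchor sequences are
# synthetic: each domain gets a random consensus with the canonical motif
# residues planted at fixed columns; each group anchor concatenates its
# domains after group-specific divergence from the domain consensus, with
# motif columns protected so that active-site status is exactly controlled.

ELEMENT_LEN <- c(PAD60 = 60L, LINKER = 10L, CLAMP_LINKER = 10L, RECA_SEG = 20L)

parse_pattern <- function(pattern) {
  if (!nzchar(pattern)) return(list())
  lapply(strsplit(pattern, ",", fixed = TRUE)[[1]], function(p) {
    if (p == "x") AA20 else strsplit(p, "/", fixed = TRUE)[[1]]
  })
}

parse_int_list <- function(x) {
  if (!nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

# Exact motifs anchored in a given domain, as (motif_id, cols, allowed sets).
domain_exact_motifs <- function(motifs, domain_id) {
  m <- motifs[motifs$mode == "exact" & motifs$domain_id == domain_id, ,
              drop = FALSE]
  lapply(seq_len(nrow(m)), function(i) {
    list(motif_id = m$motif_id[i], cols = parse_int_list(m$anchor_columns[i]),
         allowed = parse_pattern(m$pattern[i]))
  })
}

#' Synthesize the default registry
#'
#' Builds the packaged knowledge base of polymerase families, groups, domains,
#' motifs and mutasome complex types, together with deterministic synthetic
#' anchor alignments. The packaged registry shipped under
#' `inst/extdata/registry` is the serialized output of this function; the
#' TSV tables are curated, the anchor sequences are synthetic stand-ins with
#' all motif columns planted at registry-defined positions.
#'
#' @param seed integer seed controlling the synthetic sequences.
#' @return a validated `pol_registry` object.
#' @export
synthesize_registry <- function(seed = 10271L) {
  families <- registry_family_defs()
  domains <- registry_domain_defs()
  motifs <- registry_motif_defs()
  gdefs <- registry_group_defs()
  ctypes <- registry_complex_defs()

  with_seed(seed, {
    ## domain consensus sequences with planted motif residues
    dom_cons <- list()
    for (i in seq_len(nrow(domains))) {
      id <- domains$domain_id[i]
      s <- strsplit(random_aa_seq(domains$len[i]), "")[[1]]
      for (dm in domain_exact_motifs(motifs, id)) {
        s[dm$cols] <- vapply(dm$allowed, `[[`, "", 1)
      }
      dom_cons[[id]] <- paste(s, collapse = "")
    }
    protected_cols <- lapply(domains$domain_id, function(id) {
      sort(unique(unlist(lapply(domain_exact_motifs(motifs, id),
                                `[[`, "cols"))))
    })
    names(protected_cols) <- domains$domain_id

    reca_nt <- random_aa_seq(ELEMENT_LEN[["RECA_SEG"]])
    # distant DEDDh subvariant: hits the DnaQ-exo profile but is far from the
    # validated proofreader references (drives the conservative DnaQ rule)
    dnaq_B <- mutate_aa_seq(dom_cons[["DnaQ-exo"]], 0.5,
                            protect = protected_cols[["DnaQ-exo"]])

    ## domain reference alignments (gap-free, equal length)
    alignments <- list()
    for (id in domains$domain_id) {
      cons <- dom_cons[[id]]
      prot <- protected_cols[[id]]
      mem <- c(consensus = cons,
               var1 = mutate_aa_seq(cons, 0.08, prot),
               var2 = mutate_aa_seq(cons, 0.08, prot))
      if (id == "DnaQ-exo") {
        # include the DEDDy flavor and the distant subvariant
        y <- strsplit(mutate_aa_seq(cons, 0.08, prot), "")[[1]]
        y[76] <- "Y"
        mem <- c(mem, deddy = paste(y, collapse = ""),
                 distant = dnaq_B,
                 distant_var = mutate_aa_seq(dnaq_B, 0.08, prot))
      }
      alignments[[paste0("dom_", id)]] <- mem
    }
    alignments[["motif_RecA-NT"]] <- c(
      consensus = reca_nt,
      var1 = mutate_aa_seq(reca_nt, 0.10),
      var2 = mutate_aa_seq(reca_nt, 0.10))

    ## group anchors
    layouts <- list()
    grows <- list()
    for (gd in gdefs) {
      gid <- gd$group_id
      parts <- character(0)
      lay <- list()
      pos <- 0L
      protect <- integer(0)
      for (k in seq_along(gd$elements)) {
        el <- gd$elements[k]
        if (el %in% names(ELEMENT_LEN)) {
          n <- ELEMENT_LEN[[el]]
          if (el == "RECA_SEG") {
            seq_el <- mutate_aa_seq(reca_nt, 0.05)
            protect <- c(protect, pos + seq_len(n))
          } else if (el == "CLAMP_LINKER") {
            s <- strsplit(random_aa_seq(n), "")[[1]]
            s[3:7] <- c("Q", "S", "S", "L", "F")
            seq_el <- paste(s, collapse = "")
            protect <- c(protect, pos + 3:7)
          } else seq_el <- random_aa_seq(n)
        } else {
          base <- dom_cons[[el]]
          if (gid == ".DnaQ-like") base <- dnaq_B
          seq_el <- mutate_aa_seq(base, gd$divergence, protected_cols[[el]])
          protect <- c(protect, pos + protected_cols[[el]])
          n <- nchar(base)
        }
        lay[[k]] <- data.frame(group_id = gid, element = el,
                               start = pos + 1L, end = pos + n,
                               stringsAsFactors = FALSE)
        parts <- c(parts, seq_el)
        pos <- pos + n
      }
      anchor <- paste(parts, collapse = "")
      laydf <- do.call(rbind, lay)

      ## apply expectation defaults: break motifs expected absent
      chars <- strsplit(anchor, "")[[1]]
      for (mid in names(gd$motifs)) {
        st <- gd$motifs[[mid]]
        if (st != "absent") next
        mrow <- motifs[motifs$motif_id == mid, ]
        if (mrow$mode != "exact") next
        dpos <- group_motif_positions_from_layout(laydf, motifs, mid)
        # break a central motif position (boundary columns may be clipped
        # by local alignment, which would read as undetermined, not broken)
        if (length(dpos)) chars[dpos[ceiling(length(dpos) / 2)]] <- "N"
      }
      ## PolA2-style clamp in the vestigial exonuclease loop (QSSLF at the
      ## positions mirroring the S. coelicolor exemplar, residues 120-124)
      if (identical(gd$clamp_region, "exo_loop")) {
        cpos <- group_clamp_positions_from_layout(laydf, "exo_loop")
        chars[cpos] <- c("Q", "S", "S", "L", "F")
        protect <- c(protect, cpos)
      }
      anchor <- paste(chars, collapse = "")
      anchor2 <- mutate_aa_seq(anchor, 0.05, protect = sort(unique(protect)))
      aln <- c(anchor, anchor2)
      names(aln) <- paste0(gid, "_anchor", 1:2)
      alignments[[paste0("grp_", gid)]] <- aln
      layouts[[gid]] <- laydf

      domels <- gd$elements[!(gd$elements %in% names(ELEMENT_LEN))]
      grows[[gid]] <- data.frame(
        group_id = gid, family_id = gd$family_id, kind = gd$kind,
        expected_domains = paste(domels, collapse = ","),
        expected_motifs = if (length(gd$motifs))
          paste(paste0(names(gd$motifs), ":", unlist(gd$motifs)),
                collapse = ",") else "",
        anchor_ref = paste0("grp_", gid),
        clamp_region = gd$clamp_region,
        divergence = gd$divergence,
        notes = gd$notes, stringsAsFactors = FALSE)
    }

    vd <- alignments[["grp_.DnaQ-solo"]][1]
    prot_dnaq <- protected_cols[["DnaQ-exo"]]
    alignments[["validated_DnaQ"]] <- c(
      vDnaQ1 = unname(vd),
      vDnaQ2 = mutate_aa_seq(vd, 0.05, prot_dnaq),
      vDnaQ3 = mutate_aa_seq(vd, 0.05, prot_dnaq))

    reg <- structure(list(
      families = families,
      groups = do.call(rbind, grows),
      domains = domains[, c("domain_id", "reference_alignment",
                            "min_hit_length", "len")],
      motifs = motifs,
      complex_types = ctypes,
      layouts = do.call(rbind, layouts),
      alignments = alignments,
      version = "0.1.0",
      cache = new.env(parent = emptyenv())
    ), class = "pol_registry")
    rownames(reg$groups) <- NULL
    rownames(reg$layouts) <- NULL
    validate_registry(reg)
    reg
  })
}

# Positions (1-based, in the group anchor) of an exact motif, from a layout
# table; first instance of the anchoring domain is used.
group_motif_positions_from_layout <- function(laydf, motifs, motif_id) {
  mrow <- motifs[motifs$motif_id == motif_id, ]
  if (nrow(mrow) == 0 || mrow$mode != "exact") return(integer(0))
  drow <- laydf[laydf$element == mrow$domain_id, , drop = FALSE]
  if (nrow(drow) == 0) return(integer(0))
  drow$start[1] - 1L + parse_int_list(mrow$anchor_columns)
}

group_clamp_positions_from_layout <- function(laydf, clamp_region) {
  if (identical(clamp_region, "exo_loop")) {
    drow <- laydf[laydf$element == "DnaQ-exo", , drop = FALSE]
    if (nrow(drow) == 0) return(integer(0))
    return(drow$start[1] - 1L + 60:64)
  }
  drow <- laydf[laydf$element == "CLAMP_LINKER", , drop = FALSE]
  if (nrow(drow) == 0) return(integer(0))
  drow$start[1] - 1L + 3:7
}

#' Positions of a motif in a group's anchor sequence
#'
#' Ground-truth coordinates used by the synthetic-data generator; annotation
#' itself rediscovers motif positions through profile alignment.
#' @param registry a `pol_registry`.
#' @param group_id group identifier.
#' @param motif_id motif identifier (exact-set, `CLAMP`, or `RecA_NT`).
#' @return integer positions in the anchor (empty if the group lacks the motif).
#' @export
motif_positions <- function(registry, group_id, motif_id) {
  laydf <- registry$layouts[registry$layouts$group_id == group_id, ,
                            drop = FALSE]
  if (nrow(laydf) == 0) stop("unknown group: ", group_id)
  if (motif_id == "CLAMP") {
    cr <- registry$groups$clamp_region[registry$groups$group_id == group_id]
    return(group_clamp_positions_from_layout(laydf, cr))
  }
  if (motif_id == "RecA_NT") {
    drow <- laydf[laydf$element == "RECA_SEG", , drop = FALSE]
    if (nrow(drow) == 0) return(integer(0))
    return(seq.int(drow$start[1], drow$end[1]))
  }
  group_motif_positions_from_layout(laydf, registry$motifs, motif_id)
}

group_anchor <- function(registry, group_id, which = 1L) {
  aln <- registry$alignments[[paste0("grp_", group_id)]]
  if (is.null(aln)) stop("no anchors for group: ", group_id)
  unname(aln[which])
}
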