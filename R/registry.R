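# Registry container: load/validate/serialize the packaged ontology and
# query its complex-type decision table.

#' Load a polymerase registry
#'
#' Reads a registry directory (`families.tsv`, `groups.tsv`, `domains.tsv`,
#' `motifs.tsv`, `complex_types.tsv`, `layouts.tsv`, `refs/*.fasta`) and
#' validates all cross-references. With `path = NULL` the packaged default
#' registry is loaded.
#'
#' @param path registry directory, or `NULL` for the packaged default.
#' @return a validated `pol_registry` object.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "registry", package = "polcensus")
    if (!nzchar(path)) stop("packaged registry not found")
  }
  rd <- function(f) utils::read.delim(file.path(path, f), sep = "\t",
                                      header = TRUE, comment.char = "#",
                                      stringsAsFactors = FALSE,
                                      na.strings = NULL, quote = "")
  reg <- list(
    families = rd("families.tsv"),
    groups = rd("groups.tsv"),
    domains = rd("domains.tsv"),
    motifs = rd("motifs.tsv"),
    complex_types = rd("complex_types.tsv"),
    layouts = rd("layouts.tsv")
  )
  reg$motifs$threshold <- suppressWarnings(as.numeric(reg$motifs$threshold))
  reg$complex_types$known <- as.logical(reg$complex_types$known)
  fasta <- list.files(file.path(path, "refs"), pattern = "\\.fasta$",
                      full.names = TRUE)
  alignments <- list()
  for (f in fasta) {
    id <- sub("\\.synthetic\\.fasta$|\\.fasta$", "", basename(f))
    ss <- Biostrings::readAAStringSet(f)
    alignments[[id]] <- stats::setNames(as.character(ss), names(ss))
  }
  reg$alignments <- alignments
  ver <- file.path(path, "VERSION")
  reg$version <- if (file.exists(ver)) readLines(ver, n = 1) else "unknown"
  reg$cache <- new.env(parent = emptyenv())
  reg <- structure(reg, class = "pol_registry")
  validate_registry(reg)
  reg
}

#' Validate registry invariants
#'
#' Checks cross-references (groups -> families/domains/motifs, motifs ->
#' alignments), pattern shapes, the five-family constraint and the
#' 11-complex-type constraint. Called by [load_registry()] and
#' [synthesize_registry()].
#' @param registry a `pol_registry`.
#' @return the registry, invisibly; errors name the offending identifier.
#' @export
validate_registry <- function(registry) {
  r <- registry
  if (!setequal(r$families$family_id, c("A", "B", "C", "X", "Y")))
    stop("registry must define exactly the five families A, B, C, X, Y")
  pol <- r$groups[r$groups$kind == "polymerase", ]
  bad <- setdiff(pol$family_id, r$families$family_id)
  if (length(bad)) stop("polymerase group(s) with unknown family: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(r$groups$group_id))
    stop("duplicated group_id in registry")
  ## domain references
  for (i in seq_len(nrow(r$groups))) {
    doms <- strsplit(r$groups$expected_domains[i], ",", fixed = TRUE)[[1]]
    doms <- doms[nzchar(doms)]
    miss <- setdiff(doms, r$domains$domain_id)
    if (length(miss))
      stop("group ", r$groups$group_id[i],
           " references undefined domain(s): ", paste(miss, collapse = ", "))
    ms <- r$groups$expected_motifs[i]
    if (nzchar(ms)) {
      pairs <- strsplit(ms, ",", fixed = TRUE)[[1]]
      ids <- vapply(strsplit(pairs, ":", fixed = TRUE), `[[`, "", 1)
      miss <- setdiff(ids, r$motifs$motif_id)
      if (length(miss))
        stop("group ", r$groups$group_id[i],
             " references undefined motif(s): ", paste(miss, collapse = ", "))
    }
  }
  ## motif shapes and anchor columns
  for (i in seq_len(nrow(r$motifs))) {
    m <- r$motifs[i, ]
    if (m$mode == "exact") {
      cols <- parse_int_list(m$anchor_columns)
      pat <- parse_pattern(m$pattern)
      if (length(cols) != length(pat))
        stop("motif ", m$motif_id, ": pattern length != anchor column count")
      aln <- r$alignments[[paste0("dom_", m$domain_id)]]
      if (is.null(aln))
        stop("motif ", m$motif_id, ": missing reference alignment dom_",
             m$domain_id)
      if (any(cols < 1 | cols > nchar(aln[1])))
        stop("motif ", m$motif_id, ": anchor column outside alignment")
    } else if (m$mode == "profile") {
      if (is.null(r$alignments[[m$profile_ref]]))
        stop("profile motif ", m$motif_id, ": missing sub-alignment ",
             m$profile_ref)
    }
  }
  ## alignments internally consistent, anchors present for assignable groups
  for (id in names(r$alignments)) {
    aln <- r$alignments[[id]]
    if (length(unique(nchar(aln))) != 1)
      stop("alignment ", id, ": sequences of unequal length")
  }
  for (gid in r$groups$group_id) {
    if (is.null(r$alignments[[paste0("grp_", gid)]]))
      stop("group ", gid, ": anchor alignment missing")
  }
  ## complex types
  ct <- r$complex_types
  if (nrow(ct) != 11) stop("registry must define exactly 11 complex types")
  comps <- lapply(ct$required_components, function(x)
    sort(strsplit(x, ";", fixed = TRUE)[[1]]))
  if (anyDuplicated(vapply(comps, paste, "", collapse = ";")))
    stop("complex types not pairwise distinguishable by required components")
  if (!all(c("ImuA-ImuB-DnaE2", "UmuC-UmuD2-RecA") %in%
           ct$complex_id[ct$known]))
    stop("previously characterized complex types not flagged")
  for (i in seq_len(nrow(ct))) {
    for (comp in parse_complex_components(ct$required_components[i])) {
      miss <- setdiff(comp$groups, r$groups$group_id)
      if (length(miss))
        stop("complex ", ct$complex_id[i],
             ": unresolved group constraint: ", paste(miss, collapse = ", "))
    }
  }
  invisible(r)
}

# Parse a required_components string into a list of component constraints:
# list(role, groups, flags) where flags may include recA_NT/active/inactive/
# imuBC/-imuBC.
parse_complex_components <- function(components) {
  toks <- strsplit(components, ";", fixed = TRUE)[[1]]
  lapply(toks, function(tok) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    role <- kv[1]
    groups <- character(0)
    flags <- character(0)
    if (length(kv) == 2) {
      parts <- strsplit(kv[2], "+", fixed = TRUE)[[1]]
      for (p in parts) {
        if (p %in% c("recA_NT", "active", "inactive", "imuBC", "-imuBC"))
          flags <- c(flags, p)
        else groups <- c(groups, strsplit(p, "|", fixed = TRUE)[[1]])
      }
    }
    if (role %in% names(complex_role_groups) && !length(groups))
      groups <- complex_role_groups[[role]]
    list(role = role, groups = groups, flags = flags)
  })
}

#' List mutasome complex types
#'
#' Returns the registry's complex-type decision table ordered by matching
#' priority, optionally restricted to types containing a given component.
#'
#' @param registry a `pol_registry`.
#' @param component_filter optional component role (e.g. `"poly"`, `"reca"`,
#'   `"srap"`) or registry group id (e.g. `"DnaE2B"`); types whose required
#'   components involve it are returned. An identifier that is neither a
#'   known role nor a registry group is an error.
#' @return data.frame of complex types, ordered by priority.
#' @export
list_complex_types <- function(registry, component_filter = NULL) {
  ct <- registry$complex_types
  ct <- ct[order(ct$priority), , drop = FALSE]
  if (is.null(component_filter)) return(ct)
  roles <- c("poly", "dnae2", "small_subunit", names(complex_role_groups))
  known <- c(roles, registry$groups$group_id)
  if (!component_filter %in% known)
    stop("unknown component role or group: ", component_filter)
  keep <- vapply(ct$required_components, function(x) {
    comps <- parse_complex_components(x)
    any(vapply(comps, function(cc)
      identical(cc$role, component_filter) ||
        component_filter %in% cc$groups ||
        grepl(component_filter, paste(cc$groups, collapse = "|"),
              fixed = TRUE),
      TRUE))
  }, TRUE)
  ct[keep, , drop = FALSE]
}

#' Write a registry to a directory
#'
#' Serializes the registry as diffable plain text: TSV tables plus aligned
#' FASTA reference files under `refs/` (gap character `-`; files are named
#' `*.synthetic.fasta` because the packaged anchors are synthetic constructs).
#' @param registry a `pol_registry`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(file.path(dir, "refs"), recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(registry$families, "families.tsv")
  wr(registry$groups, "groups.tsv")
  wr(registry$domains, "domains.tsv")
  wr(registry$motifs, "motifs.tsv")
  wr(registry$complex_types, "complex_types.tsv")
  wr(registry$layouts, "layouts.tsv")
  writeLines(registry$version, file.path(dir, "VERSION"))
  for (id in names(registry$alignments)) {
    aln <- registry$alignments[[id]]
    ss <- Biostrings::AAStringSet(aln)
    Biostrings::writeXStringSet(ss, file.path(dir, "refs",
                                              paste0(id, ".synthetic.fasta")))
  }
  invisible(dir)
}

#' @export
print.pol_registry <- function(x, ...) {
  cat("polymerase registry (version ", x$version, ")\n", sep = "")
  cat("  families: ", paste(x$families$family_id, collapse = ", "), "\n",
      sep = "")
  cat("  groups:   ", sum(x$groups$kind == "polymerase"), " polymerase + ",
      sum(x$groups$kind == "accessory"), " accessory\n", sep = "")
  cat("  domains:  ", nrow(x$domains), "; motifs: ", nrow(x$motifs),
      "; complex types: ", nrow(x$complex_types), "\n", sep = "")
  invisible(x)
}

# groups of one family (polymerase kind)
family_groups <- function(registry, family_id) {
  registry$groups$group_id[registry$groups$family_id == family_id &
                             registry$groups$kind == "polymerase"]
}

# expected motif statuses for a group as a named character vector
group_expected_motifs <- function(registry, group_id) {
  row <- registry$groups[registry$groups$group_id == group_id, ]
  if (nrow(row) == 0) stop("unknown group: ", group_id)
  ms <- row$expected_motifs
  if (!nzchar(ms)) return(stats::setNames(character(0), character(0)))
  pairs <- strsplit(strsplit(ms, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(pairs, `[[`, "", 2), vapply(pairs, `[[`, "", 1))
}
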