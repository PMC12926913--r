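# Metadata harmonization, distribution summaries and presence-absence
# enrichment statistics.

#' Harmonize genome metadata into environment classes
#'
#' Oxygen: raw labels are mapped to aerobe/anaerobe (facultative anaerobes
#' count as aerobes, since they can use oxygen), then resolved by majority
#' vote; a tie is treated as missing data. Temperature: the first available
#' source in priority order supplies the optimal growth temperature, which is
#' binned into psychrophile (<20), mesophile ([20,45)), thermophile
#' ([45,60)), hyperthermophile (>=60); the binary variable collapses these
#' into mesophile (incl. psychrophiles) vs thermophile (incl.
#' hyperthermophiles).
#'
#' @param genome_records data.frame with `genome_id`, `oxygen_labels`
#'   (comma-separated raw labels), and either `growth_temp_c` or
#'   source-specific columns named in `source_priority`.
#' @param source_priority character vector of temperature column names in
#'   decreasing priority (default `growth_temp_c` only).
#' @return data.frame: `genome_id`, `oxygen_class`, `temp_category`,
#'   `temp_binary`, `gram`.
#' @export
harmonize_metadata <- function(genome_records,
                               source_priority = "growth_temp_c") {
  n <- nrow(genome_records)
  oxy <- character(n)
  tempc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    oxy[i] <- harmonize_oxygen(genome_records$oxygen_labels[i])
    for (src in source_priority) {
      v <- suppressWarnings(as.numeric(genome_records[[src]][i]))
      if (length(v) && !is.na(v)) { tempc[i] <- v; break }
    }
  }
  cat_of <- function(t) {
    if (is.na(t)) return("missing")
    if (t < 20) "psychrophile"
    else if (t < 45) "mesophile"
    else if (t < 60) "thermophile"
    else "hyperthermophile"
  }
  temp_category <- vapply(tempc, cat_of, "")
  temp_binary <- ifelse(temp_category == "missing", "missing",
    ifelse(temp_category %in% c("psychrophile", "mesophile"),
           "mesophile-incl-psychro", "thermophile-incl-hyper"))
  data.frame(genome_id = genome_records$genome_id,
             oxygen_class = oxy,
             temp_category = temp_category,
             temp_binary = temp_binary,
             gram = if ("gram" %in% names(genome_records))
               genome_records$gram else NA_character_,
             stringsAsFactors = FALSE)
}

# Majority vote over raw oxygen labels; facultative -> aerobe; tie -> missing.
harmonize_oxygen <- function(labels) {
  if (is.na(labels) || !nzchar(labels)) return("missing")
  raw <- trimws(strsplit(labels, ",", fixed = TRUE)[[1]])
  mapped <- vapply(raw, function(x) {
    x <- tolower(x)
    if (grepl("facultative", x)) return("aerobe")
    if (grepl("microaero|aerotoler|aerob", x) && !grepl("anaerob", x))
      return("aerobe")
    if (grepl("anaerob", x)) return("anaerobe")
    NA_character_
  }, "")
  bad <- is.na(mapped)
  if (any(bad)) warning("unmappable oxygen label(s) ignored: ",
                        paste(raw[bad], collapse = ", "))
  mapped <- mapped[!bad]
  if (!length(mapped)) return("missing")
  na <- sum(mapped == "aerobe")
  nn <- sum(mapped == "anaerobe")
  if (na > nn) "aerobe" else if (nn > na) "anaerobe" else "missing"
}

#' Two-sided Fisher's exact test for a 2x2 presence-absence table
#'
#' The two-sided p-value sums hypergeometric probabilities of all tables
#' (fixed margins) no more probable than the observed one. The reported odds
#' ratio is the unconditional cross-product (ad)/(bc); the 95% CI is the
#' Woolf logit interval, with the Haldane-Anscombe 0.5 correction applied to
#' all cells only when a zero cell exists.
#'
#' @param table 2x2 integer matrix (rows: presence/absence, columns:
#'   environment classes), or the four counts `a,b,c,d` as a vector.
#' @return list: `table`, `odds_ratio`, `ci95` (low, high), `p_two_sided`,
#'   `undefined` (TRUE for degenerate margins).
#' @export
fisher_enrichment_test <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.integer(table), nrow = 2,
                                         byrow = TRUE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  if (m == 0 || n == 0 || k == 0 || k == N) {
    return(list(table = table, odds_ratio = NA_real_,
                ci95 = c(NA_real_, NA_real_), p_two_sided = NA_real_,
                undefined = TRUE))
  }
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (a * d) / (b * c)
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  se <- sqrt(sum(1 / cells))
  or_ci <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(0.975)
  ci <- exp(log(or_ci) + c(-1, 1) * z * se)
  list(table = table, odds_ratio = or, ci95 = ci, p_two_sided = p,
       undefined = FALSE)
}

#' Environmental enrichment of a polymerase feature
#'
#' Builds the 2x2 table of feature presence against a binary environment
#' class and applies [fisher_enrichment_test()]. Genomes with missing
#' environment class are excluded.
#'
#' @param presence_flags named logical vector (names = genome ids): does the
#'   genome carry the feature.
#' @param env_classes named character vector of environment classes
#'   (`missing` excluded); must take exactly two values among the retained
#'   genomes for a defined result.
#' @param feature,variable labels carried through to the result.
#' @return data.frame with the table counts, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_two_sided`, `undefined`.
#' @export
fisher_enrichment <- function(presence_flags, env_classes,
                              feature = "feature", variable = "variable") {
  common <- intersect(names(presence_flags), names(env_classes))
  env <- env_classes[common]
  keep <- env != "missing" & !is.na(env)
  env <- env[keep]
  pres <- presence_flags[common][keep]
  lev <- sort(unique(env))
  if (length(lev) != 2) {
    return(data.frame(feature = feature, variable = variable,
                      class1 = NA, class2 = NA,
                      a = NA, b = NA, c = NA, d = NA,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_two_sided = NA_real_,
                      undefined = TRUE, stringsAsFactors = FALSE))
  }
  a <- sum(pres & env == lev[1]); b <- sum(pres & env == lev[2])
  c <- sum(!pres & env == lev[1]); d <- sum(!pres & env == lev[2])
  ft <- fisher_enrichment_test(matrix(c(a, b, c, d), 2, byrow = TRUE))
  data.frame(feature = feature, variable = variable,
             class1 = lev[1], class2 = lev[2], a = a, b = b, c = c, d = d,
             odds_ratio = ft$odds_ratio, ci_low = ft$ci95[1],
             ci_high = ft$ci95[2], p_two_sided = ft$p_two_sided,
             undefined = ft$undefined, stringsAsFactors = FALSE)
}

#' Correlation of polymerase counts with genome size
#'
#' Rank correlation (primary) and linear correlation (secondary) of the
#' total polymerase count against genome size, overall and per family.
#'
#' @param genome_table per-genome table (from [write_annotations()] /
#'   [complement_genome_row()]) with `n_polymerases` and `n_A` .. `n_Y`.
#' @param genome_records metadata with `genome_id` and `size_bp`.
#' @return data.frame: `scope`, `spearman`, `pearson`, `n` (NA correlations
#'   for zero-variance counts).
#' @export
count_correlation <- function(genome_table, genome_records) {
  df <- merge(genome_table, genome_records[, c("genome_id", "size_bp")],
              by = "genome_id")
  if (nrow(df) < 3) stop("need at least 3 genomes")
  one <- function(scope, counts) {
    sp <- if (stats::sd(counts) == 0) NA_real_ else
      suppressWarnings(stats::cor(counts, df$size_bp, method = "spearman"))
    pe <- if (stats::sd(counts) == 0) NA_real_ else
      suppressWarnings(stats::cor(counts, df$size_bp, method = "pearson"))
    data.frame(scope = scope, spearman = sp, pearson = pe, n = nrow(df),
               stringsAsFactors = FALSE)
  }
  rbind(one("total", df$n_polymerases),
        one("A", df$n_A), one("B", df$n_B), one("C", df$n_C),
        one("X", df$n_X), one("Y", df$n_Y))
}

#' Per-taxon feature percentage matrix
#'
#' For each taxon at the requested rank and each feature, the percentage of
#' the taxon's genomes carrying at least one instance of the feature.
#'
#' @param protein_table per-protein annotation table.
#' @param complex_table complex-call table.
#' @param genome_records metadata with `genome_id` and the rank column.
#' @param rank taxonomy column name (e.g. `"phylum"`).
#' @param features named list of predicate functions
#'   `function(prot_rows, cx_rows) -> logical`; defaults cover family
#'   presence, RecA-NT presence and complex presence.
#' @return numeric matrix taxa x features, values in [0, 100].
#' @export
taxon_feature_matrix <- function(protein_table, complex_table,
                                 genome_records, rank = "phylum",
                                 features = NULL) {
  if (!rank %in% names(genome_records))
    stop("rank column not in metadata: ", rank)
  if (is.null(features)) {
    fam_feat <- function(f) {
      force(f)
      function(pr, cx) any(pr$family == f & !pr$fragment)
    }
    features <- list(
      A = fam_feat("A"), B = fam_feat("B"), C = fam_feat("C"),
      X = fam_feat("X"), Y = fam_feat("Y"),
      `RecA-NT` = function(pr, cx) any(pr$family == "Y" & pr$recA_NT),
      `Solo PolY` = function(pr, cx) any(pr$family == "Y" & !pr$recA_NT),
      `any complex` = function(pr, cx) nrow(cx) > 0)
  }
  taxa <- genome_records[[rank]]
  taxa <- taxa[!is.na(taxa)]
  taxa <- unique(taxa)
  out <- matrix(NA_real_, nrow = length(taxa), ncol = length(features),
                dimnames = list(taxa, names(features)))
  for (tx in taxa) {
    gids <- genome_records$genome_id[!is.na(genome_records[[rank]]) &
                                       genome_records[[rank]] == tx]
    if (!length(gids)) next
    for (fn in names(features)) {
      hit <- vapply(gids, function(g) {
        pr <- protein_table[protein_table$genome_id == g, , drop = FALSE]
        cx <- complex_table[complex_table$genome_id == g, , drop = FALSE]
        isTRUE(features[[fn]](pr, cx))
      }, TRUE)
      out[tx, fn] <- 100 * mean(hit)
    }
  }
  out
}
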