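#' @useDynLib polcensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 20-letter amino-acid alphabet used throughout; profiles and motif patterns
# are defined over this alphabet, non-canonical residues map to X.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Robinson & Robinson (1991) background amino-acid frequencies.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)

aa_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], AA20)
  x[is.na(x)] <- 0L
  x
}

int_to_aa <- function(x) paste(ifelse(x >= 1, AA20[pmax(x, 1L)], "X"), collapse = "")

#' Normalize an amino-acid sequence
#'
#' Uppercases and maps non-canonical residues (including selenocysteine U and
#' pyrrolysine O) to X, with a warning when such residues are present.
#' @param seq character scalar amino-acid sequence.
#' @param id optional identifier used in the warning message.
#' @return normalized sequence string.
#' @keywords internal
normalize_aa <- function(seq, id = NULL) {
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  bad <- !(chars %in% AA20) & chars != "X"
  if (any(bad)) {
    warning(sprintf("sequence %s: %d non-canonical residue(s) mapped to X",
                    if (is.null(id)) "?" else id, sum(bad)))
    chars[bad] <- "X"
    s <- paste(chars, collapse = "")
  }
  s
}

# Evaluate an expression under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_aa_seq <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND), collapse = "")
}

# Point-substitute residues at `rate`, never touching `protect` positions;
# substitutions are drawn from the background, excluding the current residue.
mutate_aa_seq <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    pool <- setdiff(AA20, chars[i])
    chars[i] <- sample(pool, 1, prob = AA_BACKGROUND[pool] / sum(AA_BACKGROUND[pool]))
  }
  paste(chars, collapse = "")
}

shuffle_aa_seq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

# BLOSUM62 restricted to the 20-letter alphabet, as a numeric matrix.
blosum62_20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62[AA20, AA20]
    }
    cache
  }
})
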