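test_that("oxygen labels merge by majority with facultatives as aerobes", {
  h <- function(labels) polcensus:::harmonize_oxygen(labels)
  expect_equal(h("aerobe,facultative anaerobe"), "aerobe")
  expect_equal(h("aerobe,anaerobe"), "missing")
  expect_equal(h("anaerobe,anaerobe,aerobe"), "anaerobe")
  expect_equal(h("facultative anaerobe"), "aerobe")
  expect_equal(h("microaerophilic"), "aerobe")
  expect_warning(res <- h("aerobe,unicorn"), "unicorn")
  expect_equal(res, "aerobe")
  # label-order invariance
  expect_equal(h("anaerobe,aerobe,aerobe"), h("aerobe,aerobe,anaerobe"))
})

test_that("temperature categories use half-open boundaries", {
  df <- data.frame(genome_id = paste0("g", 1:6),
                   oxygen_labels = "aerobe",
                   growth_temp_c = c(15, 20, 44.9, 45, 60, 70))
  env <- harmonize_metadata(df)
  expect_equal(env$temp_category,
               c("psychrophile", "mesophile", "mesophile", "thermophile",
                 "hyperthermophile", "hyperthermophile"))
  expect_equal(env$temp_binary,
               c(rep("mesophile-incl-psychro", 3),
                 rep("thermophile-incl-hyper", 3)))
})

test_that("temperature sources are merged by priority", {
  df <- data.frame(genome_id = c("g1", "g2", "g3"),
                   oxygen_labels = "aerobe",
                   src_primary = c(30, NA, NA),
                   src_secondary = c(55, 55, NA))
  env <- harmonize_metadata(df, source_priority = c("src_primary",
                                                    "src_secondary"))
  expect_equal(env$temp_category,
               c("mesophile", "thermophile", "missing"))
})

test_that("Fisher's exact test reproduces the worked examples", {
  ft <- fisher_enrichment_test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(ft$p_two_sided, 34 / 70, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, 9)
  ft2 <- fisher_enrichment_test(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(ft2$p_two_sided, 1)
  expect_equal(ft2$odds_ratio, 1)
  ft3 <- fisher_enrichment_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(ft3$p_two_sided, 2 / choose(20, 10), tolerance = 1e-15)
  # CI uses the Haldane-Anscombe correction only for zero cells
  expect_true(is.finite(ft3$ci95[1]) && is.finite(ft3$ci95[2]))
  expect_true(ft3$ci95[1] > 1)
  # degenerate margins are flagged undefined
  ft4 <- fisher_enrichment_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(ft4$undefined)
})

test_that("exact p matches a brute-force enumeration oracle (N <= 30)", {
  # oracle: enumerate all tables with the observed margins via choose()
  oracle_p <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    ks <- max(0, k - n):min(k, m)
    logp <- lchoose(m, ks) + lchoose(n, k - ks) - lchoose(m + n, k)
    p <- exp(logp)
    pobs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
    sum(p[p <= pobs * (1 + 1e-7)])
  }
  worst <- 0
  for (N in c(5, 11, 18, 24, 30)) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      d <- N - a - b - c
      if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) next
      p1 <- fisher_enrichment_test(matrix(c(a, b, c, d), 2,
                                          byrow = TRUE))$p_two_sided
      p2 <- oracle_p(a, b, c, d)
      worst <- max(worst, abs(p1 - p2))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("odds ratios agree with the cross-product and stats::fisher.test p", {
  set.seed(2)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    ft <- fisher_enrichment_test(tab)
    expect_equal(ft$odds_ratio, (tab[1, 1] * tab[2, 2]) /
                   (tab[1, 2] * tab[2, 1]))
    expect_equal(ft$p_two_sided, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("enrichment wrapper excludes missing classes and labels cells", {
  pres <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                          paste0("g", 1:5))
  env <- stats::setNames(c("aerobe", "anaerobe", "aerobe", "anaerobe",
                           "missing"), paste0("g", 1:5))
  res <- fisher_enrichment(pres, env, feature = "PolY", variable = "oxygen")
  expect_equal(res$a + res$b + res$c + res$d, 4) # g5 excluded
  expect_equal(res$feature, "PolY")
  # degenerate: single class
  env2 <- stats::setNames(rep("aerobe", 5), paste0("g", 1:5))
  expect_true(fisher_enrichment(pres, env2)$undefined)
})

test_that("count correlations match a manual rank statistic", {
  set.seed(31)
  n <- 200
  size <- round(stats::runif(n, 1e6, 9e6))
  counts <- stats::rpois(n, 2 + 4 * size / 1e7)
  gt <- data.frame(genome_id = paste0("g", 1:n), n_polymerases = counts,
                   n_A = counts, n_B = 0L, n_C = 1L, n_X = 0L, n_Y = 0L)
  meta <- data.frame(genome_id = paste0("g", 1:n), size_bp = size)
  res <- count_correlation(gt, meta)
  tot <- res[res$scope == "total", ]
  manual <- stats::cor(rank(counts), rank(size), method = "pearson")
  expect_gt(tot$spearman, 0)
  expect_equal(tot$spearman, manual, tolerance = 0.1)
  # zero-variance counts -> NA
  expect_true(is.na(res$spearman[res$scope == "B"]))
  # proportional counts -> rank correlation 1
  gt2 <- gt
  gt2$n_polymerases <- size %/% 1000
  expect_equal(count_correlation(gt2, meta)$spearman[1], 1,
               tolerance = 1e-6)
  expect_error(count_correlation(gt[1:2, ], meta[1:2, ]), "at least 3")
})

test_that("taxon feature matrix computes presence percentages", {
  prot <- data.frame(
    genome_id = c("g1", "g1", "g2", "g3"),
    protein_id = paste0("p", 1:4),
    family = c("Y", "C", "C", "C"), group = c("PolY-core", "DnaE1",
                                              "DnaE1", "DnaE1"),
    fragment = FALSE, recA_NT = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cx <- data.frame(genome_id = "g1", complex_id = "PolY-RecA",
                   stringsAsFactors = FALSE)
  meta <- data.frame(genome_id = c("g1", "g2", "g3"),
                     phylum = c("P1", "P1", "P2"),
                     stringsAsFactors = FALSE)
  m <- taxon_feature_matrix(prot, cx, meta, rank = "phylum")
  expect_equal(m["P1", "Y"], 50)
  expect_equal(m["P1", "C"], 100)
  expect_equal(m["P2", "Y"], 0)
  expect_true(all(m >= 0 & m <= 100))
  expect_error(taxon_feature_matrix(prot, cx, meta, rank = "kingdom"),
               "rank")
})
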