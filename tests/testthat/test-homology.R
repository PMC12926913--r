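test_that("profile construction follows the log-odds scheme", {
  p <- build_profile(c(a = "ACD", b = "ACD"), "toy")
  expect_equal(p$consensus, "ACD")
  h <- scan_domains("ACD", list(p), tau = 0.1)
  expect_equal(h$raw_score, p$self_score, tolerance = 1e-12)
  expect_equal(h$norm_score, 1.0, tolerance = 1e-12)

  # a column holding D and E at equal weight scores both above background
  p2 <- build_profile(c(a = "ADAA", b = "AEAA"), "de")
  expect_gt(p2$scores["D", 2], p2$scores["K", 2])
  expect_gt(p2$scores["E", 2], p2$scores["K", 2])

  expect_error(build_profile(c(only = "ACD")), "at least 2")
  expect_error(build_profile(c(a = "ACD", b = "ACDE")), "inconsistent")
})

test_that("gappy columns are dropped as non-match columns", {
  p <- build_profile(c(a = "A-CD", b = "A-CD", c = "AWCD"), "gap")
  # column 2 has 2/3 gaps -> dropped
  expect_equal(ncol(p$scores), 3)
  expect_equal(p$match_columns, c(1L, 3L, 4L))
})

test_that("query identical to a profile consensus scores norm 1", {
  profs <- shared_profiles()
  p <- profs[["Pol-core-C"]]
  h <- scan_domains(p$consensus, list(p))
  expect_equal(nrow(h), 1)
  expect_equal(h$norm_score, 1.0, tolerance = 1e-9)
  expect_equal(h$q_start, 1)
  expect_equal(h$q_end, nchar(p$consensus))
})

test_that("norm_score never exceeds the consensus self-comparison", {
  reg <- shared_registry()
  profs <- shared_profiles()
  dom <- profs[reg$domains$domain_id]
  set.seed(7)
  for (g in c("PolA1", "PolC", "UmuC", "PolX1", "G1")) {
    s <- polcensus:::mutate_aa_seq(polcensus:::group_anchor(reg, g), 0.05)
    h <- scan_domains(s, dom)
    expect_true(all(h$norm_score <= 1 + 1e-9), info = g)
  }
})

test_that("sub-200-residue core fragments are flagged and excluded", {
  reg <- shared_registry()
  profs <- shared_profiles()
  core <- profs[["Pol-core-C"]]
  frag <- substr(core$consensus, 1, 150)
  h <- scan_domains(frag, list(core))
  expect_true(h$fragment)
  expect_true(is.na(assign_family(h)$family))
  # same sequence padded beyond 200 residues is no longer a fragment
  set.seed(1)
  long <- paste0(frag, polcensus:::random_aa_seq(100))
  h2 <- scan_domains(long, list(core))
  expect_false(h2$fragment)
  expect_equal(assign_family(h2)$family, "C")
})

test_that("shuffled sequences yield no hits at tau 0.3 (empirical null)", {
  reg <- shared_registry()
  profs <- shared_profiles()
  dom <- profs[reg$domains$domain_id]
  set.seed(99)
  anchors <- vapply(c("PolY-core", "DnaE1", "PolA1", "G1"),
                    function(g) polcensus:::group_anchor(reg, g), "")
  n_hit <- 0
  n <- 200
  for (i in seq_len(n)) {
    s <- polcensus:::shuffle_aa_seq(anchors[(i %% length(anchors)) + 1])
    if (nrow(scan_domains(s, dom)) > 0) n_hit <- n_hit + 1
  }
  expect_lte(n_hit / n, 0.01)
})

test_that("family assignment picks the best non-fragment core hit", {
  mkhits <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(protein_id = "p", domain_id = r[[1]], q_start = 1,
                 q_end = 100, raw_score = 1,
                 norm_score = as.numeric(r[[2]]),
                 fragment = isTRUE(r[[3]]), stringsAsFactors = FALSE)))
  }
  expect_equal(assign_family(mkhits(list("Pol-core-Y", 0.8, FALSE),
                                    list("PHP", 0.5, FALSE)))$family, "Y")
  expect_true(is.na(assign_family(mkhits(list("PHP", 0.6, FALSE)))$family))
  res <- assign_family(mkhits(list("Pol-core-C", 0.71, FALSE),
                              list("Pol-core-Y", 0.70, FALSE)))
  expect_equal(res$family, "C")
  expect_equal(res$margin, 0.01, tolerance = 1e-12)
})

test_that("anchored clustering recovers two planted groups exactly", {
  reg <- shared_registry()
  # synthetic family: two equal-length groups, ~60% between-group and
  # ~95% within-group identity
  set.seed(21)
  base1 <- polcensus:::group_anchor(reg, "PolA1-like")
  base2 <- polcensus:::group_anchor(reg, "PolA3")
  seqs <- character(0)
  truth <- character(0)
  for (i in 1:20) {
    seqs[paste0("q1_", i)] <- polcensus:::mutate_aa_seq(base1, 0.05)
    truth[paste0("q1_", i)] <- "PolA1-like"
    seqs[paste0("q2_", i)] <- polcensus:::mutate_aa_seq(base2, 0.05)
    truth[paste0("q2_", i)] <- "PolA3"
  }
  ga <- cluster_groups(seqs, reg, "A")
  expect_equal(stats::setNames(ga$group_id, ga$protein_id)[names(truth)],
               truth)

  # independent oracle: pairwise identity separates the groups
  pid_identity <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }
  within <- pid_identity(seqs[["q1_1"]], seqs[["q1_2"]])
  between <- pid_identity(seqs[["q1_1"]], seqs[["q2_1"]])
  expect_gt(within, 0.85)
  expect_lt(between, 0.75)
})

test_that("clustering is invariant to input order", {
  reg <- shared_registry()
  set.seed(5)
  seqs <- c(x1 = polcensus:::mutate_aa_seq(
              polcensus:::group_anchor(reg, "DnaE1"), 0.05),
            x2 = polcensus:::mutate_aa_seq(
              polcensus:::group_anchor(reg, "PolC"), 0.05),
            x3 = polcensus:::mutate_aa_seq(
              polcensus:::group_anchor(reg, "DnaE2A"), 0.05))
  g1 <- cluster_groups(seqs, reg, "C")
  g2 <- cluster_groups(rev(seqs), reg, "C")
  expect_equal(g1[, c("protein_id", "group_id")],
               g2[, c("protein_id", "group_id")])
  expect_equal(g1$group_id, c("DnaE1", "PolC", "DnaE2A"))
})

test_that("dissimilar singletons become unassigned-novel", {
  reg <- shared_registry()
  set.seed(3)
  novel <- c(nv = polcensus:::random_aa_seq(400))
  ga <- cluster_groups(novel, reg, "A")
  expect_equal(ga$group_id, "unassigned-novel")
})

test_that("mixed families in cluster input raise an error", {
  reg <- shared_registry()
  prots <- list(
    structure(list(protein_id = "a", sequence = "ACDEF", family = "A"),
              class = "protein_record"),
    structure(list(protein_id = "b", sequence = "ACDEF", family = "C"),
              class = "protein_record"))
  expect_error(cluster_groups(prots, reg, "A"), "mixed families")
})
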