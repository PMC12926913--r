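test_that("replication-system typing matches the three-system rule", {
  combos <- expand.grid(PolC = c(FALSE, TRUE), DnaE1 = c(FALSE, TRUE),
                        DnaE3 = c(FALSE, TRUE), DnaE2 = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    row <- combos[i, ]
    anns <- list()
    if (row$PolC) anns$pc <- stub_annotation("pc", "C", "PolC")
    if (row$DnaE1) anns$e1 <- stub_annotation("e1", "C", "DnaE1")
    if (row$DnaE3) anns$e3 <- stub_annotation("e3", "C", "DnaE3")
    if (row$DnaE2) anns$e2 <- stub_annotation("e2", "C", "DnaE2A")
    if (!row$DnaE1 && !row$DnaE3) {
      expect_error(classify_replication_system(anns), "replicative")
      next
    }
    expected <- if (row$PolC && row$DnaE3) "PolC+DnaE3"
                else if (row$PolC && row$DnaE1) "PolC+DnaE1"
                else "DnaE1-only"
    expect_equal(classify_replication_system(anns)$system, expected,
                 info = paste(names(row)[unlist(row)], collapse = "+"))
  }
})

test_that("paralogs and fragments do not change system typing", {
  anns <- list(stub_annotation("a", "C", "DnaE1"),
               stub_annotation("b", "C", "DnaE1"),
               stub_annotation("c", "C", "PolC", fragment = TRUE))
  expect_equal(classify_replication_system(anns)$system, "DnaE1-only")
})

test_that("proofreader census reproduces the two archetypes", {
  reg <- shared_registry()
  # Clostridia-like: PolC (PHP + DnaQ active) + DnaE1 (PHP active)
  sim <- simulate_genome(list(genome_id = "clo",
                              genes = list(gene_plan("PolC"),
                                           gene_plan("DnaE1")),
                              decoys = 1, mutation_rate = 0), reg, seed = 4)
  cc <- annotate_sim(sim)$complement
  expect_equal(cc$replication_system$system, "PolC+DnaE1")
  expect_equal(sum(cc$proofreaders$active), 3)
  # Bacilli-like: PolC (PHP broken, DnaQ active) + DnaE3 (PHP inactive)
  sim2 <- simulate_genome(list(
    genome_id = "bac",
    genes = list(gene_plan("PolC", motifs = c(PHP_AS = "broken")),
                 gene_plan("DnaE3")),
    decoys = 1, mutation_rate = 0), reg, seed = 5)
  cc2 <- annotate_sim(sim2)$complement
  expect_equal(cc2$replication_system$system, "PolC+DnaE3")
  act <- cc2$proofreaders[cc2$proofreaders$active, ]
  expect_equal(nrow(act), 1)
  expect_equal(act$kind, "DnaQ-domain")
})

test_that("standalone DnaQ admission is conservative", {
  reg <- shared_registry()
  sim <- simulate_genome(list(
    genome_id = "dq",
    genes = list(gene_plan("DnaE1", motifs = c(PHP_AS = "broken")),
                 gene_plan(".DnaQ-solo"), gene_plan(".DnaQ-like")),
    decoys = 0, mutation_rate = 0), reg, seed = 2)
  cc <- annotate_sim(sim)$complement
  # both standalone DEDDh proteins are detected ...
  expect_setequal(cc$accessory$group_id, c(".DnaQ-solo", ".DnaQ-like"))
  # ... but only the close homolog of the validated references is admitted
  subunits <- cc$proofreaders[cc$proofreaders$kind == "DnaQ-subunit", ]
  expect_equal(nrow(subunits), 1)
  expect_equal(subunits$carrier, "dq_p02")
  expect_true(subunits$active)
})

test_that("a model score can admit a distant standalone DnaQ", {
  reg <- shared_registry()
  sim <- simulate_genome(list(
    genome_id = "dq2",
    genes = list(gene_plan("DnaE1"), gene_plan(".DnaQ-like")),
    decoys = 0, mutation_rate = 0), reg, seed = 3)
  ms <- data.frame(protein_id = "dq2_p02", genome_id = "dq2",
                   complex_id = "DnaE-DnaQ", source = "multimer-v2",
                   pTM = 0.8, ipTM = 0.9, global = 0.45, clash = FALSE,
                   stringsAsFactors = FALSE)
  cc <- annotate_sim(sim, options = list(model_scores = ms))$complement
  expect_true("DnaQ-subunit" %in% cc$proofreaders$kind)
})

test_that("5'-3' exonuclease complementation covers the three outcomes", {
  reg <- shared_registry()
  mk <- function(genes, id, seed) {
    sim <- simulate_genome(list(genome_id = id, genes = genes, decoys = 1,
                                mutation_rate = 0), reg, seed = seed)
    annotate_sim(sim)$complement
  }
  cc1 <- mk(list(gene_plan("DnaE1"), gene_plan("PolA1")), "x1", 6)
  expect_equal(cc1$exo53_status, "PolA1")
  cc2 <- mk(list(gene_plan("DnaE1"), gene_plan(".FEN-solo")), "x2", 7)
  expect_equal(cc2$exo53_status, "solo")
  cc3 <- mk(list(gene_plan("DnaE1")), "x3", 8)
  expect_equal(cc3$exo53_status, "none")
  # Pol I with a broken FEN active site does not satisfy the requirement
  cc4 <- mk(list(gene_plan("DnaE1"),
                 gene_plan("PolA1", motifs = c(FEN_AS = "broken"))), "x4", 9)
  expect_equal(cc4$exo53_status, "none")
})

test_that("annotation is deterministic and local to the edited gene", {
  reg <- shared_registry()
  plan <- list(genome_id = "det", genes = list(gene_plan("DnaE1"),
                                               gene_plan("PolA1"),
                                               gene_plan("DinP")),
               decoys = 2, mutation_rate = 0.02)
  sim <- simulate_genome(plan, reg, seed = 10)
  t1 <- annotate_sim(sim)$table
  t2 <- annotate_sim(sim)$table
  expect_identical(t1, t2)
  # removing the PolY gene zeroes the Y count and leaves the rest unchanged
  plan2 <- plan
  plan2$genes <- plan2$genes[1:2]
  sim2 <- simulate_genome(plan2, reg, seed = 10)
  cc <- annotate_sim(sim)$complement
  cc2 <- annotate_sim(sim2)$complement
  n_of <- function(cc, f) cc$counts$family$n[cc$counts$family$family == f]
  expect_equal(n_of(cc, "Y"), 1)
  expect_equal(n_of(cc2, "Y"), 0)
  expect_equal(n_of(cc2, "A"), n_of(cc, "A"))
  expect_equal(cc2$replication_system$system, cc$replication_system$system)
})

test_that("planted truth is recovered exactly at zero mutation noise", {
  reg <- shared_registry()
  plans <- list(
    list(genome_id = "z1", genes = list(gene_plan("DnaE1"),
                                        gene_plan("PolA1"),
                                        gene_plan("UmuC")),
         decoys = 2, mutation_rate = 0),
    list(genome_id = "z2", genes = list(gene_plan("PolC"),
                                        gene_plan("DnaE3"),
                                        gene_plan("PolX1")),
         decoys = 2, mutation_rate = 0))
  for (plan in plans) {
    sim <- simulate_genome(plan, reg, seed = 11)
    res <- annotate_sim(sim)
    tr <- sim$truth$proteins
    tr <- tr[tr$kind == "polymerase", ]
    m <- merge(res$table, tr, by = "protein_id")
    expect_equal(nrow(m), nrow(tr))
    expect_equal(m$group.x, m$group.y)
    expect_equal(res$complement$replication_system$system,
                 sim$truth$replication_system)
  }
})

test_that("proofreader count is bounded by the census invariant", {
  reg <- shared_registry()
  sim <- simulate_genome(list(genome_id = "b1",
                              genes = list(gene_plan("PolC"),
                                           gene_plan("DnaE1"),
                                           gene_plan(".DnaQ-solo")),
                              decoys = 1, mutation_rate = 0), reg, seed = 12)
  cc <- annotate_sim(sim)$complement
  n_repl <- sum(vapply(cc$polymerases, function(a)
    a$family == "C" && a$group %in% c("PolC", "DnaE1", "DnaE3"), TRUE))
  n_standalone <- sum(cc$proofreaders$kind == "DnaQ-subunit")
  expect_lte(nrow(cc$proofreaders), 2 * n_repl + n_standalone)
})
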