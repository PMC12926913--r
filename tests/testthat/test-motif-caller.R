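# Direct rule-level checks of the active-site and interaction-motif calls.

motif_row <- function(motif_id) {
  reg <- shared_registry()
  reg$motifs[reg$motifs$motif_id == motif_id, ]
}

# scan one domain profile and return the alignment-column mapping
hit_mapping <- function(seq, domain_id) {
  profs <- shared_profiles()
  h <- scan_domains(seq, profs[domain_id])
  if (nrow(h) == 0) return(NULL)
  anchor_align(h[1, , drop = FALSE], profs[[domain_id]],
               mapping = attr(h, "mappings")[[1]])
}

test_that("anchor alignment maps columns through indels and truncations", {
  profs <- shared_profiles()
  p <- profs[["PHP"]]
  cons <- p$consensus
  m0 <- hit_mapping(cons, "PHP")
  expect_equal(m0, seq_len(nchar(cons)))

  # 5-residue insertion before the motif shifts downstream positions by +5
  ins <- paste0(substr(cons, 1, 2), "WWWWW", substr(cons, 3, nchar(cons)))
  m1 <- hit_mapping(ins, "PHP")
  expect_equal(m1[50], 55)
  call <- call_active_site(ins, motif_row("PHP_AS"), m1)
  expect_equal(call$status, "active")
  expect_equal(call$matched, "HHDHEHCDH")

  # truncation before the motif columns -> undetermined
  trunc <- substr(cons, 1, 40)
  m2 <- hit_mapping(trunc, "PHP")
  call2 <- call_active_site(trunc, motif_row("PHP_AS"), m2)
  expect_equal(call2$status, "undetermined")
})

test_that("PHP active-site rule: any deviation is inactive", {
  profs <- shared_profiles()
  cons <- profs[["PHP"]]$consensus
  cols <- polcensus:::parse_int_list(motif_row("PHP_AS")$anchor_columns)
  chars <- strsplit(cons, "")[[1]]
  expect_equal(paste(chars[cols], collapse = ""), "HHDHEHCDH")
  expect_equal(call_active_site(cons, motif_row("PHP_AS"),
                                hit_mapping(cons, "PHP"))$status, "active")
  # the C/H position tolerates H
  chars2 <- chars; chars2[cols[7]] <- "H"
  s2 <- paste(chars2, collapse = "")
  expect_equal(call_active_site(s2, motif_row("PHP_AS"),
                                hit_mapping(s2, "PHP"))$status, "active")
  # E -> Q deviation inactivates
  chars3 <- chars; chars3[cols[5]] <- "Q"
  s3 <- paste(chars3, collapse = "")
  call <- call_active_site(s3, motif_row("PHP_AS"), hit_mapping(s3, "PHP"))
  expect_equal(call$status, "inactive")
  expect_equal(call$matched, "HHDHQHCDH")
  # X at a motif position: inactive by default, undetermined with the flag
  chars4 <- chars; chars4[cols[1]] <- "X"
  s4 <- paste(chars4, collapse = "")
  expect_equal(call_active_site(s4, motif_row("PHP_AS"),
                                hit_mapping(s4, "PHP"))$status, "inactive")
  expect_equal(call_active_site(s4, motif_row("PHP_AS"),
                                hit_mapping(s4, "PHP"),
                                x_as_undetermined = TRUE)$status,
               "undetermined")
})

test_that("DEDDh and DEDDy discriminate on the final residue", {
  profs <- shared_profiles()
  cons <- profs[["DnaQ-exo"]]$consensus
  cols <- polcensus:::parse_int_list(motif_row("DEDDh")$anchor_columns)
  chars <- strsplit(cons, "")[[1]]
  chars[cols] <- c("D", "E", "D", "D", "H")
  sh <- paste(chars, collapse = "")
  mh <- hit_mapping(sh, "DnaQ-exo")
  expect_equal(call_active_site(sh, motif_row("DEDDh"), mh)$status, "active")
  expect_equal(call_active_site(sh, motif_row("DEDDy"), mh)$status,
               "inactive")
  chars[cols[5]] <- "Y"
  sy <- paste(chars, collapse = "")
  my <- hit_mapping(sy, "DnaQ-exo")
  expect_equal(call_active_site(sy, motif_row("DEDDh"), my)$status,
               "inactive")
  expect_equal(call_active_site(sy, motif_row("DEDDy"), my)$status, "active")
})

test_that("active-site calling is idempotent and case-insensitive", {
  profs <- shared_profiles()
  cons <- profs[["FEN-exo"]]$consensus
  m <- hit_mapping(cons, "FEN-exo")
  c1 <- call_active_site(cons, motif_row("FEN_AS"), m)
  c2 <- call_active_site(tolower(cons), motif_row("FEN_AS"), m)
  c3 <- call_active_site(cons, motif_row("FEN_AS"), m)
  expect_equal(c1$status, "active")
  expect_equal(c1, c2)
  expect_equal(c1, c3)
})

test_that("clamp motif requires QxxLF in the designated region", {
  reg <- shared_registry()
  grow <- reg$groups[reg$groups$group_id == "PolA2", ]
  anchor <- polcensus:::group_anchor(reg, "PolA2")
  profs <- shared_profiles()
  hits <- scan_domains(anchor, profs[reg$domains$domain_id])
  calls <- detect_interaction_motifs(anchor, grow, reg, hits = hits)
  clamp <- calls[calls$motif_id == "CLAMP", ]
  expect_equal(clamp$status, "present")
  expect_equal(clamp$matched, "QSSLF")
  expect_equal(clamp$positions, "120,121,122,123,124")
  # F -> A violates QxxLF
  broken <- anchor
  substr(broken, 124, 124) <- "A"
  calls2 <- detect_interaction_motifs(broken, grow, reg, hits = hits)
  expect_equal(calls2$status[calls2$motif_id == "CLAMP"], "absent")
})

test_that("RecA-NT is called by profile score against its sub-alignment", {
  reg <- shared_registry()
  grow <- reg$groups[reg$groups$group_id == "UmuC", ]
  anchor <- polcensus:::group_anchor(reg, "UmuC")
  calls <- detect_interaction_motifs(anchor, grow, reg)
  expect_equal(calls$status[calls$motif_id == "RecA_NT"], "present")
  # scrambling the segment abolishes the call
  set.seed(8)
  pos <- motif_positions(reg, "UmuC", "RecA_NT")
  chars <- strsplit(anchor, "")[[1]]
  chars[pos] <- sample(chars[pos])
  scram <- paste(chars, collapse = "")
  calls2 <- detect_interaction_motifs(scram, grow, reg)
  expect_equal(calls2$status[calls2$motif_id == "RecA_NT"], "absent")
})

test_that("catalytic-site calls drive active/inactive polymerase status", {
  reg <- shared_registry()
  profs <- shared_profiles()
  anchor <- polcensus:::group_anchor(reg, "PolY-core")
  m <- hit_mapping(anchor, "Pol-core-Y")
  expect_equal(call_polymerase_activity(anchor, "Y", m, reg)$status,
               "active")
  pos <- motif_positions(reg, "PolY-core", "CAT_Y")
  broken <- anchor
  substr(broken, pos[1], pos[1]) <- "N"
  mb <- hit_mapping(broken, "Pol-core-Y")
  expect_equal(call_polymerase_activity(broken, "Y", mb, reg)$status,
               "inactive")
  # the exonuclease-only PolX class: polymerase site dead, PHP intact
  x1 <- polcensus:::group_anchor(reg, "PolX1")
  posx <- motif_positions(reg, "PolX1", "CAT_X")
  substr(x1, posx[2], posx[2]) <- "N"
  mx <- hit_mapping(x1, "Pol-core-X")
  expect_equal(call_polymerase_activity(x1, "X", mx, reg)$status, "inactive")
  mphp <- hit_mapping(x1, "PHP")
  expect_equal(call_active_site(x1, motif_row("PHP_AS"), mphp)$status,
               "active")
})

test_that("exactly one status per call and counts are conserved", {
  reg <- shared_registry()
  set.seed(13)
  statuses <- character(0)
  for (i in 1:12) {
    g <- sample(c("PolC", "DnaE1", "PolA1"), 1)
    toggles <- c(PHP_AS = sample(c("intact", "broken"), 1))
    toggles <- toggles[names(toggles) %in%
                         names(polcensus:::group_expected_motifs(reg, g))]
    sim <- simulate_gene(reg, g, motifs = if (length(toggles)) toggles,
                         mutation_rate = 0.05)
    mid <- if ("PHP_AS" %in% names(sim$truth$motif_status)) "PHP_AS"
           else "FEN_AS"
    dom <- motif_row(mid)$domain_id
    m <- hit_mapping(sim$sequence, dom)
    call <- if (is.null(m))
      polcensus:::motif_call_row("q", mid, "undetermined")
    else call_active_site(sim$sequence, motif_row(mid), m)
    expect_true(call$status %in% c("active", "inactive", "undetermined"))
    statuses <- c(statuses, call$status)
  }
  expect_equal(sum(statuses == "active") + sum(statuses == "inactive") +
                 sum(statuses == "undetermined"), length(statuses))
})

test_that("motif count matrices conserve column sums", {
  calls <- data.frame(protein_id = paste0("p", 1:10), motif_id = "DEDDh",
                      status = c(rep("active", 7), rep("inactive", 3)),
                      matched = c(rep("DEDDH", 7), rep("NEDDH", 3)),
                      positions = "", evidence = 1,
                      stringsAsFactors = FALSE)
  cm <- export_motif_counts(list(grp = calls))$grp
  expect_equal(unname(colSums(cm)), rep(10, 5))
  expect_equal(unname(cm["D", 1]), 7)
  expect_equal(unname(cm["N", 1]), 3)
  # identical calls concentrate counts on one residue
  ident <- calls[calls$status == "active", ]
  cm2 <- export_motif_counts(list(grp = ident))$grp
  expect_true(all(apply(cm2, 2, max) == 7))
  # only undetermined -> empty matrix with warning
  und <- data.frame(protein_id = "p", motif_id = "DEDDh",
                    status = "undetermined", matched = "", positions = "",
                    evidence = NA, stringsAsFactors = FALSE)
  expect_warning(cm3 <- export_motif_counts(list(grp = und))$grp,
                 "no determined")
  expect_equal(ncol(cm3), 0)
})

test_that("group-level motif prevalence classes use the 0.9/0.1 bounds", {
  mk <- function(npres, nabs) data.frame(
    protein_id = paste0("p", seq_len(npres + nabs)), motif_id = "RecA_NT",
    status = c(rep("present", npres), rep("absent", nabs)),
    matched = "", positions = "", evidence = 1, stringsAsFactors = FALSE)
  expect_equal(summarize_motif_prevalence(mk(19, 1))$class, "most")
  expect_equal(summarize_motif_prevalence(mk(1, 19))$class, "none")
  expect_equal(summarize_motif_prevalence(mk(10, 10))$class, "partial")
})
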