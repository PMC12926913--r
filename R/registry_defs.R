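# In-code definition of the packaged ontology: families, groups, domains,
# motifs, and the mutasome complex-type decision table. synthesize_registry()
# turns these definitions into a full registry with synthetic anchor
# alignments; the packaged registry under inst/extdata/registry is the
# serialized result.

registry_family_defs <- function() {
  data.frame(
    family_id = c("A", "B", "C", "X", "Y"),
    fold_class = c("Klenow-fold", "Klenow-fold", "Polb-like", "Polb-like",
                   "Klenow-fold"),
    stringsAsFactors = FALSE
  )
}

registry_domain_defs <- function() {
  d <- rbind(
    c("Pol-core-A", 180), c("Pol-core-B", 180), c("Pol-core-C", 180),
    c("Pol-core-X", 150), c("Pol-core-Y", 150),
    c("PHP", 100), c("DnaQ-exo", 90), c("FEN-exo", 90),
    c("8kDa", 60), c("OB", 70), c("CTD", 60), c("Tudor", 60),
    c("ImuB-C", 70), c("LF", 50), c("thumb", 40), c("PolB-NT", 80),
    c("RecA-core", 120), c("ImuA-core", 120), c("UmuD-core", 70),
    c("YqjX-arm", 30), c("YqjX-body", 60), c("YhjD-extra", 60),
    c("SRAP-core", 80)
  )
  out <- data.frame(domain_id = d[, 1], len = as.integer(d[, 2]),
                    stringsAsFactors = FALSE)
  out$min_hit_length <- pmax(20L, as.integer(floor(out$len / 2)))
  out$reference_alignment <- paste0("dom_", out$domain_id)
  out
}

# Polymerase-core domain of each family.
family_core_domain <- c(A = "Pol-core-A", B = "Pol-core-B", C = "Pol-core-C",
                        X = "Pol-core-X", Y = "Pol-core-Y")

# Exact-set motifs: anchor columns are 1-based columns of the named domain's
# reference alignment; pattern positions list allowed residues ("/" separated
# in the serialized form, "x" = any residue).
registry_motif_defs <- function() {
  m <- list(
    list("PHP_AS", "exact", "PHP", c(5, 7, 21, 23, 41, 43, 56, 61, 66),
         "H,H,D,H,E,H,C/H,D,H"),
    list("DEDDh", "exact", "DnaQ-exo", c(6, 26, 41, 61, 76), "D,E,D,D,H"),
    list("DEDDy", "exact", "DnaQ-exo", c(6, 26, 41, 61, 76), "D,E,D,D,Y"),
    list("FEN_AS", "exact", "FEN-exo", c(8, 22, 40, 58, 72), "D,D/E,E,D,D"),
    list("CAT_A", "exact", "Pol-core-A", c(70, 100, 103), "D,D,E"),
    list("CAT_B", "exact", "Pol-core-B", c(70, 100, 103), "D,D,E"),
    list("CAT_Y", "exact", "Pol-core-Y", c(60, 90, 93), "D,D,E"),
    list("CAT_C", "exact", "Pol-core-C", c(70, 100, 102), "D,D,D"),
    list("CAT_X", "exact", "Pol-core-X", c(60, 88, 90), "D,D,D"),
    list("CLAMP", "regex", ".", integer(0), "Q,x,x,L,F"),
    list("RecA_NT", "profile", ".", integer(0), "")
  )
  data.frame(
    motif_id = vapply(m, `[[`, "", 1),
    mode = vapply(m, `[[`, "", 2),
    domain_id = vapply(m, function(x) as.character(x[[3]]), ""),
    anchor_columns = vapply(m, function(x) paste(x[[4]], collapse = ","), ""),
    pattern = vapply(m, `[[`, "", 5),
    profile_ref = ifelse(vapply(m, `[[`, "", 2) == "profile",
                         "motif_RecA-NT", ""),
    threshold = ifelse(vapply(m, `[[`, "", 2) == "profile", 0.5, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Per-family catalytic-site motif (palm carboxylates); Klenow-fold families
# carry two aspartates + glutamate, Polb-fold families a carboxylate triad.
family_cat_motif <- c(A = "CAT_A", B = "CAT_B", C = "CAT_C", X = "CAT_X",
                      Y = "CAT_Y")

# Group definitions. `elements` is the ordered anchor layout: domain ids plus
# layout tokens PAD60 (leading pad), LINKER (10-mer), CLAMP_LINKER (10-mer
# with QSSLF at offsets 3-7), RECA_SEG (RecA-NT segment, 20-mer).
# `motifs` maps motif_id -> expectation (required / typical / absent);
# "absent" anchors carry a deliberately broken motif.
registry_group_defs <- function() {
  g <- function(id, fam, kind, elements, motifs = character(0),
                clamp_region = "", divergence = 0.225, notes = "") {
    list(group_id = id, family_id = fam, kind = kind, elements = elements,
         motifs = motifs, clamp_region = clamp_region,
         divergence = divergence, notes = notes)
  }
  ybase <- c("Pol-core-Y", "LINKER", "thumb", "LINKER", "LF")
  defs <- list(
    ## A family
    g("PolA1", "A", "polymerase",
      c("FEN-exo", "LINKER", "DnaQ-exo", "LINKER", "Pol-core-A"),
      c(FEN_AS = "required", DEDDy = "typical", CAT_A = "required"),
      notes = "Pol I orthologs; canonical three-domain architecture"),
    g("PolA1-like", "A", "polymerase",
      c("DnaQ-exo", "LINKER", "Pol-core-A"),
      c(DEDDy = "typical", CAT_A = "required"),
      notes = "Pol I-like, lacking the 5'-3' exonuclease domain"),
    g("PolA2", "A", "polymerase",
      c("PAD60", "DnaQ-exo", "LINKER", "Pol-core-A"),
      c(DEDDy = "absent", CAT_A = "required", CLAMP = "required"),
      clamp_region = "exo_loop",
      notes = "Actinobacterial; vestigial proofreader with beta-clamp motif"),
    g("PolA3", "A", "polymerase",
      c("DnaQ-exo", "LINKER", "Pol-core-A"),
      c(DEDDy = "required", CAT_A = "required"),
      notes = "phage-related accessory group"),
    ## B family
    g("G1", "B", "polymerase",
      c("PolB-NT", "LINKER", "DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "required", CAT_B = "required"),
      notes = "Pol II orthologs"),
    g("G2", "B", "polymerase",
      c("PolB-NT", "LINKER", "DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "absent", CAT_B = "required"),
      notes = "PolB2-derived TLS group, dead proofreader"),
    g("G3", "B", "polymerase",
      c("PolB-NT", "LINKER", "DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "required", CAT_B = "required"),
      notes = "Pol epsilon N-half-like group"),
    g("G4", "B", "polymerase", c("DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "typical", CAT_B = "required")),
    g("G5", "B", "polymerase", c("DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "typical", CAT_B = "required")),
    g("G6", "B", "polymerase", c("DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "typical", CAT_B = "required")),
    g("G7", "B", "polymerase", c("DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "typical", CAT_B = "required")),
    g("G8", "B", "polymerase", c("DnaQ-exo", "LINKER", "Pol-core-B"),
      c(DEDDy = "typical", CAT_B = "required")),
    ## C family
    g("PolC", "C", "polymerase",
      c("PHP", "LINKER", "DnaQ-exo", "LINKER", "Pol-core-C"),
      c(PHP_AS = "required", DEDDh = "required", CAT_C = "required"),
      notes = "replicative alpha subunit with embedded DnaQ domain"),
    g("DnaE1", "C", "polymerase",
      c("PHP", "LINKER", "Pol-core-C", "LINKER", "OB", "LINKER", "CTD"),
      c(PHP_AS = "required", CAT_C = "required"),
      notes = "replicative alpha subunit, E. coli Pol III type"),
    g("DnaE3", "C", "polymerase",
      c("PHP", "LINKER", "Pol-core-C", "LINKER", "OB", "LINKER", "CTD"),
      c(PHP_AS = "absent", CAT_C = "required"),
      notes = "replicative alpha subunit co-occurring with PolC"),
    g("DnaE2A", "C", "polymerase", c("PHP", "LINKER", "Pol-core-C"),
      c(PHP_AS = "absent", CAT_C = "required"),
      notes = "error-prone; partners with ImuA and ImuB"),
    g("DnaE2B", "C", "polymerase", c("PHP", "LINKER", "Pol-core-C"),
      c(PHP_AS = "absent", CAT_C = "required"),
      notes = "error-prone; PolY/ImuB-C partnered"),
    g("DnaE2X", "C", "polymerase", c("PHP", "LINKER", "Pol-core-C"),
      c(PHP_AS = "absent", CAT_C = "required"),
      notes = "error-prone; split-ImuB partnered"),
    ## X family
    g("PolX1", "X", "polymerase",
      c("8kDa", "LINKER", "Pol-core-X", "LINKER", "PHP"),
      c(PHP_AS = "required", CAT_X = "required"),
      notes = "canonical bacterial PolX"),
    g("PolX2", "X", "polymerase", c("Pol-core-X", "LINKER", "CTD"),
      c(CAT_X = "required"),
      notes = "PHP-less group with novel C-terminal domain"),
    g("PolX-like", "X", "polymerase", c("PHP"),
      c(PHP_AS = "required"),
      notes = "PolX1 homologs lacking the entire polymerase domain"),
    ## Y family
    g("UmuC", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "RECA_SEG"),
      c(CAT_Y = "required", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "Pol V catalytic subunit type"),
    g("DinP", "Y", "polymerase", c(ybase, "LINKER"),
      c(CAT_Y = "required", RecA_NT = "absent"),
      notes = "no RecA-NT, no clamp motif"),
    g("DinX", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "Tudor"),
      c(CAT_Y = "required", RecA_NT = "absent", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "Tudor-bearing actinobacterial group"),
    g("PolY-core", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "RECA_SEG"),
      c(CAT_Y = "required", RecA_NT = "typical", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "DinB/Pol IV-like central group"),
    g("YqjW", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "RECA_SEG"),
      c(CAT_Y = "required", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "YqjW/UvrX type (PolY2)"),
    g("scDinB2-like", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "RECA_SEG"),
      c(CAT_Y = "absent", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "Streptomyces inactive PolY (iPolY)"),
    g("gbDinB2-like", "Y", "polymerase", c(ybase, "CLAMP_LINKER", "RECA_SEG"),
      c(CAT_Y = "absent", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "G. bemidjiensis-type inactive PolY"),
    g("ImuB1", "Y", "polymerase",
      c(ybase, "CLAMP_LINKER", "RECA_SEG", "ImuB-C"),
      c(CAT_Y = "absent", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "proteobacterial ImuB"),
    g("ImuB2", "Y", "polymerase",
      c(ybase, "CLAMP_LINKER", "RECA_SEG", "ImuB-C"),
      c(CAT_Y = "absent", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "actinobacterial ImuB"),
    g("ImuBx", "Y", "polymerase",
      c(ybase, "CLAMP_LINKER", "RECA_SEG", "ImuB-C"),
      c(CAT_Y = "absent", RecA_NT = "required", CLAMP = "typical"),
      clamp_region = "cterm_third", notes = "remaining ImuB-like sequences"),
    ## accessory components (not DNA polymerases)
    g(".RecA", ".", "accessory", c("RECA_SEG", "RecA-core"),
      divergence = 0.05, notes = "recombinase; mutasome scaffold"),
    g(".ImuA", ".", "accessory", c("ImuA-core"), divergence = 0.05,
      notes = "RecA homolog partnering ImuB-DnaE2"),
    g(".UmuD", ".", "accessory", c("UmuD-core"), divergence = 0.05,
      notes = "Pol V small subunit (UmuD' dimer)"),
    g(".YqjX", ".", "accessory", c("YqjX-arm", "LINKER", "YqjX-body"),
      divergence = 0.05, notes = "YqjX/YolD small subunit, full length"),
    g(".YqjX-NT", ".", "accessory", c("YqjX-arm"), divergence = 0.05,
      notes = "small subunit reduced to the N-terminal arm"),
    g(".YhjD", ".", "accessory", c("YqjX-arm", "LINKER", "YhjD-extra"),
      divergence = 0.05, notes = "arm fused to an unrelated domain"),
    g(".ImuBC-solo", ".", "accessory", c("ImuB-C"), divergence = 0.05,
      notes = "standalone ImuB-C beta-barrel protein"),
    g(".SRAP", ".", "accessory", c("SRAP-core"), divergence = 0.05,
      notes = "SOS-response associated peptidase-like partner"),
    g(".DnaQ-solo", ".", "accessory", c("DnaQ-exo"),
      c(DEDDh = "required"), divergence = 0.05,
      notes = "standalone proofreading subunit (epsilon-like)"),
    g(".DnaQ-like", ".", "accessory", c("DnaQ-exo"),
      c(DEDDh = "required"), divergence = 0.05,
      notes = "distant standalone DEDDh homolog, not a validated DnaQ"),
    g(".FEN-solo", ".", "accessory", c("FEN-exo"),
      c(FEN_AS = "required"), divergence = 0.05,
      notes = "standalone 5'-3' exonuclease complementing missing Pol I")
  )
  defs
}

# Decision table for the 11 mutasome complex types, ordered by matching
# priority (1 = most specific, matched first). Component grammar:
# tokens separated by ";"; "poly=<groups>+flags" constrains a Y-family
# member (flags: recA_NT, active, inactive, imuBC, -imuBC);
# "dnae2=<group>" a DnaE2; bare roles reca/umud/imua/imubc/srap and
# "small_subunit=<groups>" require accessory proteins.
registry_complex_defs <- function() {
  rows <- list(
    list("DnaE2X-iPolY-ImuBC-RecA", 1,
         "dnae2=DnaE2X;poly=recA_NT+inactive+-imuBC;imubc;reca", "", FALSE,
         "split-ImuB system; candidate ancestor of ImuA-ImuB-DnaE2"),
    list("ImuA-ImuB-DnaE2", 2,
         "dnae2=DnaE2A;imua;poly=ImuB1|ImuB2|ImuBx+recA_NT+inactive+imuBC",
         "", TRUE, "previously characterized mutasome"),
    list("DnaE2B-PolY-ImuBC-RecA", 3,
         "dnae2=DnaE2B;poly=recA_NT+active;imubc;reca", "", FALSE,
         "active PolY plus standalone ImuB-C"),
    list("DnaE2B-iPolY-RecA", 4,
         "dnae2=DnaE2B;poly=recA_NT+inactive+-imuBC;reca",
         "scDinB2-like,gbDinB2-like", FALSE,
         "two iPolY flavors encoded as variants of one type"),
    list("DnaE2B-PolY-RecA", 5,
         "dnae2=DnaE2B;poly=recA_NT+active;reca", "", FALSE,
         "Bacteroidetes-type system"),
    list("DnaE2B-ImuBC", 6, "dnae2=DnaE2B;imubc", "", FALSE,
         "DnaE2B with only an ImuB-C partner"),
    list("UmuC-UmuD2-RecA", 7,
         "poly=UmuC+recA_NT+active;umud;reca", "", TRUE,
         "Pol V; previously characterized mutasome"),
    list("YqjW-YqjX-RecA", 8,
         "poly=YqjW+recA_NT+active;small_subunit=.YqjX|.YqjX-NT|.YhjD;reca",
         ".YqjX,.YqjX-NT,.YhjD", FALSE,
         "three small-subunit variants linked by the N-terminal arm"),
    list("UmuC-SRAP", 9, "poly=UmuC;srap", "", FALSE,
         "UmuC-like polymerase with SRAP-like partner"),
    list("PolY-ImuBC", 10, "poly=active;imubc", "", FALSE,
         "PolY with standalone ImuB-C"),
    list("PolY-RecA", 11, "poly=recA_NT;reca", "", FALSE,
         "ancestral-type dimer; most abundant; lowest priority fallback")
  )
  data.frame(
    complex_id = vapply(rows, `[[`, "", 1),
    priority = vapply(rows, function(x) as.integer(x[[2]]), 0L),
    required_components = vapply(rows, `[[`, "", 3),
    variants = vapply(rows, `[[`, "", 4),
    known = vapply(rows, `[[`, TRUE, 5),
    notes = vapply(rows, `[[`, "", 6),
    stringsAsFactors = FALSE
  )
}

# Accessory role -> registry group(s).
complex_role_groups <- list(
  reca = ".RecA", umud = ".UmuD", imua = ".ImuA",
  imubc = ".ImuBC-solo", srap = ".SRAP"
)
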