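# polcensus

Annotation of bacterial DNA-polymerase complements.

Bacterial genomes encode DNA polymerases from five families — A, B, C, X and
Y — and the particular set a species carries (its *complement*) determines
its capacity for replication, proofreading and mutagenic lesion bypass.
`polcensus` is an R package for annotating that complement from a proteome:
it assigns each candidate protein to a family and group (PolA1–3, PolC,
DnaE1/2/3, PolX1/2, the Y-family groups UmuC, DinP, DinX, ImuB, …), calls
the active-site and interaction motifs that decide what each enzyme can do,
types the genome's replication system and proofreader arsenal, infers
multimeric error-prone ("mutasome") polymerase complexes, and computes
presence–absence enrichment statistics against environmental metadata.

The package targets comparative genomicists who want reproducible,
rule-based polymerase annotation on their own genome sets, without
re-deriving the group ontology from public databases.

## The rules at the core

* **Domain detection.** Position-specific score profiles (log-odds PSSMs in
  bits against Robinson–Robinson background frequencies) are built from
  packaged reference alignments and scanned against each protein by local
  alignment with affine gaps (open 11, extend 1). A hit is retained when its
  score reaches a fraction τ (default 0.3) of the profile's self-score;
  polymerase-core hits on proteins shorter than 200 residues are flagged as
  fragments and excluded from censuses.
* **Group assignment.** Proteins of one family are clustered with the
  registry anchors in a similarity graph (normalized global-alignment score
  ≥ 0.45); components inherit the group of their anchors, resolved by
  nearest anchor when a component spans several groups.
* **Active sites.** Exact-set motif rules: PHP `HHDHEH[C/H]DH`; DnaQ-type
  3′–5′ exonucleases `DEDDh` (C-family context) and `DEDDy` (A/B context);
  FEN-type 5′–3′ exonuclease `D[D/E]EDD`; palm catalytic carboxylates per
  family. Any deviation at a motif column — substitution, deletion, X —
  makes the site *inactive*; a protein whose alignment does not cover the
  motif is *undetermined*.
* **Interaction motifs.** β-clamp binding (`QxxLF`, searched in a
  group-specific region) and the RecA-NT oligomerization motif (profile
  score against a packaged sub-alignment).
* **Genome integration.** Replication systems are typed as DnaE1-only,
  PolC+DnaE1 or PolC+DnaE3 (DnaE2 never counts as replicative); proofreader
  censuses include intrinsic PHP/DnaQ domains plus standalone DnaQ subunits
  admitted only on close homology to validated references or a passing
  structure-model score; 5′–3′ exonuclease capacity is PolA1, solo (a
  standalone FEN protein) or none.
* **Complex typing.** An 11-type decision table (PolY–RecA, Pol V,
  YqjW–YqjX–RecA, ImuA–ImuB–DnaE2, the DnaE2B/DnaE2X systems, UmuC–SRAP,
  PolY–ImuBC) is matched in priority order against each genome's DnaE2s,
  RecA-NT-bearing Y-family members and accessory partners, with gene
  neighborhood (gene-index window 5) upgrading evidence from co-occurrence
  to colocalized.
* **Statistics.** Two-sided Fisher's exact tests on 2×2 presence–absence
  tables, with the unconditional cross-product odds ratio and a Woolf logit
  95% CI (Haldane–Anscombe correction only for zero cells).

A synthetic-data module generates proteomes with planted ground truth
(groups, motif toggles, operon layouts, cohort-level enrichment odds
ratios), so every stage is testable end-to-end without downloads. The
packaged reference alignments are deterministic synthetic constructs (see
`synthesize_registry()`), not database sequences.

## Worked example

```r
library(polcensus)
registry <- load_registry()

# a genome planted with a Pol V mutasome (UmuC + UmuD + RecA operon)
plan <- complex_plan("UmuC-UmuD2-RecA")
sim  <- simulate_genome(plan, registry, seed = 101)
cc   <- annotate_genome(sim$proteins, sim$features, registry)
cc
#> genome sim_UmuC_UmuD2_RecA: 2 polymerase(s); system DnaE1-only; exo5'-3' none; 1 complex call(s)

cc$complexes[, c("complex_id", "evidence_level")]
#>        complex_id evidence_level
#> 1 UmuC-UmuD2-RecA    colocalized

cc$proofreaders
#>                   carrier kind active
#> 1 sim_UmuC_UmuD2_RecA_p03  PHP   TRUE
```

The genome's two polymerases are the planted DnaE1 (replicative, with an
active PHP proofreading domain) and the UmuC-type Y-family polymerase; the
UmuC carries the RecA-NT motif and is typed, together with the adjacent
UmuD-like small subunit and RecA, as a Pol V (UmuC–UmuD′₂–RecA) mutasome
with operon-level (colocalized) evidence.

Enrichment of a feature between environment classes:

```r
ft <- fisher_enrichment_test(matrix(c(30, 10, 20, 40), 2, byrow = TRUE))
#> OR = 6.00, 95% CI [2.45, 14.68], p = 8.309e-05
```

## Package layout

* `R/`, `src/` — implementation (registry, I/O, profile scanner, motif
  caller, genome annotator, complex typer, statistics, simulator).
* `inst/extdata/registry/` — the packaged ontology: diffable TSV tables
  plus synthetic anchor alignments (`refs/*.synthetic.fasta`).
* `vignettes/polymerase-complements.Rmd` — the methods write-up: models,
  parameters, design decisions, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
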