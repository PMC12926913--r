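---
title: "Annotating bacterial DNA-polymerase complements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating bacterial DNA-polymerase complements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcensus)
```

## The problem

A bacterium's DNA-synthesis capacity is set by its full complement of DNA
polymerases: the replicative C-family α-subunits (DnaE1, DnaE3, PolC), the
nearly universal A-family Pol I with its two nuclease domains, the rare B-
and X-family enzymes, and the error-prone Y-family polymerases that carry
out translesion synthesis, often as parts of multi-protein "mutasome"
complexes such as Pol V (UmuC–UmuD′₂–RecA) or ImuA–ImuB–DnaE2. Annotating a
complement means answering, for every candidate protein: which family and
group is it, are its catalytic and proofreading sites intact, which
interaction motifs does it carry — and, at the genome level, which
replication system, proofreader set and mutasome complexes the species
encodes.

`polcensus` implements this as a deterministic, rule-based pipeline around
a packaged ontology (the *registry*), with a synthetic-data generator that
plants known truth so every rule is testable end-to-end.

## The registry

The registry (`load_registry()`, serialized under
`inst/extdata/registry/`) encodes:

* five families (A, B, C, X, Y) with their fold classes;
* 31 polymerase groups (PolA1/PolA1-like/PolA2/PolA3; B-family G1–G8;
  PolC, DnaE1, DnaE3, DnaE2A/B/X; PolX1/PolX2/PolX-like; the Y-family
  groups UmuC, DinP, DinX, PolY-core, YqjW, scDinB2-like, gbDinB2-like,
  ImuB1/ImuB2/ImuBx) plus 11 accessory partner groups (RecA, ImuA, UmuD,
  the three YqjX-type small subunits, standalone ImuB-C, SRAP, standalone
  DnaQ and FEN);
* 23 domain definitions with reference alignments, 11 motif definitions,
  and the decision table for the 11 mutasome complex types.

Accessory partners are not DNA polymerases; they are stored in the same
groups table with `family_id = "."` and `kind = "accessory"`, and the
"every group belongs to exactly one family" invariant is enforced for
polymerase groups. This keeps a single anchored-similarity assignment
machinery for both kinds.

**Synthetic anchors.** The reference alignments are deterministic synthetic
constructs built by `synthesize_registry()` (files are named
`*.synthetic.fasta`): each domain receives a random consensus with the
canonical motif residues planted at fixed columns, each group anchor
concatenates its domains after ~22.5% group-specific divergence from the
domain consensus (5% for accessory groups), motif columns being protected.
This gives within-group anchor identity ~95% and between-group identity
~60%, which is what the thresholds below are calibrated against. Real
database sequences could be dropped into the same registry format; results
on the packaged anchors validate the *rules*, not any particular public
sequence set.

## Domain detection and group assignment

Profiles are position-specific log-odds matrices,
`log2((w·f + c·b)/((1+c)·b))` per column, with Henikoff position-based
sequence weights `w`, pseudocount mass `c = 1`, and Robinson–Robinson
background `b`. Columns with more than 50% gaps are dropped. Scanning is
Smith–Waterman local alignment of the profile against the query (affine
gaps, open 11 / extend 1 bits, implemented in C++), and scores are
normalized by the profile's consensus self-score, so a hit's `norm_score`
is 1 for the consensus itself and cannot exceed 1 + ε.

Parameters that matter:

* `tau = 0.3` — retention threshold on `norm_score`. On the packaged
  anchors, group members at ≤30% divergence score ≈ 0.5–0.8; shuffled
  decoy sequences score ≤ ~0.15 (no hit in ≥99% of shuffles in the test
  suite's empirical null). The threshold stands in for the "reliably
  identified domain" gate of profile-search workflows; externally computed
  hit tables can be supplied to bypass the scanner entirely
  (`options$external_hits`).
* 200 residues — proteins below this length whose only polymerase-core hit
  would define them are flagged `fragment` and excluded from censuses.
* `edge_threshold = 0.45` — similarity-graph edges for group assignment
  use global-alignment scores (BLOSUM62, open 11 / extend 1) normalized by
  the self-score of the shorter sequence; 0.45 corresponds to roughly 55%
  identity. Components containing anchors of several groups are resolved
  per protein by the nearest anchor, so groups that blur into one
  component (deliberately, DnaE1 vs DnaE3) are still assigned correctly.
  When the DnaE1/DnaE3 margin is below 0.05, the PHP active-site signature
  breaks the tie (DnaE1 anchors carry an intact PHP site, DnaE3 a
  disrupted one).

## Motif calling

Exact-set motifs (PHP `HHDHEH[C/H]DH`, `DEDDh`, `DEDDy`, FEN `D[D/E]EDD`,
per-family catalytic carboxylates) are read off the query through the
gap-aware column mapping of the domain hit. The call is *active* iff every
motif column carries an allowed residue; any deviation — substitution,
deletion, or X — is *inactive*; a mapping that does not cover all motif
columns is *undetermined*. Treating X as a deviation (rather than
undetermined) follows the strict binary scheme; the flag
`x_as_undetermined` flips it.

Interaction motifs: the β-clamp motif is the pattern `QxxLF` searched in a
group-specific region — inside the vestigial exonuclease domain for PolA2
(the packaged anchor carries QSSLF at residues 120–124), the C-terminal
third for Y-family groups. The RecA-NT motif is profile-mode: a 20-column
profile from a packaged sub-alignment, present at `norm_score ≥ 0.5`.
Group-level motif prevalence is summarized as most / partial / none at
0.9/0.1 fractions.

## Genome-level rules

* **Replication system**: PolC+DnaE3 if both present, else PolC+DnaE1,
  else DnaE1-only; DnaE2 never counts. A complement with no DnaE-type
  subunit at all is a hard error — including the PolC-only case, since a
  DnaE-type subunit is universally required; this extends the stated
  "no replicase" error row to every DnaE-less combination.
* **Proofreaders**: intrinsic PHP and DnaQ domains of PolC/DnaE1/DnaE3
  are listed with their active-site status (DnaE2's PHP status is reported
  on the protein but never counted as a replicative proofreader).
  Standalone DEDDh proteins are admitted as DnaQ subunits only if their
  normalized similarity to a packaged validated reference reaches 0.5, or
  a supplied structure-model score passes the model filter — the
  conservative admission rule. The packaged registry includes a distant
  DEDDh subvariant (`.DnaQ-like`) specifically so this rejection path is
  exercised.
* **5′–3′ exonuclease**: PolA1 with an active FEN site, else a standalone
  FEN protein with an active site ("solo"), else "none".

## Complex typing

The decision table is matched in priority order from most specific
(DnaE2X–iPolY–ImuBC–RecA) to the PolY–RecA fallback. Component constraints
combine group membership, catalytic activity (iPolY = inactive), the
RecA-NT flag, and the ImuB-C domain; RecA presence is established from the
proteome scan (not assumed; `assume_recA` restores the permissive
behavior). Each Y-family or DnaE2 protein serves in at most one call —
chosen so a genome planted with a single complex type yields exactly one
call — while accessory partners (RecA, ImuB-C, …) are reusable across
calls; distinct types can and do coexist in one genome (e.g. Pol V
alongside ImuA–ImuB–DnaE2). Colocalization (all members on one contig
within a gene-index window of 5) upgrades evidence from `co-occurrence` to
`colocalized` but is not required, except under
`require_colocalization` for the DnaE2B/X partner types. The
two iPolY flavors of DnaE2B–iPolY–RecA (scDinB2-like, gbDinB2-like) and
the three YqjW-type small subunits are encoded as variants of single
types, keeping the total at 11.

Structure-model confidence scores, when supplied as a table, filter calls:
ipTM ≥ 0.65 (multimer-v2) or ≥ 0.7 (v3), complementary global score
> 0.4 when present, no clash flag.

## Statistics

Fisher's exact two-sided p sums hypergeometric probabilities of all tables
with the observed margins that are no more probable than the observed one
(with a 1 + 1e-7 relative tie guard, matching common implementations; the
test suite checks equality with a full `choose()`-based enumeration to
1e-12 for every table with N ≤ 40, and agreement with `stats::fisher.test`).
The reported odds ratio is the unconditional cross-product (ad)/(bc) — not
the conditional MLE — and the 95% CI is the Woolf logit interval with the
Haldane–Anscombe 0.5 correction applied only when a zero cell exists; this
estimator choice is recorded here because exact-test implementations
differ. No multiple-testing correction is applied by default.

Metadata harmonization: oxygen labels map facultative anaerobes to
aerobes, then majority vote with ties treated as missing. Growth
temperatures bin as psychrophile (<20 °C), mesophile [20, 45), thermophile
[45, 60), hyperthermophile (≥60) — the interior boundaries are made
half-open consistently, with 60 °C fixed on the hyperthermophile side; the
binary variable pools psychrophiles with mesophiles and hyperthermophiles
with thermophiles. Multiple temperature sources merge by a stated priority
order, first available wins, all sources weighted equally.

## The synthetic-data generator

`simulate_gene()` samples a group anchor, applies background substitutions
at `mutation_rate` *outside* motif columns, then rewrites motif columns
according to the toggles: intact = canonical residues, broken = a
disallowed residue (N) at a *central* motif position. Two deliberate
choices: motif columns are protected from background noise so active-site
truth is exactly controlled (detector sensitivity is probed separately via
mutation-rate sweeps), and the broken position is central because a
boundary column can be clipped by local alignment, which would read as
undetermined rather than inactive. Decoys are composition-preserving
shuffles of anchors — harder negatives for a profile scanner than i.i.d.
residues. `simulate_genome()` places operon members at adjacent gene
indices; `simulate_cohort()` adds metadata and links a focal feature (a
solo Y-family polymerase) to an environment class with a configured odds
ratio via `p1 = OR·odds(p0)/(1 + OR·odds(p0))`, baseline prevalence 0.3,
50/50 class split.

What the generator does *not* emulate: indel evolution, phylogenetic
correlation among genomes, domain shuffling, horizontal transfer,
fragmented assemblies beyond a simple truncation flag. Passing tests
therefore demonstrate the correctness of the rules and thresholds under
realistic substitution noise, not performance on real proteomes with
divergent architectures.

One numerical caveat worth recording: replicate simulations must not be
seeded with consecutive integers — nearby Mersenne–Twister seeds give
correlated early draws, which visibly biased a replicate ensemble during
development — so replicate seeds are drawn from a single seeded stream.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use: a 200-domain motif fixture
at mutation rates 0 and 0.1; the exhaustive 16-row replication-system
truth table; 11 single-complex genomes; all 2×2 tables with N ≤ 40 for the
exact-test oracle; 100 replicates of 400-genome cohorts for CI coverage
(planted OR 4) and type-I error (OR 1); and a 25-genome noisy cohort
(mutation rate 0.1) for end-to-end recovery. These sizes were chosen as
the smallest that make the statistical assertions meaningful.

## Known limitations

* Group assignment quality is bounded by the packaged anchors; on real
  data, users should supply registry anchors from curated references.
* The profile scanner has no E-value calibration against large databases;
  `tau` is a normalized-score gate, not a significance level.
* Phylogenetically corrected enrichment (accounting for lineage
  non-independence) is out of scope; Fisher tests treat genomes as
  independent.
* Structure prediction is not performed; model-based evidence enters only
  as user-supplied score tables filtered at fixed thresholds.
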