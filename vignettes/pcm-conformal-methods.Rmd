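---
title: "Proteochemometric affinity modeling with conformal prediction intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric affinity modeling with conformal prediction intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A proteochemometric (PCM) model predicts binding affinity (here pIC50 =
9 − log10 IC50[nM]) from a *pair-level* feature vector that concatenates a
ligand representation with a protein representation, so a single model
spans many targets and can interpolate both across chemistry and across
related proteins. Point predictions alone are of limited use for
compound prioritization; `pcmcp` therefore wraps its regressors in
inductive conformal prediction, which turns any per-instance uncertainty
heuristic into prediction intervals with a finite-sample marginal
coverage guarantee.

The package is organised as an analysis pipeline (see `analysis/01…06`):
simulate → curate → featurize → split → train → calibrate → evaluate.
Every stage is an exported function, so the numbered scripts, the test
suite and `scripts/acceptance.R` all drive the same code.

## Data model and curation

Activity records carry ChEMBL-style metadata (`standard_units`,
`confidence_score`, `activity_comment`, `potential_duplicate`). Curation
retains records with nM units, no duplicate flag, confidence 9, comment
other than "inconclusive", a parseable structure whose standardized form
(largest organic fragment, rule-based charge neutralization, canonical
SMILES) has molecular weight in [75, 800] Da and no PAINS substructure
match; replicate measurements of a (ligand, protein) pair are collapsed
by the median (even groups: mean of the two middle values) and IC50
converted to pIC50. Each removed record is attributed to the first rule
that rejects it, and the audit satisfies input = output + Σ removals for
the filtering stage; the ordering of rules can move counts between rules
but never changes the retained set, which the tests assert against an
order-free oracle. Median aggregation merges rows, so conservation is
accounted separately there (group sizes are recorded).

Charge neutralization is implemented as a small rule table (protonate
anionic O/S/N, deprotonate protonated amines) rather than a full
tautomer/protonation model; quaternary centres are left charged because
no neutral form exists. The PAINS catalog is shipped as a pinned
plain-text SMARTS table (12 patterns across the quinone, azo, hydrazone,
rhodanine, thiourea, isothiazolone, barbiturate, sulfonyl-hydrazide and
nitroso families) and validated pattern-by-pattern at load time; the
catalog is intentionally a subset expressible in OpenBabel SMARTS, which
is sufficient because the synthetic generator only injects contaminants
drawn from these families.

## Featurization

Ligands: 4096-bit ECFP6 (radius-3 circular substructures, folded,
binary) plus eight physicochemical descriptors in fixed order (MW, TPSA,
H-bond donors, H-bond acceptors, logP, heavy atoms, rotatable bonds,
ring count). Proteins: amino-acid composition (20), overlapping
dipeptide composition (400, counts/(L−1)) and
composition–transition–distribution descriptors (147): for each of seven
physicochemical attributes the residues are partitioned into three
groups (shipped table `inst/extdata/ctd_groups.tsv`); per attribute the
descriptor holds 3 group fractions, 3 adjacent-pair transition rates
(N_ij + N_ji)/(L−1), and for each group the sequence-position
percentiles (100·pos/L) of its first, 25%, 50%, 75% and last occurrence,
where the k% occurrence is the ⌈k/100·n_g⌉-th and an absent group
contributes five zeros. The pair vector is the 4096 + 8 + 567 = 4671
column concatenation; the non-fingerprint columns are standard-scaled
with parameters fitted on the training rows only (population SD;
zero-variance columns pass through unscaled). Labels are standard-scaled
the same way. The CTD implementation is checked exactly against an
independent direct-enumeration oracle in the tests.

## Splits

Three split families, all seed-reproducible record partitions:
record-level random; generic Bemis–Murcko scaffold (framework after
iterative terminal-atom removal, every atom mapped to carbon and every
bond to single, emitted as canonical SMILES; all acyclic molecules share
the reserved empty key and move as one group); and protein-held-out
(grouped by UniProt ID). Grouped splits use greedy shuffled-group
filling: groups enter training in seeded random order until the
record-count fraction is reached, so the achieved fraction deviates from
the target by at most the largest group, a bound the tests verify
against exhaustive enumeration of assignments. The conformal pipeline
carves a random 80/20 calibration set out of the training records, with
the validation set untouched.

## Models

The random forest uses the ranger backend (impurity importances,
per-tree prediction access) with the reference configuration 1000 trees,
sqrt max-features, leaf size 1; per-instance spread is the population SD
across trees, and `grid_search_rf` scores every combination of a
candidate grid on the validation split.

The feed-forward network treats each fingerprint bit as a two-category
variable with its own learned embedding (default 2 dimensions per bit —
a standard cardinality-based size for binary categories; the embedding
dimension is otherwise a free design choice). Embeddings are
concatenated with the 575 scaled continuous features and passed through
hidden layers (default 2000/1000/500) in the order linear → ReLU → batch
norm → dropout (0.25; embeddings 0.01). The output is
y_lo + σ(z)·(y_hi − y_lo) with [y_lo, y_hi] the scaled-label training
range expanded about its midpoint by a factor 1.2 — the expansion is
interpreted as symmetric about the midpoint, one of two readings of
"range multiplied by 1.2", chosen because it keeps the training labels
strictly inside the representable interval. Optimization is Adam with
decoupled weight decay 0.01 under a one-cycle learning-rate schedule
(cosine warm-up over the first 30% of steps to `lr_max`, cosine
annealing after). Epochs (20), batch size (256) and peak learning rate
(1e−2) are configuration values chosen for desk-scale convergence. The
network is implemented directly on matrix algebra in R; Monte Carlo
dropout (default 100 passes, batch norm in inference mode, dropout
active, seeded masks) supplies the per-instance spread, and with all
dropout rates at zero the passes are identical and the spread is exactly
zero by construction.

## Conformal prediction

Inductive (split) conformal regression with spread-normalized
nonconformity α = |y − ŷ| / λ, λ = spread + β (β = 0.01 guards
degenerate spreads; an exponential scaler λ = exp(spread) is available
as a configuration alternative). The interval half-width multiplier at
error level ε is the k-th smallest calibration score with
k = ⌈(1−ε)(n_cal+1)⌉ — the standard finite-sample correction; k > n_cal
yields an unbounded interval, which is reported, never clipped.
Intervals are symmetric (single absolute-residual score), calibration
pools all proteins (matching a single random calibration split), and
validity/efficiency are reported as coverage fraction and width
quartiles with unbounded intervals counted separately. The quantile rule
is verified against an exhaustive counting oracle for every n ≤ 50 and
ε ∈ {0.01, …, 0.5}, and marginal coverage is checked by simulation: at
n_cal = 90 the expected coverage of 95% intervals is
⌈0.95·91⌉/91 ≈ 95.6%.

## The synthetic-data generator

The generator defines the experimental conditions under which everything is
tested, with known ground truth:

* **Proteins** — `n_families = 4` families × 5 members; root sequences
  of 180–240 residues; members derived by per-residue substitution at
  rate 0.05, giving Binomial(L, rate) Hamming distances to the root.
* **Ligands** — a shipped template grammar of 14 topologically distinct
  ring frameworks, each with two substitution sites, crossed with 12
  acyclic substituent fragments; defaults select 10 scaffolds × 4
  R-groups (~120 unique molecules after canonical deduplication). Because
  substituents are acyclic, each product's generic Bemis–Murcko scaffold
  equals its template framework, and none can form a PAINS motif.
* **Labels** — for 1600 sampled unique pairs, the latent pIC50 mixes a
  sparse linear score over the *real* column-standardized 4671-column
  descriptors (2% of columns carry weight ~ N(0,1)) plus sparse
  protein×ligand interaction terms (5% of pairs) with per-generic-scaffold
  potency offsets carrying a `scaffold_effect = 0.25` fraction of the
  latent variance — chemical-series effects, the standard feature of real
  SAR data that makes held-out-scaffold prediction structurally harder
  than random-split prediction. The mix is affinely shifted and
  scaled so the sample has mean 6.5 and SD 1.3 — an affine
  implementation of publication bias toward actives, simpler than
  rejection sampling and sufficient for distribution-shape tests.
  Observed labels add N(0, 0.5) heterogeneous-assay noise; ~0.5 log
  units is the conventional magnitude for public IC50 data, a modeling
  choice since no quantitative noise model is prescribed. Records are
  emitted as IC50 nM = 10^(9−y).
* **Contaminants** — injected at configurable rates as *extra* records:
  wrong-unit / low-confidence / "inconclusive" / flagged-duplicate
  copies of clean records, i.i.d. replicates (median aggregation is then
  the exact correct reduction), PAINS-bearing molecules drawn from a
  shipped list matching the catalog, and out-of-MW-range molecules. By
  construction the expected post-curation record count equals the number
  of unique clean pairs for any contamination configuration, which makes
  curation exactly testable. Defaults are all-zero (clean data) so that
  the modeling experiments run on exchangeable records; curation
  experiments switch rates on explicitly.

Putting the latent function on the real descriptors (not hidden abstract
features) makes parameter-recovery experiments meaningful: the RF with
the reference configuration reaches Pearson r ≥ 0.7 on a random split at
5000 pairs. What the generator does *not* emulate: realistic medicinal
chemistry, assay-ontology structure, non-Gaussian noise, activity
cliffs, and the scale (302k records / 940 targets) of public
bioactivity corpora — so passing tests demonstrate correctness of the
machinery, not real-data performance.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen once:
conformal coverage uses the generator defaults (1600 pairs → 510
training / 90 calibration / 1000 test records) over 20 seeds with the
1000-tree RF; the split-difficulty comparison uses 1000 pairs and 250
trees over 5 seed pairs; signal recovery uses 5000 pairs with the
reference RF. FFN checks use reduced hidden sizes (e.g. 64/32/16) —
architecture width is a configuration value, and the embedding and
training mechanics under test are width-independent. Ties in scaffold
assignment are broken by the seeded shuffle; zero-variance feature
columns scale by 1; conformal β = 0.01; batch-norm ε = 1e−5; population
(not sample) SDs are used for tree spread, MC-dropout spread and both
scalers, consistently with the conformal λ.

## Known limitations

* The FFN is a reference implementation in R: correct and deterministic,
  but not fast enough for corpora beyond ~10⁴ records at full width.
* Charge neutralization is rule-based; exotic charge states pass
  through unchanged.
* The shipped PAINS catalog is a pinned subset; real-data curation at
  publication grade would substitute the full published list.
* Conformal calibration is pooled (non-Mondrian); per-target coverage
  may deviate from the marginal guarantee.
* OpenBabel and RDKit fingerprints are not bit-compatible; models and
  fingerprints must come from the same toolkit.
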