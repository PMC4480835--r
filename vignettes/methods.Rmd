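---
title: "Predicting functional effects of protein sequence variants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional effects of protein sequence variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind **vepnet** and the design
decisions that were genuinely open, in the spirit of a methods section a
maintainer can audit.

## The prediction problem

A *variant* is any single amino-acid substitution in a protein sequence,
written `R109Q` (wild-type residue, 1-based position, variant residue).
The prediction target is binary: does the substitution change the
protein's *molecular function* ("effect") or not ("neutral")? This is
deliberately not disease status — functional change is what mutagenesis
assays measure, and curated collections of such assays grade changes as
`=` (no change) or increases/decreases of function (`+` to `+++`, `-` to
`- - -`). `map_pmd_annotation()` encodes the mapping: neutral only when
every annotation of a substitution says `=`; any graded change, and any
conflicting annotation set, is an effect. Neutral evidence can also be
mined from pairs of enzymes that share an experimentally assigned EC
number at high sequence identity (`mine_ec_neutral_variants()`): aligned
mismatches between two such enzymes are very likely neutral with respect
to that shared function. The identity gate is >40% plus a positive
HSSP-value, i.e. identity above the length-dependent homology threshold
curve `480·L^(-0.32)` (L ≤ 450, else 19.5). The curve is a replaceable
function argument because several published variants of it exist.

## Homology-aware cross-validation

Performance estimates on variant data are easily inflated by homology:
two similar proteins on opposite sides of a train/test split share most
of their feature structure. The package therefore builds an undirected
graph whose vertices are proteins and whose edges are similarity hits
below an E-value threshold (default `1e-3`) *in either direction*
(symmetric closure is the conservative reading of an asymmetric hit
list), clusters it by single linkage — connected components, so any chain
of similarity merges — and assigns whole clusters to ten folds, largest
first onto the currently smallest fold, with seeded random tie order.
Large clusters are never split: a single giant cluster simply makes one
fold large, which is accepted (the rotation design keeps training sets
much larger than test sets regardless). Rotation r tests on fold r,
cross-trains on fold `(r mod 10) + 1` (a fixed convention; the choice of
which fold cross-trains is arbitrary but must be deterministic), and
trains on the remaining eight.

The built-in pairwise scorer computes global alignment percent identity
(BLOSUM62, gap open 10 / extend 0.5) and converts it to a pseudo-E-value:
pairs with ≥30% identity over ≥50 aligned residues fall below any sensible
threshold, all others above. Identity is taken over the *mean sequence
length* (PID4): a gap-excluded denominator systematically inflates the
identity of heavily gapped alignments between unrelated sequences and
links separate families. Precomputed all-versus-all search output can be
supplied instead (`read_edge_list()`), which is what one would do with a
real profile-search tool at scale.

## Networks and the balanced early-stopping protocol

Each rotation trains one feed-forward network with a single hidden layer,
sigmoid activations, and **two output units** (neutral, effect) — keeping
both classes' evidence explicit and making the score a difference of
averages rather than a single logit. Free parameters: hidden units
10–100, learning rate 0.005–0.1, momentum 0.01–0.3 (defaults 10 / 0.1 /
0.3). Optimization is mini-batch stochastic gradient descent (batch 32)
with momentum on the cross-entropy loss; weights initialize uniformly in
±1/√fan-in from the configuration seed.

Class imbalance (realistic collections run ~60:40 effect:neutral) is
handled by *balanced repetitions*: each training repetition draws a fresh
down-sample of the majority class to the minority count and makes one
pass over it. After every repetition the AUC on the cross-training fold
is recorded; training continues for at least `max_stagnant_rounds`
repetitions beyond the current best before stopping, and the returned
model is the snapshot at the best cross-training AUC. The default
patience is 150 repetitions (cap 1000): on interaction-shaped signals the
cross-training AUC shows a long plateau before the joint rule is learned,
and a patience of ten — the protocol's stated minimum — systematically
stops inside that plateau. Patience was chosen by watching cross-training
AUC trajectories, the protocol's own stopping signal.

Prediction averages the (neutral, effect) outputs over all ten members;
`score = 100·(avg_effect − avg_neutral)` ranges −100 (confident neutral)
to +100 (confident effect). The default decision threshold is −0.05 *on
the raw averaged difference* (−5 on the display scale): scores at 0
classify as effect. The reliability index is
`RI = floor(10·|avg_effect − avg_neutral|)` capped at 10, with the
user-facing digit capped at 9. A literal integer truncation of the raw
difference would collapse to {0, 1} for bounded outputs, so the flooring
of 10× the absolute difference is used — it reproduces the intended 0–10
banding. A `1e-9` guard inside the floor absorbs binary floating-point
noise at band edges (e.g. 0.7 − 0.0 stored as 0.699…97).

## Feature space

Providers are registered by name and come in three kinds: per-residue
(windowed around the variant with zero-padding plus one explicit padding
indicator per window cell — padding must be distinguishable from real
zeros), variant-pairwise (the delta features `native − variant`, one-hot
wt/var encodings, contact-potential rows and delta, the derived
effect-matrix probability), and global (composition, scaled length).
Proximity to the chain termini is its own per-residue feature,
`min(i, L−i+1)` scaled to (0, 1], preserving terminus information without
inventing residues beyond the chain. Normalization is per-column z-score
fitted **on training rows only** and reused unchanged on cross-training,
test, and production rows; padding indicators stay on their 0/1 scale.
Missing values from external profile providers exclude the affected
variant rows with a logged count — never silent imputation, since an
imputed evolutionary feature is indistinguishable from evidence.

Shipped scales: Kyte–Doolittle hydropathy, integer formal charge,
Zamyatnin side-chain volumes, molecular weights, aromatic/aliphatic
indicators. The index-scale subset is deliberately small and factual. The
contact-potential table is a **synthetic surrogate** derived from the
hydropathy scale (symmetric, more favourable for hydrophobic pairs),
mimicking the dominant additive trend of statistical contact potentials;
any user-supplied symmetric 20×20 table drops in through
`contact_potential_feature()`. One-hot wild-type/variant encoding stands
in for sequence-profile features when no alignment profiles are supplied.

## Feature selection

Greedy forward selection per network: every remaining (provider, window)
pair is evaluated by training a freshly initialized network (fresh
initialization per candidate and step, each from a derived seed, so
selection is deterministic yet no warm-start bias accrues) and scoring
the cross-training fold; the best candidate joins the set if it improves
AUC by more than the tolerance (default `1e-3`); ties break to the lowest
candidate index. The rotation's test fold is held out of the entire
procedure. Per-network selections are unioned (first-seen order, windows
distinct) and pruned by backward elimination: remove any descriptor whose
removal changes the mean test-rotation Q2 by at most the tolerance, one
fixed-order pass repeated to a fixed point. The default step budget is 25.
In the shipped tests the tolerances are raised to 0.05 (forward) / 0.02
(backward) because every candidate evaluation *retrains* a network:
repeated AUC/Q2 measurements on desk-scale fixtures jitter at the
±0.01–0.02 level, and a "no change" decision is meaningful only when the
tolerance dominates that jitter.

## Alignment-free mode and the effect matrix

Without alignment profiles, prediction falls back to a named feature
profile restricted to composition, length, wt/var identity,
contact-potential profiles and deltas, biophysical scales and deltas, and
index scales — plus one derived feature: the **effect-probability
substitution matrix**. A trained ensemble predicts all 19 substitutions
at every residue of a protein set (`saturation_predict()`); cell (wt,
var) of the matrix is then the fraction of wt→var predictions classified
effect at the decision threshold (a thresholded-class fraction — it is a
probability of a *predicted effect*, which is what the feature should
carry). Cells without support are undefined, never zero, and propagate as
missing. The source protein set is a parameter: the synthetic set in
tests, any FASTA in production. The command-line `predict` subcommand
logs a notice when it falls back to the alignment-free mode.

## Evaluation suite

"Effect" is the positive class. Per-class accuracy (precision) and
coverage (recall), F-measures, Q2 and MCC follow the standard confusion
definitions; zero denominators yield an `NA` marker rather than a silent
0, and that marker propagates (an undefined precision cannot make an
F-measure defined). ROC curves sweep the unique scores; the trapezoid
area equals the tie-corrected Mann–Whitney statistic (ties at half
credit), which the tests verify against an O(n²) pairwise oracle and an
established ROC implementation. Bootstrap errors use 1,000 sets of 50%
subsamples drawn *without replacement* (family over-representation makes
with-replacement resampling optimistic); SD is the root mean squared
deviation from the per-set mean and SE = SD/√(n−1). Multi-method triage
partitions variants into easy (all methods agree, correctly), unsolvable
(all agree, wrongly) and difficult (any disagreement); the random
baseline for a difficult subset with effect fraction `p` under an
effect-probability background `b` has the closed form
`b·p + (1−b)·(1−p)` — with a 60:40 background and the difficult-subset
class counts 15,121:7,504 this gives Q2 ≈ 0.534, which the acceptance
script recomputes by simulation.

## The synthetic generator

`synthetic_config()` defines the study conditions: 10 families × 3
proteins (lengths 80–150), members derived from a founder at a 20%
per-residue substitution rate — far above the 30%-identity homology edge
threshold within families, far below it across families, so
single-linkage clustering provably recovers the families and the fold
leakage guarantee is testable. 2,000 variants are drawn uniformly over
positions and substitutions and labeled by a planted rule expressed
through *implemented* features: effect iff the position is interior
(terminus proximity above the median) **and** |hydropathy delta| > 2
Kyte–Doolittle units. Labels flip independently at 5% noise, and
rejection sampling rebalances to 60:40 effect:neutral. Because both the
signal carriers (terminus proximity, hydropathy delta) are default
descriptors, downstream learnability is attributable to the implemented
encoding and training code, not to chance structure.

What the generator does **not** emulate: realistic evolutionary profiles,
correlated annotation errors, heterogeneous per-protein variant density,
and assay-specific label semantics. Passing the planted-signal test shows
the pipeline can learn a feature-expressible interaction through the
implemented machinery at realistic noise; it does not certify accuracy on
real mutagenesis data.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at 2,000 variants (the default
study), a 600-variant fixture for selection experiments, and a 10,000
variant independent evaluation set for reliability-curve calibration —
sizes chosen so the whole suite completes in about a minute and a half on
a single core while leaving the statistical checks well-powered. The
reliability check uses the large evaluation set and the ensemble's
averaged outputs deliberately: adjacent RI bands differ in accuracy by
~10⁻³, so per-band samples must be in the thousands before the monotone
trend resolves above single-variant granularity; per-rotation
single-network CV predictions at n = 2,000 show one-variant-sized
wobbles, which is sampling noise rather than a calibration failure.

Degenerate inputs are rejected loudly: substitutions with wt = var,
tokens off the sequence, wild-type mismatches (with row numbers),
single-class training or cross-training folds, non-finite training loss
(with a pointer at the learning rate), asymmetric contact tables, empty
prediction sets. Non-canonical residues (B, Z, X, U, O) are an error in
strict mode; lenient mode maps them to X, and variants at such positions
fail wild-type validation rather than silently encoding garbage.

## Known limitations

- The built-in alignment scorer is O(n²) pairwise global alignment —
  fine for hundreds of proteins, not for proteomes; use a real search
  tool and `read_edge_list()` at scale.
- One hidden layer and raw sigmoid outputs; no probability calibration
  beyond the reliability index.
- The effect matrix depends on the ensemble that generated it; matrices
  from small or biased protein sets carry that bias into the
  alignment-free mode.
- Evolutionary, structural and annotation features are consumed only as
  precomputed tables; the package computes none of them.
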