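---
title: "Models and methods behind phosphobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions behind them, the numerical choices that were
genuinely open, and what the test suite does and does not demonstrate.

## 1. The prediction problem

A phosphoprotein-binding domain (PPBD) recognizes a phosphorylated
serine/threonine or tyrosine together with its local sequence context.
Given a curated set of *positive* binding sites for one node of the domain
hierarchy (group, family, or single-domain cluster) the task is to score
every other candidate S/T/Y site for binding by that node. The unit of
analysis is the window `PBP(m, n)`: the central residue plus `m` upstream
and `n` downstream flanking residues, `*`-padded where the window overruns
a protein terminus. The defaults `m = n = 10` give a 21-mer — long enough
to cover the footprint of the known linear motifs (the 14-3-3
`RxRSxpSxP`-type pattern spans offsets -5..+2; SH2 selectivity sits at
+1..+4) and short enough that terminal padding stays rare. Coordinates are
1-based, matching UniProt convention. Non-standard residue letters (U, B,
Z, X, J, O) are mapped to the padding symbol so that the alphabet stays at
exactly 21 symbols, which the 231-pair encoding below requires.

## 2. Group-based similarity scoring

The base score of query `A` against positives `P_1..P_N` is

S = (1/N) · Σ_j [ Σ_i M(A_j, P_ij) ] · W_j ,

with `M` = BLOSUM62 extended by the conventional `*` row (+1 diagonal, -4
off-diagonal; taken from Biostrings and reordered to the alphabetical
21-letter alphabet) and `W_j` a per-position weight. The underlying
assumption is the group-based prediction hypothesis: peptides similar to
known binders are themselves likely binders, with positions contributing
unequally. The matrix is user-replaceable (`read_substitution_matrix()`
reads the NCBI text format); matrix optimization itself is out of scope.

When a training item is scored against a positive set that contains it,
`similarity_score()` does *not* exclude it — exclusion is the job of the
validation machinery. The one place where self-matching would actively
mislead is the weight-fitting featurization, discussed next.

## 3. Position-weight determination

Weights are learned in two stages.

**Penalized logistic regression.** Each benchmark item is featurized as
its length-K vector of per-position mean substitution scores against the
positive set, and an L1-penalized logistic regression of label on features
is fitted with glmnet (`standardize = FALSE`, since all features share the
BLOSUM scale). Two numerical choices matter here:

* *Jackknifed features for positives.* A positive item left inside its own
  positive set inflates **every** position's feature by its self-match
  `M(a, a)/N`, a label-correlated offset that makes LASSO spread weight
  over uninformative positions. The featurization therefore removes the
  item's own contribution in closed form,
  `s'_j = (N·s_j − M(A_j, A_j)) / (N − 1)`.
* *Penalty by the one-standard-error rule.* The penalty is chosen by
  internal cross-validation (AUC criterion when both classes are large,
  deviance otherwise) at `lambda.1se`, the sparsest model within one
  standard error of the best — exactly the convention glmnet recommends
  when the goal is a parsimonious, interpretable weight profile. Exact
  zeros from the penalty are preserved.

**Randomized hill climbing.** Starting weights are the all-ones vector or
the PLR coefficients, whichever scores better under the same objective
(this reconciles "PLR initializes the climb" with the guarantee that the
final AUC is at least that of the all-ones start). Because the AUC
objective is invariant to positive rescaling of `W`, the PLR start is
rescaled to the all-ones L1 norm (`Σ|W_j| = K`): the climb's move set —
add ±1 to one weight, or zero one weight — is calibrated to unit-scale
weights, and an unscaled LASSO solution (typical coefficients well below
1) would be destroyed by its own move set. Moves alternate
deterministically (mutation on odd iterations, zeroing on even); the
obvious alternative, choosing the move type at random, changes nothing
structurally and is not exposed.

The objective is the pooled-score AUC of held-out similarity scores under
stratified 10-fold cross-validation (leave-one-out below 10 positives,
signalled in the returned state; for a held-out positive the fold
features again use the closed-form self-exclusion). All fold assignments
are drawn **once** from the seed, so the objective is a deterministic
function of the weights. A single fixed partition, however, lets the
climb harvest hundreds of tiny chance improvements that are real for that
partition and spurious for any other; averaging partitions makes this
worse by refining the objective's granularity. The rule adopted instead:
the objective holds `cv_repeats = 5` fixed assignments and a proposal is
accepted only when it raises the AUC of *every* assignment. A genuine
improvement replicates across assignments; a fluctuation rarely survives
five. The test suite's parameter-recovery experiment (a single
informative position, q = 0.9, 100 positives at 1:10 imbalance, 20 seeded
runs) asserts that the informative position carries the largest absolute
weight in at least 90 % of runs under this rule.

Termination follows the printed stagnation rule — stop when the best AUC
has improved by less than 1e-5 over the last 50 iterations — plus a hard
cap (default 5000 iterations) guaranteeing termination. Accepted-move AUCs
are strictly increasing by construction; weights may go negative, as no
clamp is specified anywhere.

## 4. Pair-similarity encoding

The 231-vector expands the scalar score by unordered residue pair: with
`D_j` the number of alignments of pair `{a, b}` between the query and the
positives at position `j`,

S_ab = Σ_j D_j · M(a, b) · W_j / Σ_j D_j ,

laid out in lexicographic order of the sorted pair over the alphabetical
alphabet (`AA, AC, …, A*, CC, …, **`). Two readings of the formula were
open and are fixed here:

* the denominator is *pair-specific* (the same `D_j` as the numerator),
  the only reading under which `S_ab` is a weighted average of the
  `W_j` — giving the invariant `S_ab / M(a,b) ∈ [min W, max W]` for
  realized pairs — and under which unrealized pairs take the natural
  "no evidence" value 0;
* `D_j` counts query-versus-positive alignments only, never
  positive-versus-positive pairs.

The encoding deliberately normalizes match *frequency* away: only the
positional profile of where a pair occurs survives, not how often. On
moderately noisy motifs the downstream classifier therefore plateaus
below what the raw weighted score achieves — a structural property of the
transform worth knowing when interpreting accuracy numbers. Batch
encoding is exact, not approximate: each query's vector is a sum of
precomputed per-(symbol, position) contribution rows gathered by one
sparse indicator product, and the unit tests pin it against a brute-force
enumeration of every aligned residue pair.

## 5. The classifier and transfer learning

The network has one input layer (width 231), five fully connected ReLU
hidden layers, and an output layer of two independent sigmoid units
trained against one-hot targets with binary cross-entropy; the reported
probability is the positive-class unit. Training is plain SGD with
momentum, inverted dropout on hidden activations (training only —
inference is deterministic), and L2 regularization; all of initialization
(He), shuffling and dropout masks derive from the configuration seed, so
two runs with one seed produce bit-identical parameters. Defaults:
hidden sizes 128-64-32-16-8, dropout 0.2, learning rate 0.01, momentum
0.9, batch 64, L2 1e-4, 100 epochs; with `validation_fraction = 0.1` a
stratified slice is monitored and training stops after 20 epochs without
validation-AUC improvement, restoring the best weights. The hidden widths
are a desk-scale choice — nothing in the source material prints layer
widths — and every hyperparameter can be searched over a grid by mean
10-fold CV AUC (`hyperparameter_search()`, ties broken toward fewer
parameters). Dropout is gated on the same AUC objective as everything
else; gating it on a different metric than the other hyperparameters
would complicate the search for no clear benefit. Class weighting for the
heavy imbalance of real benchmarks (up to ~200:1) is implemented but off
by default, since the reference procedure states no balancing.

Transfer learning follows the hierarchy: a child model is initialized
from its parent's parameters and continued at a tenth of the learning
rate (`fine_tune()`); zero epochs returns a predictor identical to the
parent, and each model records its parent, so cluster → family → group
chains are inspectable. The package's transfer experiment
(`compare_transfer()`) is deliberately strict: both arms share the same
stratified folds, the same encoding (child training-fold positives with
the parent's weights), the same architecture and budget, and differ only
in initialization; the per-replicate comparison averages pooled CV-AUC
over three fold assignments because a 110-item benchmark's single 4-fold
split is dominated by assignment luck. The acceptance experiment draws
cluster benchmarks of 10 positives from the *same* moderate-adherence
family motif the parent was trained on — mirroring the practice of
clusters being subsets of family data — and asserts fine-tuning wins in
at least 70 % of 20 replicates. Where the child task is strongly
separable both arms saturate near AUC 1 and transfer shows no measurable
advantage; that regime is documented, not hidden.

## 6. Validation schemes

`cross_validate()` refits the entire pipeline — weights, encoding,
classifier — inside each training fold and pools held-out scores into one
ROC/AUC (Mann-Whitney with half-credit ties; the trapezoid under the
threshold-swept ROC equals it to machine precision, which the tests
assert). Scheme selection follows the 30-positive rule: 4/6/8/10-fold for
larger benchmarks, leave-one-out below it. For LOO the default "fast
mode" optimizes position weights once on the full benchmark and re-does
only encoding and classifier training per round — weight optimization is
the expensive stage and its leave-one-out refit rarely moves the
weights — with exact per-round refitting available via `exact_loo =
TRUE`. All negatives are used in every fold; no subsampling. Metrics with
empty denominators are reported as `NA`, never silently zero. The
end-to-end acceptance experiment runs the well-separated family benchmark
(100 positives, 1:10) through all four fold counts and asserts every AUC
at or above 0.90 with a spread of at most 0.05.

## 7. Threshold calibration

Score cutoffs are defined by empirical false-positive rates on random
background: per repeat (default 20), 10,000 windows of the node's central
classes are drawn without replacement from the background pool and
scored; the cutoff for a target FPR is the smallest observed score whose
pass fraction does not exceed the target (conservative and deterministic
under ties; a target below 1/n yields a cutoff just above the maximum, so
nothing passes); per-level cutoffs are averaged over repeats. Defaults
are high/medium/low = 2/6/10 % for pS/pT-group predictors and 4/9/15 %
for pY-group predictors, plus an `all` level that returns every
prediction with its score. Stricter levels are always subsets of looser
ones. The background is any user-supplied protein set — a real proteome
draw is a data choice, not an algorithmic one — and known positives are
not excluded from it by default, since the background is meant as
*near-negative*. The acceptance target recomputes the whole loop:
calibrate at 2 % on one synthetic proteome, score a fresh independently
generated background of 10,000 windows, and report the observed
percentage (asserted within ±0.5 points).

## 8. Co-regulation statistics

`permutation_test()` fixes the binding-domain site set and redraws the
kinase family's site set uniformly (same size) per round, recounting the
overlap. Under this null the overlap is exactly
Hypergeometric(T, m_K, n_L), which the tests exploit as a closed-form
oracle. The empirical p-value is add-one smoothed,
`(#{x' ≥ x} + 1)/(rounds + 1)`, so it is never zero and is the default —
it is the only distribution-free rule. Gaussian mode fits a normal to the
permuted overlaps and reports the continuity-corrected upper tail
`P(N(μ, σ) ≥ x − ½)` (the overlap is an integer count), warning when the
null sample's skewness reaches 0.5. Across a families grid,
`associate_families()` applies Bonferroni control by default; a raw
cutoff remains available via `adjust = "none"`. Redrawing sets rather
than shuffling a paired vector is equivalent under this marginal null and
much easier to verify; whether real data's per-site multi-family
structure should be preserved in the permutation is an open modelling
question beyond this implementation. `hypergeometric_enrichment()` is the
standard upper-tail test with fold enrichment, filtered at the caller's
alpha.

## 9. The synthetic-data generator

`motif_spec()` defines a motif as a central class plus per-offset
constraints (residue set, adherence probability q); positives sample each
constrained offset from its set with probability q and from the
background otherwise, negatives are pure background with the same central
residue, and both are de-duplicated (which can leave slightly fewer
items than requested — counts are reported, never resampled, so seeds
stay meaningful). The default background is uniform over the 20 standard
residues, which keeps analytic expectations in the tests exact; a
proteome-like frequency preset exists. Presets: a 14-3-3-like pS motif at
moderate adherence (the "realistic" family), SH2-like YxN/YxxM pY motifs,
a five-constraint q = 0.95 pS motif (`separable-family`) used where an
experiment's premise is a well-separated benchmark, and null generators.
`generate_proteome()` plants whole motif windows at recorded positions
away from termini and returns the truth table for recovery scoring; same
seed, same FASTA bytes.

What the generator does *not* emulate: real flanking-sequence
composition beyond single-residue frequencies, disorder context,
homology between training and test proteins, position-dependent
background, or curation noise in site coordinates. Green tests on
synthetic data therefore demonstrate that the machinery is correct and
internally consistent at realistic sizes and imbalances (3-100 positives,
1:4 to 1:20 here, against the 4.3-204.3 range reported for real
benchmarks), not that any particular real family reaches a particular
accuracy.

## 10. Problem sizes and runtime choices

The suite runs unit tests on windows of length 5-21 with tens of items,
and the end-to-end experiments at 100 positives / 1000 negatives (family
scale), 10 positives (cluster scale), 20 × 10,000 background windows for
calibration, and 10,000 permutation rounds — sizes chosen so the whole
suite completes on one desktop core in a few minutes while keeping every
stochastic assertion comfortably away from its boundary. The classifier
runs in plain R matrix arithmetic; at 231 input features and ≤ 1,100
items per fit, vectorized BLAS calls dominate and no compiled code is
warranted.

## 11. Known limitations

* The pair-similarity encoding discards match frequency (Section 4); on
  weak motifs the classifier can trail the raw weighted score. A richer
  encoding would leave the method described here.
* The hill climb optimizes a cross-validated objective of the *scoring*
  stage only; weights are not trained jointly with the classifier, by
  design — the pipeline is strictly staged.
* LOO fast mode shares one weight vector across rounds; for the smallest
  clusters with an unusually influential single positive, `exact_loo =
  TRUE` is the honest (slower) setting.
* Threshold calibration assumes the deployment background resembles the
  calibration background; a compositionally different proteome shifts
  realized FPRs.
* The permutation null treats sites as exchangeable and families as
  marginal; correlated multi-family annotation structure is not
  preserved.
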