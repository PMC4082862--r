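---
title: "Spectral-count biomarker discovery: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count biomarker discovery: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcregress)
```

## The problem

A fraction of high-grade premalignant cervical lesions (CIN2-3) regresses
spontaneously, and patients whose lesions would regress are currently
overtreated. One line of work asks whether the water-soluble proteins a
biopsy sheds into culture medium can predict regression ahead of time: the
supernatant is depleted of high-abundance proteins, digested, run through
LC-MS/MS, and each protein's abundance is summarized by its *spectral
count* (SPC) — the number of peptide-spectrum matches (PSMs) the search
engine assigns to it in a sample. The design is two groups (regression
versus persistence, 20 patients each in the motivating study) split into a
learning and a validation half, and the question is which proteins
discriminate the groups and how well a one- or two-protein rule classifies
held-out patients.

`spcregress` implements that entire downstream analysis as reusable,
tested components: identification filtering, count normalization, a
PLS-DA target-projection model with selectivity ratios, the
discriminating-variable (DIVA) test, nested double cross-validation,
threshold classifiers, and seeded generators of synthetic datasets with
the same structure, so every stage can be exercised without access to the
original (undeposited) raw data.

## Identification filtering

PSM exports are filtered by the conventional multistep criteria:

* **Xcorr by charge.** A PSM passes when its SEQUEST cross-correlation
  score reaches the threshold of its charge class: 1.9 (z = 2), 2.3
  (z = 3), 2.6 (z >= 4). All thresholds are inclusive, reading every rule's
  "at least" uniformly; the Xcorr boundary is taken inclusive by the same
  convention. Charge-1 PSMs, which data-dependent acquisition on z >= 2
  precursors should never produce, are gated defensively at the z = 2
  threshold.
* **Two acceptance paths.** A protein identified by two or more unique
  peptide sequences is accepted on the Xcorr gate alone. A single-peptide
  protein must additionally have a peptide of at least 7 amino acids, a
  run of at least 3 consecutive matched b- or y-ions, and at least 3
  rule-passing PSMs in one sample. This split is the package's
  `strict_paper_mode` default; turning it off applies the three extra
  rules to every PSM, a stricter generalization useful for sensitivity
  analyses.
* **"b- and y-ions".** The phrase "three consecutive b- and y-ions" is
  ambiguous; the default (`either_series`) requires the run in at least
  one series, which is the common reading of the underlying criterion, and
  `both_series` is available by configuration.
* **Occurrence counting** uses PSMs that pass the other rules, not all
  PSMs for the peptide — an identification supported three times by poor
  matches is not the kind of evidence the rule is after.
* **Group presence.** After acceptance, a protein is kept only if detected
  in at least 30% of the samples of one group, computed on *raw* counts
  (detection is a property of the data, not of the +1 offset applied
  later), with `ceiling(0.30 * group size)` as the sample threshold.

Spectral counts per protein are the number of Xcorr-passing PSMs mapped to
its accession; no shared-peptide parsimony is attempted, since nothing in
the workflow depends on a grouping algorithm. Single-peptide
identifications are flagged (`single_peptide_flag`) as pending external
sequence-database confirmation rather than confirmed in-package.

## Offset and normalization

All counts are incremented by 1 (`add_offset()`), so an undetected protein
has offset count 1 and "<= 1 versus > 1" is exactly a detection rule.
Normalization then scales each sample by the relation between its total
offset count and the mean total of its group. The published formula, taken
literally, multiplies by `sample total / group average` — which scales
deep samples *up*, the opposite of a depth correction. This is almost
certainly a transcription inversion in the source, but we do not silently
"fix" a printed formula: `normalize_spc()` offers `as_printed` (the
default, faithful to the text) and `depth_corrected` (the conventional
reading, `group average / sample total`, under which doubling a sample's
depth leaves its normalized values unchanged up to the group-average
recomputation). The group average is always computed from the samples in
the matrix at hand, so learning and validation sets normalized separately
use their own averages, matching the two-set design. We use
`depth_corrected` in our synthetic-data studies, where per-sample depth
variation is explicitly simulated.

The "group average" is taken as the mean of *sample totals* within the
group — the only reading that gives the normalization factor consistent
units.

## PLS-DA, target projection, selectivity ratio

The class is coded regression = 0, persistence = 1 and centered; the
sample x protein matrix is column mean centered (autoscaling is available
but off by default: spectral counts share a scale, and scaling would
inflate rarely-seen proteins). Components are extracted by NIPALS for a
single response (PLS1), deflating X only: for component $a$,

$$w_a \propto X_a^\top y_c,\quad t_a = X_a w_a,\quad
p_a = X_a^\top t_a / t_a^\top t_a,\quad X_{a+1} = X_a - t_a p_a^\top .$$

The fitted A-component model is collapsed to a single *target-projection*
(TP) component: $w_{TP} = b/\lVert b \rVert$ with $b$ the PLS regression
vector, $t_{TP} = X_c\, w_{TP}$, $p_{TP} = X_c^\top t_{TP}/t_{TP}^\top
t_{TP}$. With one component, TP reproduces the first PLS component up to
sign (a test asserts this numerically). The component is oriented so the
persistence group has the positive mean score, making score signs
comparable across fits.

The *selectivity ratio* of protein $i$ is the explained-to-residual
variance ratio along the TP component, signed by its loading:

$$\mathrm{SR}_i = \mathrm{sign}(p_{TP,i})\,
\frac{\lVert t_{TP}\, p_{TP,i} \rVert^2}
     {\lVert x_i - t_{TP}\, p_{TP,i} \rVert^2}.$$

A protein exactly collinear with $t_{TP}$ has zero residual variance; it
is reported as a signed infinite *sentinel* with a flag, not as some large
finite number, so downstream ranking is explicit about degenerate
separability. A constant protein gets SR 0.

## The DIVA test

The source workflow computes, for each variable, a correct classification
rate (CCR: 50% for a useless variable, 100% for complete separation) and
converts a CCR objective into an SR significance limit, but does not give
the computation — it lives in closed software. The package's
operationalization, documented as an interpretation, is chosen to realize
exactly those endpoints:

* over `n_splits` seeded stratified Monte-Carlo splits, hold out ~25% of
  each group; on the training part choose the midpoint threshold and side
  maximizing *balanced* accuracy (mean of per-group accuracies, so
  unequal groups cannot inflate the rate; ties go to the lower midpoint);
  score the held-out part with balanced accuracy;
* CCR = $100 \times \max(m, 1-m)$, $m$ the mean held-out balanced
  accuracy: chance maps to ~50 and the direction of separation is
  irrelevant.

The SR limit for an objective (e.g. 90%) is the smallest |SR| among
proteins whose CCR reaches it; a protein is significant iff |SR| >= limit,
and when nothing qualifies the limit is $+\infty$. Raising the objective
can only raise the limit and shrink the significant set. `n_splits`
defaults to 100 — at ~10 held-out samples per split this puts the Monte
Carlo standard error of a CCR near 1.5 percentage points, small against
the 90% objective — and both `n_splits` and the seed are exposed.

## Double cross-validation

Honest error for the TP classifier comes from two nested loops: the outer
loop holds out 20% of samples at a time (5 folds, every sample out once);
the inner loop, on the retained 80%, holds out 25% at a time (4 folds).
The source describes the loop geometry but not what the inner loop
optimizes; the only free hyperparameter in this chain is the number of
PLS components, so that is what the inner loop selects (grid 1-5, capped
by rank), by misclassification of the TP-score sign, ties to the smaller
A. Folds are stratified by default so the 10+10 group structure survives
5-fold splitting; the pooled CCR is computed from concatenated held-out
predictions rather than fold averages. Identical data, plan and seed give
an identical report. The supplied matrix is treated as one pool; callers
who want per-set cross-validation can pass each set separately.

## Threshold classifiers

* `roc_threshold()` picks the cutoff maximizing Youden's J over midpoints
  plus the two extremes (ties to the lower threshold). ROC analysis is
  named in the source without a criterion; J is the standard
  single-number choice, and on offset detection patterns it reproduces
  the "<= 1 versus > 1" rule. Constant variables yield a flagged
  uninformative rule rather than an arbitrary cut.
* `fit_two_node_tree()` is an exhaustive CART-style search: Gini impurity
  decrease, root ties broken by lexicographic accession then lower
  threshold, one child split on the (more profitably) impure branch, and
  a competitor ranking of all proteins by their best root decrease. Depth
  is capped at two nodes, matching the two-marker models this design can
  support; pruning and surrogate splits are out of scope.
* `logistic_rank()` fits one-protein binomial GLMs and ranks by the
  likelihood-ratio statistic against the intercept-only model. Complete
  separation is detected directly from the group-wise ranges and
  reported as a flag (such proteins rank first) instead of letting
  coefficients diverge quietly.

Thresholds for the stump and tree are meant to be applied to offset
counts, so "<= 1" reads "not detected".

## Synthetic data: what it emulates and what it does not

`generate_spc_dataset()` draws, per protein and sample, a Bernoulli
presence indicator (group-specific for planted markers, shared for
background proteins) and, when present, a count
`1 + NegBin(mu = mean x depth - 1, size = dispersion)`. The +1 shift makes
presence and detection coincide — necessary for planted presence
probabilities to mean what the printed detection patterns mean — while
preserving the configured mean. Defaults are the study conditions:
20 + 20 samples split 10/10, 163 background proteins plus two planted
markers (165 total), a strong marker at presence 0.95 vs 0.0 and a weaker
one at 0.60 vs 0.0, both with mean count 3 when present. Values the
source does not state were fixed once at realistic levels for shotgun
supernatant data: background presence 0.6 and mean count 2 (most
identifications are low-count and patchy), negative-binomial size 2
(clearly overdispersed, Poisson recoverable as the size grows), and
log-normal depth factors with sdlog 0.3 (moderate run-to-run depth
variation, and the reason both normalization modes are exercised in
tests).

The generator does *not* emulate correlated protein blocks, shared
peptides across accessions, batch or acquisition-order effects, or
abundance-dependent detection. Passing tests on this synthetic structure
therefore show that the estimators recover planted signal under
independent overdispersed noise at the study's sample sizes — not that
they would on any particular real cohort.

`generate_psm_table()` builds a deterministic battery of PSMs straddling
every filtering-rule boundary and stamps it with the accept/reject
expectation computed by an independent straight-line evaluator, so the
identification filter is tested against an oracle rather than against
itself.

## Numerical choices and degenerate inputs

Rank deficiencies during NIPALS raise errors naming the failing
component; a response orthogonal to every predictor ("no discriminative
signal") is an error, not a zero model. The infinite-SR sentinel uses a
relative residual tolerance of 1e-12; variance conservation (explained +
residual = total per protein) is asserted to 1e-8 relative. The 30%
presence threshold uses `ceiling(frac * n - 1e-9)` to keep binary
floating-point spillover from turning 3.0 into 4. Stratified folds that
would leave a single class in a training set are reshuffled with an
incremented seed, at most 10 times. All Monte-Carlo machinery runs in a
private RNG stream so library calls never perturb a caller's random
state.

## Problem sizes used by the test suite

The replicated studies in the tests use 50 replicates for the TP
sign-agreement summary, 100 replicates for the DIVA planted-marker
recovery (1 planted + 150 background proteins) and for the permuted-label
null of the double cross-validation, and `n_splits = 100` Monte-Carlo
splits per variable in DIVA. These sizes put the Monte-Carlo error of
each summary well inside the margins the assertions use while keeping the
default suite fast on a single CPU.

## Known limitations

The DIVA computation is this package's operationalization of a published
idea whose reference implementation is closed; absolute SR limits (such
as any particular numeric limit reported on the original cohort) are
properties of data that were never deposited and are not reproduced here.
Protein inference is accession-level only. The normalization follows the
printed formula or its depth-corrected inversion, not compositional
(NSAF/emPAI-style) alternatives.
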