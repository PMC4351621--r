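---
title: "Two-stage, sensitivity-first prediction of clinical drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage, sensitivity-first prediction of clinical drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exresponse)
```

## The prediction problem

Each patient contributes four functional read-outs from drug-treated tumour
explants — viability, histology, proliferation, apoptosis — and an ordinal
clinical outcome: NR (progressive disease), PR (partial response) or CR
(complete response). Two asymmetries shape the design:

* **Cost asymmetry.** Predicting NR for a patient who would respond denies
  them an effective drug; predicting response for a non-responder "only"
  causes unnecessary treatment. The model therefore privileges sensitivity
  and accepts a bounded false positive rate.
* **Ordinality.** NR < PR < CR is an ordered scale, and a linear score over
  the read-outs can carry all three decisions through two thresholds.

The package assumes the read-outs arrive pre-quantified on a shared,
bounded 0–100 score scale. That convention is an inference from the
published model — its weights sum to 1 and its thresholds (19.1, 55.14)
only make sense on a common score scale — not a documented unit; range
validation is strict by default and can be relaxed
(`strict_range = FALSE`).

## Stage 1: partial-AUC-optimal ranking

With responders R = {PR, CR} coded +1 and NR coded −1, the partial AUC up
to false positive rate $\beta$ is the pairwise ranking accuracy between the
$n_+$ responders and the set $S_\beta$ of the $j_\beta = \lfloor \beta
n_-\rfloor$ highest-scoring non-responders:

$$\mathrm{pAUC}_\beta(\mathbf{w}) = \frac{1}{n_+ j_\beta}
\sum_{i \in R}\sum_{j \in S_\beta(\mathbf{w})}
\Big(\mathbb{1}[\mathbf{w}\cdot\mathbf{x}_i > \mathbf{w}\cdot\mathbf{x}_j]
+ \tfrac12\,\mathbb{1}[\mathbf{w}\cdot\mathbf{x}_i = \mathbf{w}\cdot\mathbf{x}_j]\Big).$$

The $\tfrac12$ tie convention matches the Mann–Whitney statistic and makes
$\beta = 1$ reduce *exactly* to the trapezoidal AUC — a property the test
suite asserts on random instances against a brute-force pair-enumeration
oracle. `floor` rounding of $j_\beta$ never exceeds the FPR budget;
ranking ties among negatives are broken by input index, making $S_\beta$
deterministic.

Training minimizes the regularized pairwise hinge relaxation

$$\frac{\lambda}{2}\lVert\mathbf{w}\rVert^2 + \frac{1}{n_+ j_\beta}
\sum_{i \in R}\sum_{j \in S_\beta(\mathbf{w})}
\max\big(0,\, 1 - \mathbf{w}\cdot(\mathbf{x}_i - \mathbf{x}_j)\big)$$

by alternating minimization: fix $S_\beta$ at the current weights (the
most-violated top-$\beta$ set), solve the resulting convex ranking problem,
recompute $S_\beta$, and stop when the working set stabilizes or the
objective improvement falls below `tolerance`. A cutting-plane structural
SVM would solve the same surrogate; the alternating scheme is simpler and
its contract here is the objective and the achieved pAUC, not a particular
solver trajectory. New weights are accepted only if the full objective
(with its own recomputed $S_\beta$) improves, so the recorded objective
path is non-increasing by construction — asserted after every fit.

### Numerical choices

* **Inner solver.** The fixed-$S_\beta$ problem has four unknowns;
  `stats::optim` (BFGS) on the exact objective with an almost-everywhere
  subgradient converges reliably at this dimension, and the solver falls
  back to its start point if it fails to improve. Everything is
  deterministic: initialization is equal weights (¼ each), there are no
  stochastic restarts, so the `seed` only governs data simulation.
* **Global scale normalization.** Before optimizing, read-outs are divided
  by a single factor (the standard deviation of all training read-out
  entries). Because the factor is common to all four read-outs it cannot
  change their relative weighting, but it makes training exactly
  equivariant to a common rescaling of the inputs: rescaled data yield
  rescaled weights and an identical ranking. Weights are mapped back to
  the raw read-out scale before the model is assembled.
* **Regularization default** `lambda = 0.001`. On the normalized scale the
  margin-1 hinge already pins the magnitude of useful weight vectors, so
  the ridge term's role is to select among near-equivalent separating
  directions, not to shrink. A default of 1 visibly biases the direction
  on recoverable synthetic data (latent-weight cosine drops from ≈0.97 to
  ≈0.85 at n = 500); 0.001 keeps the tie-breaking function without the
  bias. Per-read-out standardization remains available
  (`standardize = TRUE`) but is off by default, since the read-outs share
  one scale and published weights are interpreted on it.

## Stage 1.5: the responder threshold

`fit_stage1_threshold()` returns the *smallest* cut $t_1$ whose training
FPR under "predict R iff score > t" is at most $\beta$ — the most
sensitive rule satisfying specificity $\ge 1-\beta$, mirroring a published
threshold placed "at approximately the $\beta$ false positive rate" rather
than at the class boundary. Spending the budget buys sensitivity headroom
on future data at the price of letting up to a $\beta$ fraction of
non-responders through; it also means a noiseless, perfectly separable
test set is *not* error-free under the trained rule (the frozen model, by
contrast, is exact on noiseless simulated data — see below). Candidate
cuts are midpoints between adjacent distinct scores plus guards below the
minimum and at the maximum, so a boundary never sits on an observed value
and the strict `>` semantics are stable under floating-point noise. A cut
at the maximum score always has FPR 0, so the rule is always feasible.

## Stage 2: the PR/CR threshold

Among *predicted* responders carrying a PR or CR label, $t_2$ maximizes
the accuracy of "CR iff score > t". Accuracy is piecewise constant between
adjacent distinct scores; on ties the widest optimal open interval wins
and its midpoint is returned (end intervals are clamped to width 1;
remaining ties go to the lowest interval — all deterministic). Predicted
responders whose true label is NR are excluded: they carry no PR/CR
information. Degenerate stage-2 inputs (only PR, or only CR) push the cut
past the data on the appropriate side with a warning, and the assembled
model always satisfies $t_2 > t_1$.

## The ordinal-regression baseline

`train_svor()` implements the explicit all-threshold support vector
ordinal regression: one weight vector, ordered cuts $b_1 \le b_2$
(enforced structurally by parameterizing $b_2 = b_1 + \delta^2$), and a
hinge penalty for every (patient, cut) pair on the wrong side of its
margin. It shares the learner's global normalization and ridge convention.
Its predictions are a monotone step function of the score by construction
— the ordinality invariant the tests assert. Unlike the two-stage rule it
has no sensitivity preference, which is exactly the comparison of
interest: on simulated study-shaped splits the two-stage model's test
sensitivity matches or beats the ordinal baseline's on the large majority
of seeds, while the baseline often wins on raw accuracy.

## What the simulator emulates — and what it does not

The real per-patient read-outs were never published as data (they exist
only as plots), so the generator reproduces the *structure* the analysis
assumes, not an estimated distribution:

* **`score_anchored`** (default): each patient draws a class from the
  cohort proportions, then a target composite score uniformly from that
  class's band — NR [0, 19.1], PR (19.1, 55.14], CR (55.14, 100] — and
  each read-out is the composite plus independent Gaussian assay noise
  (`noise_sd`, default 5 score units, a choice representing a realistic
  imperfect assay), clipped to [0, 100]. Because the published weights sum
  to 1 (verified numerically in the tests), the frozen model's score at
  zero noise equals the composite exactly, making `published_model()` an
  exact oracle on noiseless cohorts — the anchor for the end-to-end
  acceptance checks.
* **`latent_linear`**: read-outs uniform on $[0,100]^4$, class assigned by
  thresholding a latent linear score plus noise. This mode has a known
  ground-truth direction and is used for parameter-recovery testing.

`simulate_study_cohorts()` reproduces the published cohort geometry: 109
training patients (70 HNSCC, 39 CRC) and 55 test patients (42 HNSCC,
13 CRC), disjoint identifiers. The test-class mix uses the published
non-responder count (24 of 55); the PR:CR split among the remaining
responders (2:1) and the training mix (0.4, 0.4, 0.2) are package choices,
since neither is printed as text. Clipping at the range bounds (rather
than rejection sampling) is deterministic and leaves slight boundary mass.

None of this captures the real data's joint correlation structure between
read-outs, heteroscedastic assay error, or per-cancer-type differences —
so passing tests demonstrate the *pipeline's* correctness and its design
guarantees (e.g., training specificity ≥ 75% at β = 0.25 on every seed),
not clinical performance on real explant data.

## Degenerate inputs and edge behaviour

* Cohorts for training must contain both NR and R labels; evaluation of
  sensitivity (specificity) with no actual responders (non-responders)
  yields `NA` with a warning, never 0.
* `floor(beta * n_neg) = 0` is rejected with guidance rather than silently
  clamped.
* Scores exactly at a threshold fall in the lower class (strict `>`),
  matching the published rule's phrasing at both boundaries.
* All-tied scores produce the diagonal ROC and AUC 0.5.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at the
study's own scale: cohorts of 55–500 patients, 20-seed training sweeps at
n = 109, and 200-instance randomized oracle comparisons for the pAUC
engine — sizes chosen to match the study geometry and to exercise every
code path thoroughly, and all small enough that the full suite runs in
seconds on one CPU.

## Known limitations

* Weight-level reproduction of the published coefficients is impossible in
  principle — the 109-patient training read-outs are unpublished — so the
  learner's contract is behavioural (pAUC achieved, recovery on synthetic
  ground truth), and the published coefficients are shipped verbatim as a
  frozen model instead.
* One model serves both cancer types; no per-type submodels, no
  probability calibration, no multi-regimen ranking.
* The pAUC surrogate optimizes a lower bound; with four features and small
  cohorts the alternating scheme converges in a handful of outer
  iterations, but global optimality is not guaranteed for any fixed
  working set sequence.
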