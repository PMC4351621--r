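# exresponse

Sensitivity-first prediction of clinical response to anticancer therapy from
ex vivo tumour-explant read-outs.

## The problem

Tumour explants cultured in a patient-matched microenvironment yield four
functional measurements of drug response per patient — **viability**,
**histology**, **proliferation** and **apoptosis**, each expressed as a
unitless score on a common 0–100 scale. The clinical question is ordinal:
will the patient show no response (NR, progressive disease), a partial
response (PR) or a complete response (CR)? The clinically asymmetric cost —
denying a drug to a would-be responder is far worse than treating a
non-responder — motivates a *sensitivity-first* classifier.

`exresponse` is for biostatisticians and translational researchers who want
that prediction layer as a tested, reusable pipeline: the learning
algorithm, the frozen published model, an ordinal-regression baseline,
single-read-out baselines, evaluation metrics, and a synthetic-cohort
generator that makes every stage testable without patient data.

## The model

Stage 1 collapses PR and CR into a responder class R and learns a linear
score *s* = **w**·**x** over the four read-outs by maximizing a concave
surrogate of the **partial AUC** — the area under the ROC curve restricted
to false positive rates in [0, β], here β = 0.25:

    pAUC_β(w) = (1 / (n₊ · j_β)) Σ_{i ∈ R} Σ_{j ∈ S_β(w)} 1[ w·x_i > w·x_j ]

where j_β = ⌊β·n₋⌋ and S_β(w) is the top-β fraction of non-responders
ranked by w·x (the "most violated" negatives, structural-SVM style).
Training minimizes the regularized pairwise hinge relaxation of this
quantity, alternating between fixing S_β and solving the resulting convex
ranking problem. The responder threshold t₁ is then the most sensitive cut
whose training false positive rate stays within β — so training specificity
is ≥ 1 − β = 75% by construction.

Stage 2 refines predicted responders only: a second threshold t₂ > t₁
maximizes PR-vs-CR accuracy among them. The decision rule is strict:
s > t₂ ⇒ CR, t₁ < s ≤ t₂ ⇒ PR, s ≤ t₁ ⇒ NR.

The frozen published instance of this model —
**w** = (0.2977, 0.5562, 0.0073, 0.1388), t₁ = 19.1, t₂ = 55.14 — ships as
`published_model()`.

## Worked example

```r
library(exresponse)

sp  <- simulate_study_cohorts(seed = 42)   # 109 training / 55 test patients
fit <- train_two_stage(sp$train)
fit
#> Linear response model (two_stage_pauc, trained)
#>   weights:    viability=0.1216  histology=0.0254  proliferation=0.0711  apoptosis=-0.0096
#>   thresholds: responder > 2.844, CR > 11.6   (beta = 0.25)
#>   training: stage-1 specificity 76.74%, sensitivity 100.00%

cm <- confusion_matrix3(sp$test$clinical_response, predict(fit, sp$test))
cm
#>       predicted
#> actual NR PR CR
#>     NR 14  5  0
#>     PR  0 27  0
#>     CR  0  1  8
unlist(binary_metrics(cm))
#> sensitivity specificity   accuracy3    n_errors
#>   100.00000    73.68421    89.09091     6.00000
```

Every actual responder is predicted as a responder (sensitivity 100%): the
partial-AUC objective and the budget-spending threshold trade a few false
alarms among non-responders for never demoting a responder to NR. The
absolute threshold values differ from the published 19.1/55.14 because
learned weights are identified only up to positive scaling.

The published validation outcome is built in as an arithmetic consistency
fixture:

```r
chk <- published_validation_check()
unlist(chk$metrics)
#> sensitivity specificity   accuracy3    n_errors
#>   100.00000    91.66667    87.27273     7.00000
```

## Package tour

| Area | Functions |
| --- | --- |
| Cohort I/O and validation | `read_cohort`, `write_cohort`, `as_cohort`, `validate_cohort`, `cohort_counts` |
| Simulation | `simulate_cohort`, `simulate_study_cohorts` |
| ROC / metrics | `roc_points`, `roc_auc`, `partial_auc`, `partial_auc_bruteforce`, `confusion_matrix3`, `binary_metrics` |
| Learning | `train_svmpauc`, `most_violated_negatives`, `pauc_objective`, `fit_stage1_threshold`, `fit_stage2_threshold`, `train_two_stage` |
| Baselines | `train_svor`, `single_readout_model` |
| Models | `published_model`, `predict`/`coef`/`summary`/`plot` methods, `score_class`, `read_model`, `write_model` |
| Experiments | `run_experiment`, `report_json`, `published_validation_check` |

See `vignettes/two-stage-response-prediction.Rmd` for the methods account:
model assumptions, what the simulator does and does not emulate, numerical
choices, and known limitations.
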