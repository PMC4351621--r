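# The two-stage decision rule: a partial-AUC-trained linear score, a
# responder cut spending at most the beta FPR budget on the training set,
# and a PR/CR cut maximizing accuracy among the predicted responders.

#' Fit the two-stage response model
#'
#' Stage 1 trains the partial-AUC-maximizing linear ranker
#' ([train_svmpauc()]) on the binary responder grouping and places the
#' responder threshold with [fit_stage1_threshold()] — by construction the
#' training specificity is at least `1 - beta`. Stage 2 refines the
#' predicted responders only: their PR/CR labels feed
#' [fit_stage2_threshold()]. Predicted responders whose true label is NR
#' carry no PR/CR information and are excluded from stage 2.
#'
#' @param cohort fully labelled cohort; needs NR plus at least one
#'   responder class (a missing PR or CR class among the predicted
#'   responders yields a sentinel CR threshold with a warning).
#' @inheritParams train_svmpauc
#' @return A `response_model` (`provenance = "trained"`) whose `fit` field
#'   records the learner's objective path, the stage-1 training
#'   sensitivity/specificity, and the 3-class training confusion matrix.
#' @examples
#' cohort <- simulate_cohort(109, seed = 1)
#' fit <- train_two_stage(cohort)
#' fit
#' table(predict(fit, cohort), cohort$clinical_response)
#' @export
train_two_stage <- function(cohort, beta = 0.25, lambda = 0.001,
                            tolerance = 1e-4, max_iterations = 200L,
                            standardize = FALSE) {
  validate_cohort(cohort, require_labels = TRUE, require_both_classes = TRUE,
                  strict_range = FALSE)
  w <- train_svmpauc(cohort, beta = beta, lambda = lambda,
                     tolerance = tolerance, max_iterations = max_iterations,
                     standardize = standardize)
  assemble_two_stage(cohort, as.numeric(w), beta,
                     model_type = "two_stage_pauc",
                     fit_extra = list(objective_path = attr(w, "objective_path"),
                                      converged = attr(w, "converged"),
                                      lambda = lambda))
}

# shared by the full model and the single-read-out baselines
assemble_two_stage <- function(cohort, w, beta, model_type, fit_extra = list()) {
  scores <- drop(readout_matrix(cohort) %*% w)
  y <- responder_labels(cohort)
  t1 <- fit_stage1_threshold(scores, y, beta)
  pred_r <- scores > t1
  spec1 <- 100 * mean(scores[y < 0] <= t1)
  sens1 <- 100 * mean(scores[y > 0] > t1)
  stopifnot(spec1 >= 100 * (1 - beta))  # guaranteed by the threshold rule

  stage2 <- pred_r & cohort$clinical_response %in% c("PR", "CR")
  if (!any(stage2)) {
    warning("no labelled PR/CR cases among predicted responders; ",
            "CR threshold placed above all scores")
    t2 <- max(scores) + 1
  } else {
    t2 <- fit_stage2_threshold(scores[stage2],
                               cohort$clinical_response[stage2])
  }
  if (t2 <= t1) {
    # sentinel from a CR-only stage 2 can undershoot; keep the cuts ordered
    # strictly, just below the lowest stage-2 score
    t2 <- (t1 + min(scores[stage2])) / 2
  }
  model <- new_response_model(
    weights = w, threshold_responder = t1, threshold_cr = t2,
    beta = beta, provenance = "trained", model_type = model_type)
  pred <- predict(model, cohort)
  model$fit <- c(list(n = nrow(cohort),
                      beta = beta,
                      stage1_specificity = spec1,
                      stage1_sensitivity = sens1,
                      training_confusion =
                        confusion_matrix3(cohort$clinical_response, pred)),
                 fit_extra)
  model
}

#' Single-read-out baseline model
#'
#' Degenerate linear model with unit weight on one read-out and zeros
#' elsewhere; both thresholds are fitted by the same two-stage procedure as
#' the full model. Used to show that the learned combination outperforms
#' any one functional read-out alone.
#'
#' @param cohort fully labelled cohort.
#' @param readout one of `readout_names()`.
#' @param beta false-positive-rate budget for the responder cut.
#' @return A `response_model` with `model_type = "single_readout"`.
#' @export
single_readout_model <- function(cohort, readout, beta = 0.25) {
  if (!readout %in% readout_names()) {
    stop("unknown read-out: ", readout, " (expected one of ",
         paste(readout_names(), collapse = ", "), ")")
  }
  validate_cohort(cohort, require_labels = TRUE, require_both_classes = TRUE,
                  strict_range = FALSE)
  w <- as.numeric(readout_names() == readout)
  assemble_two_stage(cohort, w, beta, model_type = "single_readout")
}
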