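# Support vector ordinal regression baseline: the explicit all-threshold
# formulation. One weight vector w and ordered cuts b1 <= b2 minimizing
#   (lambda/2) ||w||^2 + (1/n) sum_k sum_i max(0, 1 - z_ik (w.x_i - b_k))
# with z_ik = +1 when patient i's class lies above cut k, else -1.
# Prediction: NR if w.x <= b1, PR if b1 < w.x <= b2, CR otherwise.

#' Train the support vector ordinal regression baseline
#'
#' Direct three-class ordinal model over the four read-outs; unlike the
#' two-stage rule it does not privilege sensitivity. The ordered-threshold
#' constraint `b1 <= b2` is enforced by construction (the second cut is
#' parameterized as `b1 + delta^2`), so predictions are always a monotone
#' step function of the score. Deterministic: quantile-based
#' initialization, exact objective, BFGS.
#'
#' @param cohort fully labelled cohort with all three classes present.
#' @param lambda ridge penalty on the (internally normalized) weights,
#'   default 0.001, matching the stage-1 learner's convention.
#' @param max_iterations BFGS iteration cap, default 500.
#' @return A `response_model` with `model_type = "svor"`,
#'   `threshold_responder = b1`, `threshold_cr = b2`.
#' @export
train_svor <- function(cohort, lambda = 0.001, max_iterations = 500L) {
  validate_cohort(cohort, require_labels = TRUE, strict_range = FALSE)
  lab <- cohort$clinical_response
  if (!all(response_levels() %in% lab)) {
    stop("ordinal regression needs all three classes (NR, PR, CR) present")
  }
  X <- readout_matrix(cohort)
  # same global scale normalization as the stage-1 learner: hinge margins
  # and the ridge live on a scale-free footing, thresholds are unaffected
  g <- stats::sd(as.vector(X))
  if (!is.finite(g) || g == 0) g <- 1
  X <- X / g
  n <- nrow(X)
  cls <- match(lab, response_levels())        # 1, 2, 3
  Z <- cbind(ifelse(cls > 1L, 1, -1),         # above cut 1?
             ifelse(cls > 2L, 1, -1))         # above cut 2?

  obj <- function(theta) {
    w <- theta[1:4]
    b <- c(theta[5L], theta[5L] + theta[6L]^2)
    s <- drop(X %*% w)
    h <- pmax(0, 1 - Z * (s - rep(b, each = n)))
    lambda / 2 * sum(w^2) + sum(h) / n
  }
  grad <- function(theta) {
    w <- theta[1:4]
    b <- c(theta[5L], theta[5L] + theta[6L]^2)
    s <- drop(X %*% w)
    V <- (Z * (s - rep(b, each = n)) < 1) * Z   # -z_ik on violated terms
    gw <- lambda * w - crossprod(X, rowSums(V))[, 1L] / n
    gb <- colSums(V) / n                        # d/db_k = +z_ik on violated
    c(gw, gb[1L] + gb[2L], gb[2L] * 2 * theta[6L])
  }

  w0 <- rep(0.25, 4L)
  s0 <- drop(X %*% w0)
  q <- stats::quantile(s0, c(mean(cls == 1L), mean(cls <= 2L)),
                       names = FALSE)
  theta0 <- c(w0, q[1L], sqrt(max(q[2L] - q[1L], 1e-6)))
  opt <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = max_iterations, reltol = 1e-12))
  theta <- if (opt$value <= obj(theta0)) opt$par else theta0
  b1 <- theta[5L]
  b2 <- theta[5L] + theta[6L]^2

  model <- new_response_model(
    weights = theta[1:4] / g, threshold_responder = b1, threshold_cr = b2,
    beta = 1, provenance = "trained", model_type = "svor",
    strict_thresholds = FALSE)
  pred <- predict(model, cohort)
  model$fit <- list(n = n, lambda = lambda, objective = opt$value,
                    training_confusion = confusion_matrix3(lab, pred))
  model
}
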