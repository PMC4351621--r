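# Partial-AUC-maximizing linear ranker (structural-SVM style).
#
# Surrogate objective for weights w:
#   (lambda/2) ||w||^2
#     + (1 / (n_pos * j_beta)) sum_{i in pos} sum_{j in S_beta(w)}
#         max(0, 1 - (w.x_i - w.x_j))
# where S_beta(w) is the most-violated top-beta negative set: the
# j_beta = floor(beta * n_neg) negatives ranked highest by w.x. Training
# alternates between fixing S_beta from the current w and solving the
# resulting convex pairwise-hinge problem, until S_beta stabilizes or the
# objective stops improving.

#' Most-violated top-beta negative set
#'
#' Indices of the `floor(beta * n)` negatives with the highest scores under
#' `weights`; score ties are broken by input index (lower index first).
#'
#' @param weights weight 4-vector.
#' @param negatives read-outs of the negatives: cohort rows, matrix or
#'   4-vector.
#' @param beta false-positive-rate budget in (0, 1\].
#' @return Sorted integer indices into `negatives`.
#' @export
most_violated_negatives <- function(weights, negatives, beta) {
  X <- readout_matrix(negatives)
  n <- nrow(X)
  if (n < 1L) stop("no negatives supplied")
  j <- floor(beta * n)
  if (j < 1L) stop("floor(beta * n) = 0; increase beta or supply more negatives")
  s <- drop(X %*% as.numeric(weights))
  pauc_top_negatives(s, j)
}

#' Regularized partial-AUC hinge objective
#'
#' Evaluates the training surrogate at `weights`, recomputing the
#' most-violated negative set for those weights. Always at least
#' `lambda/2 * ||w||^2`, with equality exactly when every
#' (positive, S_beta) pair has ranking margin >= 1.
#'
#' @param weights weight 4-vector.
#' @param cohort labelled cohort (NR = negative, PR/CR = positive).
#' @param beta false-positive-rate budget.
#' @param lambda ridge penalty on the weights.
#' @return Objective value (scalar).
#' @export
pauc_objective <- function(weights, cohort, beta = 0.25, lambda = 1) {
  validate_cohort(cohort, require_labels = TRUE, require_both_classes = TRUE,
                  strict_range = FALSE)
  w <- as.numeric(weights)
  y <- responder_labels(cohort)
  X <- readout_matrix(cohort)
  Xp <- X[y > 0, , drop = FALSE]
  Xn <- X[y < 0, , drop = FALSE]
  S <- most_violated_negatives(w, Xn, beta)
  D <- pair_differences(Xp, Xn[S, , drop = FALSE])
  lambda / 2 * sum(w^2) + mean(pmax(0, 1 - drop(D %*% w)))
}

# all positive-minus-negative read-out differences, one row per pair
pair_differences <- function(Xp, Xn) {
  np <- nrow(Xp)
  nn <- nrow(Xn)
  Xp[rep(seq_len(np), each = nn), , drop = FALSE] -
    Xn[rep(seq_len(nn), times = np), , drop = FALSE]
}

# convex inner problem: ridge + mean pairwise hinge over fixed pairs.
# BFGS on the exact objective with an a.e. subgradient; falls back to the
# start point if no improvement (keeps the outer loop monotone).
solve_pairwise_hinge <- function(D, w0, lambda) {
  npair <- nrow(D)
  fn <- function(w) {
    lambda / 2 * sum(w^2) + sum(pmax(0, 1 - drop(D %*% w))) / npair
  }
  gr <- function(w) {
    viol <- drop(D %*% w) < 1
    g <- lambda * w
    if (any(viol)) g <- g - colSums(D[viol, , drop = FALSE]) / npair
    g
  }
  opt <- stats::optim(w0, fn, gr, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  if (opt$value < fn(w0)) opt$par else w0
}

#' Train the partial-AUC-maximizing linear ranker
#'
#' Learns a weight vector over the four read-outs from the binary responder
#' grouping (NR vs PR/CR) by alternating minimization of the regularized
#' pairwise-hinge surrogate of the partial AUC up to false positive rate
#' `beta` (see [pauc_objective()]). Fully deterministic: initialization is
#' equal weights (1/4 each) and every step is exact.
#'
#' @param cohort labelled cohort containing both responders and
#'   non-responders.
#' @param beta false-positive-rate budget, default 0.25.
#' @param lambda ridge penalty on the (internally normalized) weights,
#'   default 0.001 — small enough to act as a tie-break among
#'   margin-equivalent directions rather than a bias toward short weights.
#' @param tolerance stop when the objective improves by less than this
#'   between outer iterations (default 1e-4).
#' @param max_iterations cap on outer iterations (default 200). Hitting it
#'   with the objective still improving sets `attr(w, "converged") = FALSE`
#'   and warns, but still returns the best weights found.
#' @param standardize divide each read-out by its training standard
#'   deviation before optimizing, mapping the weights back to the raw scale
#'   afterwards. Off by default: the read-outs already share the 0-100
#'   score scale.
#' @return Named weight 4-vector with attributes `objective_path`
#'   (objective after each outer iteration, non-increasing), `converged`,
#'   and `iterations`.
#' @export
train_svmpauc <- function(cohort, beta = 0.25, lambda = 0.001,
                          tolerance = 1e-4, max_iterations = 200L,
                          standardize = FALSE) {
  stopifnot(beta > 0, beta <= 1, lambda > 0, tolerance > 0,
            max_iterations >= 1L)
  validate_cohort(cohort, require_labels = TRUE, require_both_classes = TRUE,
                  strict_range = FALSE)
  y <- responder_labels(cohort)
  X <- readout_matrix(cohort)
  scale_sd <- rep(1, 4L)
  if (standardize) {
    scale_sd <- apply(X, 2L, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(X, 2L, scale_sd, "/")
  }
  # single global scale factor: keeps the optimization (hinge margin 1,
  # ridge penalty) equivariant to a common rescaling of all read-outs
  # without touching the weights' relative sizes
  g <- stats::sd(as.vector(X))
  if (!is.finite(g) || g == 0) g <- 1
  X <- X / g
  Xp <- X[y > 0, , drop = FALSE]
  Xn <- X[y < 0, , drop = FALSE]
  j <- floor(beta * nrow(Xn))
  if (j < 1L) stop("floor(beta * n_neg) = 0; increase beta or the cohort")

  obj_at <- function(w) {
    S <- pauc_top_negatives(drop(Xn %*% w), j)
    D <- pair_differences(Xp, Xn[S, , drop = FALSE])
    lambda / 2 * sum(w^2) + mean(pmax(0, 1 - drop(D %*% w)))
  }

  w <- rep(0.25, 4L)
  best <- obj_at(w)
  path <- best
  converged <- FALSE
  S_prev <- integer(0)
  for (it in seq_len(max_iterations)) {
    S <- pauc_top_negatives(drop(Xn %*% w), j)
    D <- pair_differences(Xp, Xn[S, , drop = FALSE])
    w_new <- solve_pairwise_hinge(D, w, lambda)
    obj_new <- obj_at(w_new)
    if (obj_new < best - .Machine$double.eps * abs(best)) {
      improvement <- best - obj_new
      w <- w_new
      best <- obj_new
      path <- c(path, best)
      if (improvement < tolerance && identical(S, S_prev)) {
        converged <- TRUE
        break
      }
    } else {
      # no descent available from the current working set: stationary
      converged <- TRUE
      break
    }
    S_prev <- S
  }
  if (!converged) {
    warning("partial-AUC training reached max_iterations without converging")
  }
  w <- w / (scale_sd * g)
  names(w) <- readout_names()
  structure(w, objective_path = path, converged = converged,
            iterations = length(path) - 1L)
}
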