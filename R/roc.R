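# ROC construction, full and partial AUC (normalized, with the top-beta
# negative set S_beta), and 3-class / binary evaluation metrics.

#' ROC curve points
#'
#' Standard ROC by sweeping a strict threshold over the distinct scores,
#' highest first. Points are sorted by false positive rate, start at (0, 0)
#' and end at (1, 1); tied scores contribute a single diagonal segment.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tied block
  tpr <- cumsum(y)[keep] / n_pos
  fpr <- cumsum(!y)[keep] / n_neg
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under ROC points
#'
#' @param roc data frame from [roc_points()].
#' @return Full AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  dx <- diff(roc$fpr)
  sum(dx * (utils::head(roc$tpr, -1L) + utils::tail(roc$tpr, -1L)) / 2)
}

new_pauc_result <- function(value, beta, j_beta, s_beta_indices,
                            n_pos, n_neg) {
  structure(list(value = value, beta = beta, j_beta = j_beta,
                 s_beta_indices = s_beta_indices,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pauc_result")
}

#' @export
print.pauc_result <- function(x, ...) {
  cat(sprintf("Partial AUC up to FPR %g: %.6f (%d positives vs top %d of %d negatives)\n",
              x$beta, x$value, x$n_pos, x$j_beta, x$n_neg))
  invisible(x)
}

pauc_top_negatives <- function(scores_neg, j_beta) {
  # ties broken by input index, lower index first
  sort(order(-scores_neg, seq_along(scores_neg))[seq_len(j_beta)])
}

check_pauc_inputs <- function(scores_pos, scores_neg, beta) {
  stopifnot(is.numeric(scores_pos), is.numeric(scores_neg),
            all(is.finite(scores_pos)), all(is.finite(scores_neg)),
            is.numeric(beta), beta > 0, beta <= 1)
  if (length(scores_pos) < 1L) stop("need at least one positive score")
  j <- as.integer(floor(beta * length(scores_neg)))
  if (j < 1L) {
    stop("floor(beta * n_neg) = 0; increase beta or supply more negatives")
  }
  j
}

#' Normalized partial AUC up to a false positive rate
#'
#' Restricts the pairwise (Mann-Whitney) AUC to the set `S_beta` of the
#' `j_beta = floor(beta * n_neg)` highest-scoring negatives and normalizes
#' by `n_pos * j_beta`, so the value lies in \[0, 1\]:
#' `value = mean over (positive, S_beta) pairs of 1(s_pos > s_neg) + 1/2 * 1(s_pos = s_neg)`.
#' At `beta = 1` this is exactly the full trapezoidal AUC. Ranking ties
#' among negatives are broken by input index (lower index enters `S_beta`
#' first).
#'
#' Computed by joint ranking (no explicit pair loop); see
#' [partial_auc_bruteforce()] for the independent pair-enumeration oracle.
#'
#' @param scores_pos scores of the positives (responders).
#' @param scores_neg scores of the negatives (non-responders).
#' @param beta false-positive-rate budget in (0, 1\].
#' @return A `pauc_result`: `value`, `beta`, `j_beta`, `s_beta_indices`
#'   (indices into `scores_neg`), `n_pos`, `n_neg`.
#' @export
partial_auc <- function(scores_pos, scores_neg, beta) {
  j <- check_pauc_inputs(scores_pos, scores_neg, beta)
  S <- pauc_top_negatives(scores_neg, j)
  s_neg <- scores_neg[S]
  n_pos <- length(scores_pos)
  # Mann-Whitney via midranks of the positives in the pooled sample
  r <- rank(c(scores_pos, s_neg), ties.method = "average")
  U <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  new_pauc_result(U / (n_pos * j), beta, j, S, n_pos, length(scores_neg))
}

#' @describeIn partial_auc Naive double-loop evaluation of the identical
#'   contract; intended as a testing oracle.
#' @export
partial_auc_bruteforce <- function(scores_pos, scores_neg, beta) {
  j <- check_pauc_inputs(scores_pos, scores_neg, beta)
  S <- pauc_top_negatives(scores_neg, j)
  total <- 0
  for (si in scores_pos) {
    for (sj in scores_neg[S]) {
      total <- total + (si > sj) + 0.5 * (si == sj)
    }
  }
  new_pauc_result(total / (length(scores_pos) * j), beta, j, S,
                  length(scores_pos), length(scores_neg))
}

#' 3x3 confusion matrix over the ordered response categories
#'
#' @param actual,predicted label vectors over \{NR, PR, CR\}, equal length.
#' @return Integer matrix indexed \[actual, predicted\] with NR, PR, CR in
#'   order, class `"confusion_matrix3"`.
#' @export
confusion_matrix3 <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have the same length")
  }
  bad <- !c(actual, predicted) %in% response_levels()
  if (any(bad)) {
    stop("unknown label(s): ",
         paste(unique(c(actual, predicted)[bad]), collapse = ", "))
  }
  m <- table(actual = factor(actual, levels = response_levels()),
             predicted = factor(predicted, levels = response_levels()))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_matrix3", "matrix"))
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Binary and 3-class metrics from a confusion matrix
#'
#' Collapses PR and CR into the responder category R:
#' sensitivity = responders predicted PR or CR / actual responders;
#' specificity = NR predicted NR / actual NR;
#' `accuracy3` = 3-class trace / total; `n_errors` = total - trace.
#' Rates are reported in percent. A rate whose denominator is zero is
#' returned as `NA` (undefined, never 0) with a warning.
#'
#' @param cm a `confusion_matrix3`.
#' @return List with `sensitivity`, `specificity`, `accuracy3` (percent)
#'   and `n_errors` (count).
#' @export
binary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix3"))
  total <- sum(cm)
  if (total < 1L) stop("empty confusion matrix")
  resp <- c("PR", "CR")
  n_resp <- sum(cm[resp, ])
  n_nr <- sum(cm["NR", ])
  sens <- if (n_resp == 0L) {
    warning("no actual responders: sensitivity undefined")
    NA_real_
  } else 100 * sum(cm[resp, resp]) / n_resp
  spec <- if (n_nr == 0L) {
    warning("no actual non-responders: specificity undefined")
    NA_real_
  } else 100 * cm["NR", "NR"] / n_nr
  list(sensitivity = sens,
       specificity = spec,
       accuracy3 = 100 * sum(diag(cm)) / total,
       n_errors = as.integer(total - sum(diag(cm))))
}
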