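# Decision-threshold selection for the two-stage rule. Candidate cuts are
# midpoints between adjacent distinct scores (plus guards), so boundaries
# never sit on observed values and the strict ">" semantics stay stable
# under floating-point noise.

#' Stage-1 responder threshold under a false-positive-rate budget
#'
#' Returns the smallest threshold `t` for which the training false positive
#' rate of the rule "predict responder iff score > t" does not exceed
#' `beta` — equivalently, the most sensitive cut satisfying specificity
#' >= 1 - beta. Always feasible: a cut at the maximum score has zero FPR.
#'
#' @param scores numeric model scores.
#' @param labels logical or +/-1 or 0/1 vector; positive = responder.
#' @param beta allowed false positive rate in \[0, 1\].
#' @return The selected threshold.
#' @export
fit_stage1_threshold <- function(scores, labels, beta) {
  pos <- as.logical(labels > 0 | labels == TRUE)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)),
            beta >= 0, beta <= 1)
  if (!any(pos) || all(pos)) {
    stop("need both responders and non-responders to place the threshold")
  }
  neg_scores <- scores[!pos]
  cand <- threshold_candidates(scores)
  fpr <- vapply(cand, function(t) mean(neg_scores > t), numeric(1))
  min(cand[fpr <= beta])
}

# midpoints between adjacent distinct scores plus below-min / at-max guards
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  mid <- if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2 else numeric(0)
  c(s[1L] - 1, mid, s[length(s)])
}

#' Stage-2 PR/CR threshold by training accuracy
#'
#' Among patients carrying a PR or CR label, selects the threshold `t`
#' maximizing the accuracy of "predict CR iff score > t". Accuracy is
#' piecewise constant between adjacent distinct scores; when several
#' intervals tie, the widest optimal open interval wins and its midpoint is
#' returned (unbounded end intervals are clamped to width 1; remaining ties
#' go to the lowest interval). With only one label present the cut is
#' pushed past the data on the appropriate side, with a warning.
#'
#' @param scores numeric model scores of the (predicted) responders.
#' @param labels character vector over \{"PR", "CR"\}.
#' @return The selected threshold.
#' @export
fit_stage2_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!all(labels %in% c("PR", "CR"))) {
    stop("stage-2 labels must be PR or CR")
  }
  is_cr <- labels == "CR"
  if (!any(is_cr)) {
    warning("no CR cases among predicted responders; ",
            "CR threshold placed above all scores")
    return(max(scores) + 1)
  }
  if (all(is_cr)) {
    warning("no PR cases among predicted responders; ",
            "CR threshold placed below all scores")
    return(min(scores) - 1)
  }
  s <- sort(unique(scores))
  # open candidate intervals, left to right; ends clamped to width 1
  lo <- c(s[1L] - 1, s)
  hi <- c(s, s[length(s)] + 1)
  acc <- vapply(lo, function(t) mean((scores > t) == is_cr), numeric(1))
  best <- which(acc == max(acc))
  widths <- (hi - lo)[best]
  pick <- best[which.max(widths)]  # widest; first (lowest) on width ties
  (lo[pick] + hi[pick]) / 2
}
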