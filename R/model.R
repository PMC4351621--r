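# Linear response models: a weight vector over the four read-outs plus two
# ordered decision thresholds (responder cut, CR cut).

new_response_model <- function(weights, threshold_responder, threshold_cr,
                               beta, provenance = c("trained", "published"),
                               model_type = "two_stage_pauc", fit = NULL,
                               strict_thresholds = TRUE) {
  provenance <- match.arg(provenance)
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 4L, all(is.finite(weights)))
  if (all(weights == 0)) stop("model needs at least one nonzero weight")
  names(weights) <- readout_names()
  stopifnot(is.finite(threshold_responder), is.finite(threshold_cr),
            is.numeric(beta), beta > 0, beta <= 1)
  if (strict_thresholds && threshold_cr <= threshold_responder) {
    stop("threshold_cr must exceed threshold_responder")
  }
  if (threshold_cr < threshold_responder) {
    stop("thresholds out of order")
  }
  structure(list(weights = weights,
                 threshold_responder = threshold_responder,
                 threshold_cr = threshold_cr,
                 beta = beta,
                 provenance = provenance,
                 model_type = model_type,
                 fit = fit),
            class = "response_model")
}

#' The frozen published prediction model
#'
#' The exact coefficients and thresholds of the published two-stage model:
#' weights 0.2977, 0.5562, 0.0073 and 0.1388 on viability, histology,
#' proliferation and apoptosis, responder threshold 19.1 (scores strictly
#' above predict response) and CR threshold 55.14 (scores strictly above
#' predict complete response), trained at false-positive-rate budget
#' `beta = 0.25`.
#'
#' @return A `response_model` with `provenance = "published"`.
#' @examples
#' m <- published_model()
#' predict(m, c(50, 50, 50, 50))           # class call
#' predict(m, c(50, 50, 50, 50), type = "score")
#' @export
published_model <- function() {
  new_response_model(
    weights = c(viability = 0.2977, histology = 0.5562,
                proliferation = 0.0073, apoptosis = 0.1388),
    threshold_responder = 19.1,
    threshold_cr = 55.14,
    beta = 0.25,
    provenance = "published")
}

#' Predict response scores or classes
#'
#' The model score is the dot product of the weight vector with the four
#' read-outs in canonical order. Classes follow the strict decision rule:
#' score > `threshold_cr` is CR, score > `threshold_responder` (but not
#' above the CR cut) is PR, anything else is NR — so a score exactly at a
#' threshold falls in the lower class.
#'
#' @param object a `response_model`.
#' @param newdata a cohort, a numeric matrix with 4 read-out columns, or a
#'   single read-out vector of length 4.
#' @param type `"class"` (default) or `"score"`.
#' @param ... unused.
#' @return Character vector of NR/PR/CR calls, or numeric scores.
#' @export
predict.response_model <- function(object, newdata,
                                   type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- readout_matrix(newdata)
  s <- drop(X %*% object$weights)
  if (type == "score") return(unname(s))
  score_class(object, s)
}

#' Classify already-computed model scores
#'
#' Applies the strict two-threshold rule directly to numeric scores:
#' score > `threshold_cr` is CR, score > `threshold_responder` is PR,
#' otherwise NR. A score exactly at a threshold falls in the lower class.
#'
#' @param model a `response_model`.
#' @param scores numeric scores.
#' @return Character vector over NR/PR/CR.
#' @export
score_class <- function(model, scores) {
  stopifnot(inherits(model, "response_model"), is.numeric(scores))
  unname(ifelse(scores > model$threshold_cr, "CR",
                ifelse(scores > model$threshold_responder, "PR", "NR")))
}

#' @export
coef.response_model <- function(object, ...) {
  c(object$weights,
    threshold_responder = object$threshold_responder,
    threshold_cr = object$threshold_cr)
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Linear response model (%s, %s)\n", x$model_type, x$provenance))
  cat("  weights:   ",
      paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = "  "),
      "\n")
  cat(sprintf("  thresholds: responder > %.4g, CR > %.4g   (beta = %g)\n",
              x$threshold_responder, x$threshold_cr, x$beta))
  if (!is.null(x$fit) && !is.null(x$fit$stage1_specificity)) {
    cat(sprintf("  training: stage-1 specificity %.2f%%, sensitivity %.2f%%\n",
                x$fit$stage1_specificity, x$fit$stage1_sensitivity))
  }
  invisible(x)
}

#' @export
summary.response_model <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    f <- object$fit
    if (!is.null(f$objective_path)) {
      cat(sprintf("  optimizer: %d outer iteration(s), objective %.6g -> %.6g%s\n",
                  length(f$objective_path), f$objective_path[1L],
                  f$objective_path[length(f$objective_path)],
                  if (isFALSE(f$converged)) " (NOT converged)" else ""))
    }
    if (!is.null(f$training_confusion)) {
      cat("  training confusion matrix:\n")
      print(f$training_confusion)
    }
  }
  invisible(object)
}

#' Plot the training or evaluation ROC of a model
#'
#' Draws the ROC of the model's scores on a labelled cohort (responders vs
#' non-responders), shading the partial-AUC region up to the model's
#' false-positive-rate budget `beta`.
#'
#' @param x a `response_model`.
#' @param cohort a labelled cohort.
#' @param ... passed to [graphics::plot()].
#' @return The ROC points, invisibly.
#' @export
plot.response_model <- function(x, cohort, ...) {
  validate_cohort(cohort, require_labels = TRUE, require_both_classes = TRUE,
                  strict_range = FALSE)
  s <- predict(x, cohort, type = "score")
  y <- responder_labels(cohort)
  pts <- roc_points(s, y > 0)
  graphics::plot(pts$fpr, pts$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(v = x$beta, lty = 2, col = "grey40")
  graphics::abline(0, 1, lty = 3, col = "grey70")
  invisible(pts)
}

#' Serialize / deserialize a response model
#'
#' JSON document with keys `weights` (object keyed by read-out name),
#' `threshold_responder`, `threshold_cr`, `beta`, `provenance` and
#' `model_type`. The round-trip is lossless (full double precision).
#'
#' @param model a `response_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reloaded `response_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "response_model"))
  doc <- list(weights = as.list(model$weights),
              threshold_responder = model$threshold_responder,
              threshold_cr = model$threshold_cr,
              beta = model$beta,
              provenance = model$provenance,
              model_type = model$model_type)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("weights", "threshold_responder", "threshold_cr", "beta",
            "provenance")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0L) {
    stop("model file is missing field(s): ", paste(miss, collapse = ", "))
  }
  w <- unlist(doc$weights)
  miss_w <- setdiff(readout_names(), names(w))
  if (length(miss_w) > 0L) {
    stop("model file weights missing read-out(s): ",
         paste(miss_w, collapse = ", "))
  }
  new_response_model(weights = w[readout_names()],
                     threshold_responder = doc$threshold_responder,
                     threshold_cr = doc$threshold_cr,
                     beta = doc$beta,
                     provenance = doc$provenance,
                     model_type = if (is.null(doc$model_type)) "two_stage_pauc"
                                  else doc$model_type,
                     strict_thresholds = FALSE)
}
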