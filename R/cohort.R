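# Patient cohorts: one row per patient, four functional read-outs on a
# common 0-100 score scale, an ordinal clinical response in {NR, PR, CR}.

#' Canonical read-out names, in model weight order
#'
#' The four ex vivo functional read-outs, in the order the linear model's
#' weight vector indexes them: tumour cell viability, histopathology,
#' proliferation, apoptosis.
#'
#' @return Character vector of length 4.
#' @export
readout_names <- function() {
  c("viability", "histology", "proliferation", "apoptosis")
}

#' Ordered clinical response categories
#'
#' Non-response (progressive disease), partial response, complete response.
#' The responder grouping R = \{PR, CR\} used by the stage-1 binary model is
#' always derived on the fly, never stored.
#'
#' @return Character vector `c("NR", "PR", "CR")`.
#' @export
response_levels <- function() {
  c("NR", "PR", "CR")
}

cancer_types <- function() c("HNSCC", "CRC")

cohort_columns <- function() {
  c("patient_id", "cancer_type", "regimen", readout_names(),
    "clinical_response")
}

#' Build a validated cohort from a data frame
#'
#' A cohort is a plain `data.frame` (class `"cohort"`) with columns
#' `patient_id`, `cancer_type`, `regimen`, the four read-outs, and
#' `clinical_response` (`NA` allowed only when `allow_unlabelled = TRUE`).
#' Read-outs are unitless scores expected to live on a common 0-100 scale;
#' values outside it are rejected unless `strict_range = FALSE`.
#'
#' @param x data frame with the cohort columns (extra columns are dropped).
#' @param allow_unlabelled keep rows with no clinical label (prediction-only
#'   cohorts).
#' @param strict_range reject read-outs outside \[0, 100\].
#' @return The validated cohort.
#' @export
as_cohort <- function(x, allow_unlabelled = FALSE, strict_range = TRUE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(x)[cohort_columns()]
  out$patient_id <- as.character(out$patient_id)
  out$cancer_type <- toupper(trimws(as.character(out$cancer_type)))
  out$regimen <- as.character(out$regimen)
  for (rd in readout_names()) out[[rd]] <- as.numeric(out[[rd]])
  lab <- toupper(trimws(as.character(out$clinical_response)))
  lab[!is.na(lab) & lab == ""] <- NA_character_
  out$clinical_response <- lab
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  validate_cohort(out, require_labels = !allow_unlabelled,
                  strict_range = strict_range)
}

#' Validate cohort invariants
#'
#' Checks identifiers (non-empty, unique), cancer types, read-out ranges and
#' label vocabulary; returns the cohort unchanged when all invariants hold.
#' Idempotent.
#'
#' @param cohort a cohort data frame.
#' @param require_labels error on any unlabelled record.
#' @param require_both_classes error unless the cohort contains at least one
#'   labelled non-responder and one labelled responder (PR or CR) — the
#'   precondition for any training or evaluation use.
#' @param strict_range reject read-outs outside \[0, 100\] (finiteness is
#'   always required).
#' @return `cohort`, invisibly validated.
#' @export
validate_cohort <- function(cohort, require_labels = FALSE,
                            require_both_classes = FALSE,
                            strict_range = TRUE) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) > 0L) {
    if (anyNA(cohort$patient_id) || any(!nzchar(cohort$patient_id))) {
      stop("patient_id must be non-empty")
    }
    if (anyDuplicated(cohort$patient_id)) {
      dup <- cohort$patient_id[duplicated(cohort$patient_id)][1L]
      stop("duplicate patient_id: ", dup)
    }
    bad_type <- !cohort$cancer_type %in% cancer_types()
    if (any(bad_type)) {
      stop("unknown cancer_type in row(s) ",
           paste(which(bad_type), collapse = ", "),
           " (expected HNSCC or CRC)")
    }
    X <- as.matrix(cohort[readout_names()])
    if (!all(is.finite(X))) {
      stop("non-finite read-out in row(s) ",
           paste(which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0),
                 collapse = ", "))
    }
    if (strict_range && (any(X < 0) || any(X > 100))) {
      bad <- which(apply(X < 0 | X > 100, 1L, any))
      stop("read-out outside [0, 100] in row(s) ",
           paste(bad, collapse = ", "),
           "; pass strict_range = FALSE to accept")
    }
    lab <- cohort$clinical_response
    known <- is.na(lab) | lab %in% response_levels()
    if (!all(known)) {
      stop("unknown clinical_response in row(s) ",
           paste(which(!known), collapse = ", "),
           " (expected NR, PR or CR)")
    }
    if (require_labels && anyNA(lab)) {
      stop("unlabelled record(s) in row(s) ",
           paste(which(is.na(lab)), collapse = ", "))
    }
  }
  if (require_both_classes) {
    cc <- cohort_counts(cohort)
    if (cc$n_pos < 1L || cc$n_neg < 1L) {
      stop("degenerate cohort: need at least one labelled non-responder ",
           "and one labelled responder (PR or CR)")
    }
  }
  invisible(cohort)
}

#' Label bookkeeping for a cohort
#'
#' @param cohort a cohort data frame.
#' @return List with `n`, `n_pos` (labelled PR or CR), `n_neg` (labelled NR)
#'   and `n_unlabelled`.
#' @export
cohort_counts <- function(cohort) {
  lab <- cohort$clinical_response
  list(n = nrow(cohort),
       n_pos = sum(lab %in% c("PR", "CR")),
       n_neg = sum(lab %in% "NR"),
       n_unlabelled = sum(is.na(lab)))
}

#' @export
print.cohort <- function(x, ...) {
  cc <- cohort_counts(x)
  cat(sprintf("Patient cohort: %d records (%d NR, %d responders, %d unlabelled)\n",
              cc$n, cc$n_neg, cc$n_pos, cc$n_unlabelled))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Comma-separated, UTF-8, header exactly
#' `patient_id,cancer_type,regimen,viability,histology,proliferation,apoptosis,clinical_response`.
#' The last column may be empty (unlabelled). Labels are parsed
#' case-insensitively. Row order is preserved.
#'
#' @param path file path.
#' @inheritParams as_cohort
#' @return A validated cohort.
#' @export
read_cohort <- function(path, allow_unlabelled = FALSE, strict_range = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  if (!identical(names(raw), cohort_columns())) {
    stop("cohort file header must be exactly: ",
         paste(cohort_columns(), collapse = ","))
  }
  for (rd in readout_names()) {
    num <- suppressWarnings(as.numeric(raw[[rd]]))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s value %s in row %d",
                   rd, dQuote(raw[[rd]][bad[1L]]), bad[1L]))
    }
    raw[[rd]] <- num
  }
  as_cohort(raw, allow_unlabelled = allow_unlabelled,
            strict_range = strict_range)
}

#' Write a cohort to delimited text
#'
#' Read-outs are rendered with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param cohort a validated cohort.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, strict_range = FALSE)
  out <- as.data.frame(cohort)
  for (rd in readout_names()) out[[rd]] <- sprintf("%.17g", out[[rd]])
  out$clinical_response[is.na(out$clinical_response)] <- ""
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                             fileEncoding = "UTF-8"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write cohort file: ", path)
  invisible(path)
}

# read-out matrix in canonical column order
readout_matrix <- function(x) {
  if (is.data.frame(x)) {
    as.matrix(x[readout_names()])
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 4L)
    colnames(x) <- readout_names()
    x
  } else if (is.numeric(x) && length(x) == 4L) {
    matrix(x, nrow = 1L, dimnames = list(NULL, readout_names()))
  } else {
    stop("cannot interpret read-outs: need a cohort, 4-column matrix or ",
         "numeric vector of length 4")
  }
}

# binary responder labels (+1 R, -1 NR) for labelled rows
responder_labels <- function(cohort) {
  lab <- cohort$clinical_response
  ifelse(lab %in% c("PR", "CR"), 1L, ifelse(lab %in% "NR", -1L, NA_integer_))
}
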