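# Synthetic patient cohorts. Two generative modes:
#   score_anchored — each patient gets a target composite score drawn
#     uniformly from their class's score band (NR [0,19.1], PR (19.1,55.14],
#     CR (55.14,100]); each read-out is that score plus Gaussian assay noise,
#     clipped to [0,100]. Because the published weights sum to 1, the frozen
#     model recovers the composite exactly at zero noise, which makes it an
#     exact classification oracle for noiseless cohorts.
#   latent_linear — read-outs are drawn uniformly on [0,100]^4, a latent
#     score true_weights . x + noise is thresholded into the three classes;
#     used for parameter-recovery tests of the learner.

class_score_bands <- function() {
  m <- published_model()
  rbind(NR = c(0, m$threshold_responder),
        PR = c(m$threshold_responder, m$threshold_cr),
        CR = c(m$threshold_cr, 100))
}

#' Simulate a labelled patient cohort
#'
#' Deterministic given `seed`. See the package vignette for what the two
#' modes emulate and what they deliberately leave out (the real read-outs'
#' joint distribution is unknown).
#'
#' @param n_total number of patients.
#' @param class_proportions probabilities of (NR, PR, CR); must sum to 1.
#' @param cancer_mix probabilities of (HNSCC, CRC). Default mirrors the
#'   70:39 mix of the published training cohort.
#' @param mode `"score_anchored"` (default) or `"latent_linear"`.
#' @param noise_sd per-read-out Gaussian noise, in score units. Default 5:
#'   overlap comparable to a realistic imperfect assay.
#' @param true_weights latent-mode weight 4-vector (required in
#'   `latent_linear` mode).
#' @param latent_thresholds latent-mode class cut points, strictly
#'   increasing pair (required in `latent_linear` mode).
#' @param seed integer RNG seed (required).
#' @param id_prefix prefix for generated patient identifiers.
#' @return A validated, fully labelled cohort.
#' @export
simulate_cohort <- function(n_total,
                            class_proportions = c(0.4, 0.4, 0.2),
                            cancer_mix = c(70, 39) / 109,
                            mode = c("score_anchored", "latent_linear"),
                            noise_sd = 5,
                            true_weights = NULL,
                            latent_thresholds = NULL,
                            seed,
                            id_prefix = "P") {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  check_sim_config(n_total, class_proportions, cancer_mix, mode, noise_sd,
                   true_weights, latent_thresholds)
  withr::with_seed(seed, {
    cancer <- sample(cancer_types(), n_total, replace = TRUE,
                     prob = cancer_mix)
    simulate_records(n_total, class_proportions, cancer, mode, noise_sd,
                     true_weights, latent_thresholds, id_prefix)
  })
}

check_sim_config <- function(n_total, class_proportions, cancer_mix, mode,
                             noise_sd, true_weights, latent_thresholds) {
  stopifnot(n_total >= 1, length(class_proportions) == 3L,
            all(class_proportions >= 0),
            length(cancer_mix) == 2L, all(cancer_mix >= 0),
            is.numeric(noise_sd), noise_sd >= 0)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (mode == "latent_linear") {
    if (is.null(true_weights) || is.null(latent_thresholds)) {
      stop("latent_linear mode requires true_weights and latent_thresholds")
    }
    stopifnot(length(true_weights) == 4L, all(is.finite(true_weights)),
              length(latent_thresholds) == 2L)
    if (!(latent_thresholds[1L] < latent_thresholds[2L])) {
      stop("latent_thresholds must be strictly increasing")
    }
  }
  invisible(TRUE)
}

# RNG-consuming core; callers own the seed
simulate_records <- function(n, class_proportions, cancer, mode, noise_sd,
                             true_weights, latent_thresholds, id_prefix) {
  if (mode == "score_anchored") {
    bands <- class_score_bands()
    lab <- sample(response_levels(), n, replace = TRUE,
                  prob = class_proportions)
    s <- stats::runif(n, bands[lab, 1L], bands[lab, 2L])
    X <- s + matrix(stats::rnorm(n * 4L, 0, noise_sd), n, 4L)
    X <- pmin(pmax(X, 0), 100)
  } else {
    X <- matrix(stats::runif(n * 4L, 0, 100), n, 4L)
    latent <- drop(X %*% as.numeric(true_weights)) +
      stats::rnorm(n, 0, noise_sd)
    lab <- ifelse(latent > latent_thresholds[2L], "CR",
                  ifelse(latent > latent_thresholds[1L], "PR", "NR"))
  }
  colnames(X) <- readout_names()
  regimen <- ifelse(cancer == "HNSCC", "TPF", "cetuximab+FOLFIRI")
  df <- data.frame(patient_id = sprintf("%s-%04d", id_prefix, seq_len(n)),
                   cancer_type = cancer, regimen = regimen, X,
                   clinical_response = lab)
  as_cohort(df)
}

#' Simulate a training/validation pair shaped like the published study
#'
#' Training cohort of 109 patients (70 HNSCC, 39 CRC); independent test
#' cohort of 55 patients (42 HNSCC, 13 CRC) with disjoint patient
#' identifiers. Both are fully labelled `score_anchored` cohorts. The test
#' class mix uses the published non-responder count (24 of 55) with the
#' remaining responders split 2:1 PR:CR; the training class mix defaults to
#' (0.4, 0.4, 0.2) since the published training composition is not printed
#' as text.
#'
#' @param seed integer RNG seed.
#' @param noise_sd per-read-out Gaussian noise, score units (default 5).
#' @param train_proportions class mix of the training cohort.
#' @return List with elements `train` and `test`.
#' @export
simulate_study_cohorts <- function(seed, noise_sd = 5,
                                   train_proportions = c(0.4, 0.4, 0.2)) {
  if (missing(seed)) stop("seed is required")
  test_proportions <- c(24, 21, 10) / 55
  withr::with_seed(seed, {
    train <- simulate_records(109L, train_proportions,
                              rep(cancer_types(), c(70L, 39L)),
                              "score_anchored", noise_sd, NULL, NULL, "TR")
    test <- simulate_records(55L, test_proportions,
                             rep(cancer_types(), c(42L, 13L)),
                             "score_anchored", noise_sd, NULL, NULL, "TS")
    list(train = train, test = test)
  })
}
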