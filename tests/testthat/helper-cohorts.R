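# Fixture builders, all programmatic.

make_cohort <- function(X, labels, cancer = "HNSCC", id_prefix = "p") {
  X <- matrix(X, ncol = 4L)
  colnames(X) <- readout_names()
  cancer <- rep(cancer, length.out = nrow(X))
  labels <- rep(labels, length.out = nrow(X))
  as_cohort(data.frame(
    patient_id = sprintf("%s%04d", id_prefix, seq_len(nrow(X))),
    cancer_type = cancer,
    regimen = ifelse(cancer == "HNSCC", "TPF", "cetuximab+FOLFIRI"),
    X,
    clinical_response = labels),
    allow_unlabelled = anyNA(labels))
}

# two well-separated read-out clusters, NR low / responders high
separable_cohort <- function(n_per = 50, centers = c(30, 70), sd = 3,
                             labels = c("NR", "PR"), seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 4, centers[1], sd), n_per, 4),
               matrix(rnorm(n_per * 4, centers[2], sd), n_per, 4))
    make_cohort(pmin(pmax(X, 0), 100), rep(labels, each = n_per))
  })
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
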