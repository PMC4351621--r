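test_that("most-violated negative set is the top-beta fraction with stable ties", {
  X <- matrix(0, 4, 4)
  X[, 1] <- c(-2, -1, 0, 1)   # scores under unit viability weight
  w <- c(1, 0, 0, 0)
  expect_identical(most_violated_negatives(w, X, 0.5), c(3L, 4L))
  expect_identical(most_violated_negatives(w, matrix(5, 4, 4), 0.5),
                   c(1L, 2L))  # all tied: lowest indices win
  expect_error(most_violated_negatives(w, X[0, , drop = FALSE], 0.5),
               "no negatives")
  # random instances against an argsort oracle
  withr::with_seed(31, {
    for (rep in 1:20) {
      Xr <- matrix(runif(10 * 4, 0, 100), 10, 4)
      wr <- runif(4, -1, 1)
      got <- most_violated_negatives(wr, Xr, 0.3)
      s <- drop(Xr %*% wr)
      expect_identical(got, sort(order(s, decreasing = TRUE)[1:3]))
    }
  })
})

test_that("the surrogate objective matches a naive pair-loop evaluation", {
  co <- simulate_cohort(30, seed = 17)
  expect_equal(pauc_objective(rep(0, 4), co), 1)
  withr::with_seed(23, {
    for (rep in 1:10) {
      w <- runif(4, -0.02, 0.05)
      got <- pauc_objective(w, co, beta = 0.25, lambda = 1)
      y <- ifelse(co$clinical_response == "NR", -1, 1)
      X <- as.matrix(co[readout_names()])
      sn <- drop(X[y < 0, ] %*% w)
      j <- floor(0.25 * sum(y < 0))
      S <- sort(order(-sn, seq_along(sn))[1:j])
      acc <- 0
      for (i in which(y > 0)) {
        for (jj in which(y < 0)[S]) {
          acc <- acc + max(0, 1 - sum(w * (X[i, ] - X[jj, ])))
        }
      }
      expect_equal(got, sum(w^2) / 2 + acc / (sum(y > 0) * j),
                   tolerance = 1e-12)
    }
  })
})

test_that("training separable classes reaches perfect partial AUC monotonically", {
  co <- separable_cohort()
  w <- train_svmpauc(co)
  expect_true(attr(w, "converged"))
  expect_true(all(diff(attr(w, "objective_path")) <= 0))
  s <- drop(as.matrix(co[readout_names()]) %*% w)
  y <- ifelse(co$clinical_response == "NR", -1, 1)
  expect_equal(partial_auc(s[y > 0], s[y < 0], 0.25)$value, 1)
})

test_that("an informative single read-out dominates the learned weights", {
  withr::with_seed(7, {
    X <- matrix(runif(100 * 4, 0, 100), 100, 4)
    X[, 2] <- c(runif(50, 0, 35), runif(50, 65, 100))
    co <- make_cohort(X, rep(c("NR", "CR"), each = 50))
  })
  w <- train_svmpauc(co)
  expect_gte(abs(w[["histology"]]) / sqrt(sum(w^2)), 0.9)
})

test_that("degenerate cohorts are rejected", {
  expect_error(train_svmpauc(make_cohort(rep(50, 20), rep("PR", 5))),
               "degenerate")
  tiny <- make_cohort(rep(c(10, 80), each = 4), c("NR", "PR"))
  expect_error(train_svmpauc(tiny, beta = 0.25), "floor")
})

test_that("rescaling all read-outs leaves the learned ranking unchanged", {
  co <- simulate_cohort(80, seed = 29)
  w1 <- train_svmpauc(co)
  scaled <- co
  for (rd in readout_names()) scaled[[rd]] <- scaled[[rd]] / 10
  w2 <- train_svmpauc(validate_cohort(scaled))
  probe <- simulate_cohort(50, seed = 30)
  Xp <- as.matrix(probe[readout_names()])
  expect_identical(order(drop(Xp %*% as.numeric(w1))),
                   order(drop((Xp / 10) %*% as.numeric(w2))))
})

test_that("the learner recovers latent generating weights", {
  truth <- published_model()$weights
  co <- simulate_cohort(500, mode = "latent_linear", noise_sd = 2, seed = 1,
                        true_weights = truth,
                        latent_thresholds = c(19.1, 55.14))
  w <- train_svmpauc(co)
  expect_gte(cosine(as.numeric(w), as.numeric(truth)), 0.95)
})

test_that("the combined model beats each read-out alone when none is fully informative", {
  # every read-out carries signal plus independent strong noise
  withr::with_seed(55, {
    s <- c(runif(60, 0, 40), runif(60, 60, 100))
    X <- s + matrix(rnorm(120 * 4, 0, 18), 120, 4)
    co <- make_cohort(pmin(pmax(X, 0), 100), rep(c("NR", "PR"), each = 60))
  })
  y <- ifelse(co$clinical_response == "NR", -1, 1)
  X <- as.matrix(co[readout_names()])
  w <- train_svmpauc(co)
  s_full <- drop(X %*% as.numeric(w))
  pauc_full <- partial_auc(s_full[y > 0], s_full[y < 0], 0.25)$value
  for (k in 1:4) {
    pauc_k <- partial_auc(X[y > 0, k], X[y < 0, k], 0.25)$value
    expect_gte(pauc_full, pauc_k)
  }
})
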