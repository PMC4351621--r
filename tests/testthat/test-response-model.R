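test_that("the frozen published model scores and classifies as printed", {
  m <- published_model()
  expect_identical(as.numeric(m$weights),
                   c(0.2977, 0.5562, 0.0073, 0.1388))
  expect_identical(m$weights[["histology"]], 0.5562)
  expect_equal(m$threshold_cr - m$threshold_responder, 36.04)
  expect_gt(m$threshold_cr, m$threshold_responder)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)

  expect_identical(predict(m, rep(0, 4), type = "score"), 0)
  expect_equal(predict(m, c(100, 0, 0, 0), type = "score"), 29.77)
  expect_equal(predict(m, rep(100, 4), type = "score"), 100)

  # strict threshold semantics at the printed boundaries
  expect_identical(score_class(m, c(19.1, 30, 55.14, 55.15)),
                   c("NR", "PR", "PR", "CR"))
})

test_that("stage-1 threshold spends at most the FPR budget, most sensitively", {
  t <- fit_stage1_threshold(1:6, c(-1, -1, -1, -1, 1, 1), beta = 0.25)
  expect_equal(t, 3.5)
  neg <- 1:4
  pos <- 5:6
  expect_equal(mean(neg > t), 0.25)
  expect_equal(mean(pos > t), 1)
  # perfectly separated: TPR 1 always; FPR never exceeds the budget and is
  # 0 when the budget admits no negative at all
  for (beta in c(0, 0.1, 0.5)) {
    ts <- fit_stage1_threshold(c(1, 2, 9, 10), c(0, 0, 1, 1), beta)
    expect_equal(mean(c(9, 10) > ts), 1)
    expect_lte(mean(c(1, 2) > ts), beta)
  }
  expect_equal(mean(c(1, 2) >
                      fit_stage1_threshold(c(1, 2, 9, 10),
                                           c(0, 0, 1, 1), 0.1)), 0)
  # always feasible, even at beta = 0 with interleaved scores
  expect_silent(fit_stage1_threshold(c(1, 3, 2, 4), c(0, 0, 1, 1), 0))
  expect_error(fit_stage1_threshold(1:3, c(1, 1, 1), 0.5), "both")
})

test_that("stage-2 threshold maximizes PR/CR accuracy with the stated tie rule", {
  expect_equal(fit_stage2_threshold(c(25, 30, 60, 70),
                                    c("PR", "PR", "CR", "CR")), 45)
  expect_equal(fit_stage2_threshold(c(20, 80), c("PR", "CR")), 50)
  expect_equal(fit_stage2_threshold(c(40, 35), c("PR", "CR")), 34.5)
  expect_warning(t_hi <- fit_stage2_threshold(c(30, 40), c("PR", "PR")),
                 "no CR")
  expect_gt(t_hi, 40)
  expect_warning(t_lo <- fit_stage2_threshold(c(60, 70), c("CR", "CR")),
                 "no PR")
  expect_lt(t_lo, 60)
  expect_error(fit_stage2_threshold(1:2, c("NR", "PR")), "PR or CR")
})

test_that("two-stage training meets its construction guarantees", {
  for (seed in c(3, 11, 27)) {
    co <- simulate_cohort(109, seed = seed)
    fit <- train_two_stage(co)
    expect_gt(fit$threshold_cr, fit$threshold_responder)
    expect_gte(fit$fit$stage1_specificity, 75)
    expect_identical(sum(fit$fit$training_confusion), 109L)
  }
})

test_that("classification is monotone in positively weighted read-outs", {
  fit <- train_two_stage(simulate_cohort(109, seed = 3))
  ord <- match(c("NR", "PR", "CR"), response_levels())
  withr::with_seed(61, {
    for (rep in 1:40) {
      x <- runif(4, 0, 80)
      cls <- match(predict(fit, x), response_levels())
      k <- sample(which(fit$weights > 0), 1)
      x2 <- x
      x2[k] <- x2[k] + runif(1, 0, 20)
      cls2 <- match(predict(fit, x2), response_levels())
      expect_gte(cls2, cls)
    }
  })
})

test_that("prediction interfaces agree across input shapes", {
  fit <- published_model()
  co <- simulate_cohort(20, seed = 41)
  X <- as.matrix(co[readout_names()])
  expect_identical(predict(fit, co), predict(fit, X))
  expect_identical(predict(fit, co)[1], predict(fit, X[1, ]))
  expect_identical(predict(fit, co),
                   score_class(fit, predict(fit, co, type = "score")))
  cf <- coef(fit)
  expect_identical(unname(cf[c("threshold_responder", "threshold_cr")]),
                   c(19.1, 55.14))
})
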