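test_that("cohort files round-trip exactly, including unlabelled rows", {
  co <- simulate_cohort(40, seed = 11)
  co$clinical_response[c(3, 17)] <- NA
  co <- as_cohort(co, allow_unlabelled = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, allow_unlabelled = TRUE)
  expect_equal(back, co)
  # property: round-trip equality over random cohorts
  for (seed in 1:5) {
    c2 <- simulate_cohort(25, seed = seed, noise_sd = seed)
    write_cohort(c2, path)
    expect_equal(read_cohort(path), c2)
  }
})

test_that("reading parses labels case-insensitively and preserves order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("patient_id", "cancer_type", "regimen", readout_names(),
            "clinical_response"), collapse = ","),
    "a,HNSCC,TPF,10,10,10,10,nr",
    "b,crc,cetuximab+FOLFIRI,90,90,90,90,Cr"), path)
  co <- read_cohort(path)
  expect_identical(co$patient_id, c("a", "b"))
  expect_identical(co$clinical_response, c("NR", "CR"))
  cc <- cohort_counts(co)
  expect_identical(c(cc$n, cc$n_pos, cc$n_neg), c(2L, 1L, 1L))
})

test_that("schema and parse failures are reported with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- paste(c("patient_id", "cancer_type", "regimen", readout_names(),
                    "clinical_response"), collapse = ",")
  writeLines(c("patient_id,viability", "a,1"), path)
  expect_error(read_cohort(path), "header")
  writeLines(c(header,
               "a,HNSCC,TPF,10,10,10,10,NR",
               "b,HNSCC,TPF,20,20,20,20,PR",
               "c,HNSCC,TPF,abc,30,30,30,CR"), path)
  expect_error(read_cohort(path), "row 3")
  writeLines(c(header,
               "a,HNSCC,TPF,10,10,10,10,NR",
               "a,HNSCC,TPF,20,20,20,20,PR"), path)
  expect_error(read_cohort(path), "duplicate")
})

test_that("validation enforces ranges, labels and class balance", {
  co <- make_cohort(rep(50, 8), c("NR", "NR"))
  expect_error(validate_cohort(co, require_both_classes = TRUE), "degenerate")
  mixed <- make_cohort(seq(5, 100, length.out = 40), rep(c("NR", "PR"), 5))
  cc <- cohort_counts(validate_cohort(mixed, require_both_classes = TRUE))
  expect_identical(c(cc$n_pos, cc$n_neg), c(5L, 5L))
  hot <- mixed
  hot$viability[1] <- 150
  expect_error(validate_cohort(hot), "outside \\[0, 100\\]")
  expect_silent(validate_cohort(hot, strict_range = FALSE))
  # idempotence
  expect_equal(validate_cohort(validate_cohort(mixed)), mixed)
})

test_that("model serialization round-trips and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".json")
  pub <- published_model()
  write_model(pub, path)
  back <- read_model(path)
  expect_identical(back$weights, pub$weights)
  expect_identical(back$threshold_responder, 19.1)
  expect_identical(back$threshold_cr, 55.14)
  expect_identical(back$provenance, "published")

  trained <- train_two_stage(simulate_cohort(80, seed = 5))
  write_model(trained, path)
  back <- read_model(path)
  expect_equal(back$weights, trained$weights)
  expect_equal(back$threshold_cr, trained$threshold_cr)

  doc <- jsonlite::read_json(path)
  doc$threshold_cr <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "threshold_cr")
})

test_that("empty and label-free cohorts write as documented", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- make_cohort(numeric(0), character(0))
  write_cohort(empty, path)
  expect_identical(length(readLines(path)), 1L)  # header only
  one <- make_cohort(rep(10, 4), NA_character_)
  write_cohort(one, path)
  expect_match(readLines(path)[2], ",$")  # empty clinical_response field
})
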