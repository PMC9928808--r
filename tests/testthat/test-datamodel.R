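# Domain types, packaged coefficient sets, and serialization round trips.

# published reference rows, frozen here as decimal strings so the packaged
# coefficient file is checked digit-for-digit against an independent copy
REF_1DOF <- list(
  tf_lateral_shift = c("1.57", "-0.0488", "1.37E-04"),
  tf_external_rotation = c("-0.16", "-0.1944", "1.39E-03"),
  pf_anterior_translation = c("49.59", "-0.0940", "-6.86E-04"),
  pf_flexion = c("0.30", "0.6284", "6.49E-04")
)
REF_2DOF <- list(
  tf_anterior_drawer = c("0.51", "0.0014", "-0.155", "7.32E-04", "4.30E-03"),
  tf_abduction = c("-4.87", "-0.0567", "-0.136", "6.19E-04", "5.16E-03"),
  pf_lateral_tilt = c("1.15", "0.0851", "0.244", "-6.58E-04", "-2.89E-03")
)

test_that("packaged models have the published shape and exact coefficients", {
  m1 <- knee_package_model("table1_1dof")
  expect_identical(m1$input_names, "tf_flexion")
  expect_equal(nrow(coef(m1)), 11L)
  expect_equal(ncol(coef(m1)), 3L)
  for (p in names(REF_1DOF)) {
    expect_identical(unname(m1$coef_strings[p, ]), REF_1DOF[[p]])
    expect_identical(unname(coef(m1)[p, ]), as.numeric(REF_1DOF[[p]]))
  }
  m2 <- knee_package_model("table1_2dof")
  expect_identical(m2$input_names, c("tf_flexion", "tf_external_rotation"))
  expect_equal(nrow(coef(m2)), 10L)
  expect_equal(ncol(coef(m2)), 5L)
  for (p in names(REF_2DOF))
    expect_identical(unname(m2$coef_strings[p, ]), REF_2DOF[[p]])
  # inputs are never outputs
  expect_false("tf_flexion" %in% rownames(coef(m1)))
  expect_false(any(m2$input_names %in% rownames(coef(m2))))
})

test_that("unknown packaged model names are rejected", {
  expect_error(knee_package_model("table1_3dof"), "no such packaged model")
})

test_that("model JSON round trip is exact for packaged coefficients", {
  m2 <- knee_package_model("table1_2dof")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path)
  back <- read_model(path)
  expect_identical(back$coef_strings, m2$coef_strings)
  expect_identical(coef(back), coef(m2))
  expect_identical(back$input_names, m2$input_names)
})

test_that("fitted models survive a JSON round trip within 1 ulp", {
  fit <- knee_fit(tiny_cohort(noise = 0.3, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  drift <- abs(coef(back) - coef(fit))
  ulp <- abs(coef(fit)) * .Machine$double.eps
  expect_true(all(drift <= pmax(ulp, .Machine$double.xmin)))
})

test_that("inconsistent model JSON is rejected", {
  m1 <- knee_package_model("table1_1dof")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m1, path)
  obj <- jsonlite::read_json(path)
  # claim tf_flexion is simultaneously an input and an output
  obj$coefficients$tf_flexion <- obj$coefficients$tf_external_rotation
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_model(path), "input parameter")
  writeLines("{not json", path)
  expect_error(read_model(path), "malformed")
})

test_that("model constructor enforces the input/output partition", {
  cf <- matrix(0, 11, 3,
               dimnames = list(setdiff(ALL_PARAMS, "tf_flexion"), NULL))
  expect_s3_class(knee_model("tf_flexion", cf), "knee_model")
  expect_error(knee_model("tf_abduction", cf), "tf_flexion")
  expect_error(knee_model("tf_flexion", cf[-1, ]), "exactly")
  expect_error(knee_model("pf_flexion", cf), "subset of the TF parameters")
})

test_that("trial CSV round trips and groups by participant/activity", {
  co <- tiny_cohort(seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(co, path)
  back <- read_trials(path)
  expect_equal(length(back), length(co))
  for (k in seq_along(co)) {
    expect_identical(back[[k]]$participant, co[[k]]$participant)
    expect_identical(back[[k]]$activity, co[[k]]$activity)
    expect_equal(as.matrix(back[[k]]$data), as.matrix(co[[k]]$data),
                 tolerance = 1e-12)
    expect_equal(back[[k]]$bicondylar_width, co[[k]]$bicondylar_width,
                 tolerance = 1e-12)
  }
})

test_that("malformed trial CSVs produce named parse errors", {
  co <- tiny_cohort(seed = 22)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(co, path)
  df <- utils::read.csv(path)

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, setdiff(names(df), "pf_lateral_tilt")], bad,
                   row.names = FALSE)
  expect_error(read_trials(bad), "pf_lateral_tilt")

  df2 <- df; df2$tf_abduction[3] <- NA
  utils::write.csv(df2, bad, row.names = FALSE)
  expect_error(read_trials(bad), "non-finite.*tf_abduction.*row 3")

  df3 <- df; df3$time_index[2] <- df3$time_index[1]
  utils::write.csv(df3, bad, row.names = FALSE)
  expect_error(read_trials(bad), "duplicate")
})

test_that("a two-activity file yields two trials with ordered samples", {
  set.seed(99)
  n <- 51
  base <- as.data.frame(matrix(0, n, 12, dimnames = list(NULL, ALL_PARAMS)))
  base$tf_flexion <- seq(0, 90, length.out = n)
  rows <- rbind(
    cbind(participant = "P1", activity = "open_flexion",
          time_index = 0:(n - 1), base),
    cbind(participant = "P1", activity = "level_walk",
          time_index = 0:(n - 1), base)
  )
  rows <- rows[sample(nrow(rows)), ]   # shuffled rows must still parse
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  co <- read_trials(path, default_width = 81.7)
  expect_equal(length(co), 2L)
  expect_equal(co[[1]]$data$tf_flexion, base$tf_flexion)
})
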