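# Residual metrics, report aggregation, LOOCV, and model-selection sweeps.

test_that("TF joint RMS residual matches hand-computed cases", {
  # n = 1 input: five outputs, all unit errors over two observations
  f <- matrix(1, 2, 5); m <- matrix(0, 2, 5)
  expect_equal(rmsr_tf(f, m, n_inputs = 1), 1.0)

  # n = 2 inputs: four outputs, single observation, errors (3, 0, 0, 0)
  f2 <- matrix(c(3, 0, 0, 0), 1, 4); m2 <- matrix(0, 1, 4)
  expect_equal(rmsr_tf(f2, m2, n_inputs = 2), 1.5)

  expect_error(rmsr_tf(f2, m2, n_inputs = 1), "expected 5")
  expect_error(rmsr_tf(f[0, ], m[0, ], 1), "p = 0")
})

test_that("PF joint RMS residual matches hand-computed cases", {
  f <- matrix(2, 3, 6); m <- matrix(0, 3, 6)
  expect_equal(rmsr_pf(f, m), 2.0)
  expect_equal(rmsr_pf(m, m), 0.0)
  expect_error(rmsr_pf(matrix(0, 3, 5), matrix(0, 3, 5)), "6 PF")
})

test_that("joint residuals equal the naive double-loop oracle", {
  set.seed(123)
  for (rep in 1:25) {
    p <- sample(2:40, 1)
    ftab <- matrix(rnorm(p * 5), p, 5)
    mtab <- matrix(rnorm(p * 5), p, 5)
    expect_equal(rmsr_tf(ftab, mtab, 1), rmsr_loop_oracle(ftab, mtab),
                 tolerance = 1e-12)
    f6 <- cbind(ftab, rnorm(p)); m6 <- cbind(mtab, rnorm(p))
    expect_equal(rmsr_pf(f6, m6), rmsr_loop_oracle(f6, m6),
                 tolerance = 1e-12)
  }
})

test_that("pooled RMSE reproduces the published aggregation conventions", {
  # per-participant values for the 1-DOF model, first participant:
  # five predicted TF parameters with flexion excluded
  v1 <- c(tf_lateral_shift = 1.2, tf_anterior_drawer = 3.0,
          tf_joint_distraction = 1.6, tf_flexion = 0.0,
          tf_abduction = 3.6, tf_external_rotation = 10.0)
  expect_equal(round(pooled_rmse(v1, exclude = "tf_flexion"), 1), 5.0)

  # 2-DOF: flexion and external rotation both excluded
  v2 <- c(tf_lateral_shift = 1.2, tf_anterior_drawer = 2.5,
          tf_joint_distraction = 1.5, tf_flexion = 0.0,
          tf_abduction = 4.1, tf_external_rotation = 0.0)
  expect_equal(round(pooled_rmse(v2, exclude = c("tf_flexion",
                                                 "tf_external_rotation")), 1),
               2.6)

  # single parameter and idempotence on equal values
  expect_equal(pooled_rmse(c(a = 3.7)), 3.7)
  expect_equal(pooled_rmse(c(a = 2, b = 2, c = 2)), 2)
  expect_error(pooled_rmse(v1, exclude = names(v1)), "no parameters")
})

test_that("noiseless homogeneous cohorts cross-validate to zero error", {
  co <- tiny_cohort(n_participants = 2, noise = 0, het = 0, seed = 31)
  cv <- knee_loocv(co)
  pred <- setdiff(ALL_PARAMS, cv$input_names)
  expect_lt(max(cv$per_param[pred, ]), 1e-8)
  expect_lt(max(cv$all_tf, cv$all_pf), 1e-8)
  # input rows are exactly zero for every participant
  expect_true(all(cv$per_param[cv$input_names, ] == 0))
})

test_that("LOOCV matches an independently coded fold loop", {
  co <- tiny_cohort(n_participants = 3, noise = 0.4, het = 0.15, seed = 32)
  cv <- knee_loocv(co, inputs = "tf_flexion", order = 2)
  participants <- cohort_participants(co)
  for (p in participants) {
    # independent fold: fit with lm() on the other participants, predict
    train <- do.call(rbind, lapply(
      Filter(function(t) t$participant != p, co),
      function(t) t$data))
    test <- do.call(rbind, lapply(
      Filter(function(t) t$participant == p, co), function(t) t$data))
    for (param in c("tf_external_rotation", "pf_flexion",
                    "tf_lateral_shift")) {
      lmfit <- lm(y ~ f + I(f^2),
                  data.frame(y = train[[param]], f = train$tf_flexion))
      pred <- predict(lmfit, data.frame(f = test$tf_flexion))
      rmse <- sqrt(mean((pred - test[[param]])^2))
      expect_equal(unname(cv$per_param[param, p]), rmse, tolerance = 1e-8)
    }
    # pooled "All" value equals the RMS over the predicted-parameter table
    expect_equal(unname(cv$all_tf[p]),
                 pooled_rmse(cv$per_param[TF_PARAMS, p], "tf_flexion"),
                 tolerance = 1e-10)
  }
  # the Mean column is the arithmetic mean across participants
  expect_equal(unname(cv$mean_param["pf_flexion"]),
               mean(cv$per_param["pf_flexion", ]), tolerance = 1e-12)
  expect_equal(cv$mean_all_tf, mean(cv$all_tf), tolerance = 1e-12)
})

test_that("the CV report table has one column per participant plus Mean", {
  co <- tiny_cohort(n_participants = 3, noise = 0.2, seed = 33)
  cv <- knee_loocv(co)
  df <- as.data.frame(cv)
  expect_identical(colnames(df), c(cohort_participants(co), "Mean"))
  expect_identical(rownames(df),
                   c(TF_PARAMS, "all_tf", PF_PARAMS, "all_pf"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv(cv, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 14L)
  expect_error(knee_loocv(knee_cohort(co[1:2])), "at least 2")
})

test_that("input-set enumeration has the right combinatorics and winner", {
  co <- tiny_cohort(n_participants = 3, noise = 0.3, het = 0, seed = 35,
                    activities = c("open_flexion", "level_walk",
                                   "stair_descent"))
  sel2 <- enumerate_input_sets(co, max_dof = 2)
  expect_equal(nrow(sel2), 6L)         # 1 + choose(5, 1)
  sel5 <- enumerate_input_sets(co, max_dof = 5)
  expect_equal(nrow(sel5), 31L)        # sum_{k=0..4} choose(5, k)
  expect_true(all(grepl("tf_flexion", sel5$inputs)))
  expect_error(enumerate_input_sets(co, max_dof = 0), "between 1 and 6")

  # data generated with genuine flexion + external-rotation coupling:
  # that input pair must win among the 2-DOF candidates
  two_dof <- sel2[sel2$n_inputs == 2, ]
  expect_equal(two_dof$inputs[which.min(two_dof$rmsr_tfj)],
               "tf_flexion+tf_external_rotation")
})

test_that("order sweep residuals are monotone and flatten at the truth", {
  # exact quadratic data: orders 2..4 all hit (near) zero residual
  f <- seq(0, 90, length.out = 60)
  dat <- as.data.frame(matrix(0, 60, 12, dimnames = list(NULL, ALL_PARAMS)))
  dat$tf_flexion <- f
  for (p in setdiff(ALL_PARAMS, "tf_flexion"))
    dat[[p]] <- 0.3 - 0.02 * f + 1e-4 * f^2
  sw <- order_sweep(dat, inputs = "tf_flexion", orders = 2:4)
  expect_true(all(sw$rmsr_tfj < 1e-10))
  expect_true(all(sw$rmsr_pfj < 1e-10))

  # quadratic + noise: order 1 clearly worse, orders 2 and 4 at the floor
  set.seed(77)
  for (p in setdiff(ALL_PARAMS, "tf_flexion"))
    dat[[p]] <- 2 - 0.5 * f + 0.01 * f^2 + rnorm(60, sd = 0.3)
  sw2 <- order_sweep(dat, inputs = "tf_flexion", orders = c(1, 2, 4))
  expect_gt(sw2$rmsr_tfj[1], 2 * sw2$rmsr_tfj[2])
  expect_equal(sw2$rmsr_tfj[2], sw2$rmsr_tfj[3], tolerance = 0.05)
  expect_true(all(diff(sw2$rmsr_tfj) <= 1e-10))
})
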