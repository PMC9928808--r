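# Shared fixtures and independent oracles for the test suite.

ALL_PARAMS <- knee_parameters()
TF_PARAMS <- knee_parameters("tf")
PF_PARAMS <- knee_parameters("pf")

# tiny deterministic cohort: quick to fit, no randomness needed
tiny_cohort <- function(n_participants = 2, noise = 0, het = 0, seed = 11,
                        activities = c("open_flexion", "level_walk")) {
  simulate_cohort(n_participants = n_participants, activities = activities,
                  n_points = 51, participant_sd = het,
                  noise_sd_rotation = noise, noise_sd_translation = noise,
                  seed = seed)
}

# independent normal-equations OLS oracle (deliberately the naive solve)
ols_oracle <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y

# naive double-loop RMS residual oracle
rmsr_loop_oracle <- function(fitted, measured) {
  acc <- 0
  for (i in seq_len(ncol(fitted)))
    for (j in seq_len(nrow(fitted)))
      acc <- acc + (fitted[j, i] - measured[j, i])^2
  sqrt(acc / (ncol(fitted) * nrow(fitted)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
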