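# Signal conditioning for raw kinematic trials: zero-phase Butterworth
# low-pass filtering, resampling onto a normalized time grid, and
# bicondylar-width scaling of the translation channels.

#' Preprocessing configuration
#'
#' Bundles the signal-conditioning settings applied to raw trials. Defaults
#' reproduce the conditioning used for the packaged reference models: a
#' fourth-order low-pass Butterworth filter with a 10 Hz cut-off applied to
#' 200 Hz recordings, resampling to 201 points on a normalized time grid,
#' and scaling of translations to a reference femoral bicondylar width of
#' 81.7 mm (the cohort mean behind the packaged coefficients).
#'
#' @param filter_order Butterworth filter order (applied twice: the filter
#'   runs forward and backward for zero phase lag).
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist rate.
#' @param sample_rate Sampling rate of raw trials in Hz.
#' @param n_points Number of samples on the normalized time grid.
#' @param reference_width Reference bicondylar width in mm.
#' @return A list of class `knee_preprocess_config`.
#' @export
knee_preprocess_config <- function(filter_order = 4L, cutoff = 10,
                                   sample_rate = 200, n_points = 201L,
                                   reference_width = 81.7) {
  filter_order <- as.integer(filter_order)
  n_points <- as.integer(n_points)
  stopifnot(filter_order >= 1L, cutoff > 0, sample_rate > 0,
            reference_width > 0)
  if (cutoff >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency (sample_rate/2)",
         call. = FALSE)
  if (n_points < 2L) stop("n_points must be at least 2", call. = FALSE)
  structure(list(filter_order = filter_order, cutoff = cutoff,
                 sample_rate = sample_rate, n_points = n_points,
                 reference_width = reference_width),
            class = "knee_preprocess_config")
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters each column (or a single vector) with a low-pass Butterworth
#' filter run forward and then backward, giving zero phase lag and unit DC
#' gain. The series is extended at both ends by reflected padding of length
#' three times the filter order before filtering, and the padding is
#' discarded afterwards, so trial endpoints are not contaminated by filter
#' start-up transients.
#'
#' @param x Numeric vector, matrix or data frame of uniformly sampled
#'   series (columns are channels). Length must exceed `3 * filter_order`.
#' @param config A [knee_preprocess_config()] supplying filter order,
#'   cut-off and sample rate.
#' @return Filtered object of the same shape as `x`.
#' @export
lowpass_filter <- function(x, config = knee_preprocess_config()) {
  if (is.data.frame(x) || is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- lowpass_filter(x[, j], config)
    return(out)
  }
  n <- length(x)
  pad <- 3L * config$filter_order
  if (n <= pad)
    stop("series too short to filter: need more than ", pad,
         " samples (3 x filter order), got ", n, call. = FALSE)
  bf <- signal::butter(config$filter_order,
                       config$cutoff / (config$sample_rate / 2),
                       type = "low")
  # reflect about the end values so padding is continuous in value and slope
  pre <- 2 * x[1L] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(pre, x, post)
  y <- iir_filter_ss(bf$b, bf$a, xp)
  y <- rev(iir_filter_ss(bf$b, bf$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# internal: IIR filter (direct form II transposed) whose state starts at the
# step-response steady state scaled by the first sample, so constant inputs
# pass through exactly and start-up transients are suppressed
iir_filter_ss <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  m <- length(a) - 1L
  # steady-state unit-step state: (I - A) z = B with the companion form of a
  A <- cbind(-a[-1], rbind(diag(1, m - 1L), 0))
  B <- b[-1] - a[-1] * b[1]
  zi <- solve(diag(m) - A, B)
  z <- zi * x[1L]
  y <- numeric(length(x))
  for (k in seq_along(x)) {
    y[k] <- b[1] * x[k] + z[1L]
    z <- c(z[-1L], 0) + b[-1L] * x[k] - a[-1L] * y[k]
  }
  y
}

#' Resample a trial onto a normalized time grid
#'
#' Interpolates every channel onto `n_points` uniformly spaced points
#' spanning \[0, 1\] of the trial's duration. Interpolation is cubic spline
#' (natural end conditions); trials with fewer than 4 samples fall back to
#' linear interpolation. The first and last samples are preserved exactly,
#' and affine-in-time signals are reproduced exactly.
#'
#' @param trial A [knee_trial] with at least 2 samples.
#' @param n_points Target number of samples (default 201).
#' @return A [knee_trial] on the normalized grid (`normalized = TRUE`).
#' @export
time_normalize <- function(trial, n_points = 201L) {
  stopifnot(inherits(trial, "knee_trial"))
  n_points <- as.integer(n_points)
  n <- nrow(trial$data)
  if (n < 2L)
    stop("cannot time-normalize a trial with fewer than 2 samples",
         call. = FALSE)
  if (n_points < 2L) stop("n_points must be at least 2", call. = FALSE)
  t_old <- seq(0, 1, length.out = n)
  t_new <- seq(0, 1, length.out = n_points)
  out <- vapply(trial$data, function(col) {
    if (n < 4L)
      stats::approx(t_old, col, xout = t_new)$y
    else
      stats::splinefun(t_old, col, method = "natural")(t_new)
  }, numeric(n_points))
  out <- as.data.frame(out)
  # endpoints are grid points of the source series: force exact preservation
  out[1L, ] <- trial$data[1L, ]
  out[n_points, ] <- trial$data[n, ]
  trial$data <- out
  trial$normalized <- TRUE
  trial$sample_rate <- NA_real_
  trial
}

#' Scale translations to a reference bicondylar width
#'
#' Makes translations comparable across knees of different size by
#' multiplying the six translation channels by
#' `reference_width / bicondylar_width`, i.e. expressing them on a knee of
#' the reference width. Rotation channels are untouched (bitwise identical).
#' The transformation is invertible with `invert = TRUE`.
#'
#' @param trial A [knee_trial] with positive `bicondylar_width`.
#' @param reference_width Reference width in mm (default 81.7).
#' @param invert If `TRUE`, undo a previous scaling with the same reference.
#' @return The scaled [knee_trial].
#' @export
scale_translations <- function(trial, reference_width = 81.7,
                               invert = FALSE) {
  stopifnot(inherits(trial, "knee_trial"))
  if (!is.numeric(reference_width) || reference_width <= 0)
    stop("reference_width must be positive", call. = FALSE)
  factor <- reference_width / trial$bicondylar_width
  if (invert) factor <- 1 / factor
  trial$data[KP_TRANSLATIONS] <- trial$data[KP_TRANSLATIONS] * factor
  trial
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, per trial: zero-phase low-pass filtering (raw trials with a
#' known sample rate only), resampling to the normalized time grid, and
#' translation scaling to the reference bicondylar width — in that order,
#' since the filter requires uniform sampling in true time.
#'
#' @param cohort A [knee_cohort] (or single [knee_trial]).
#' @param config A [knee_preprocess_config()].
#' @return The preprocessed [knee_cohort].
#' @export
preprocess_cohort <- function(cohort, config = knee_preprocess_config()) {
  single <- inherits(cohort, "knee_trial")
  if (single) cohort <- knee_cohort(list(cohort))
  out <- lapply(cohort, function(tr) {
    if (!tr$normalized && !is.na(tr$sample_rate)) {
      cfg <- config
      cfg$sample_rate <- tr$sample_rate
      tr$data <- lowpass_filter(tr$data, cfg)
    }
    tr <- time_normalize(tr, config$n_points)
    scale_translations(tr, config$reference_width)
  })
  if (single) out[[1L]] else knee_cohort(out)
}
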