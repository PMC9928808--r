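# Least-squares fitting of the polynomial coupling model.

#' Polynomial design matrix for a set of observations
#'
#' Builds the cross-term-free polynomial basis evaluated at the input
#' columns of `observations`: a leading intercept column, then all linear
#' terms, then all squared terms, and so on up to `order`
#' (`[1, x1, x2, ..., x1^2, x2^2, ...]`). There are never interaction
#' (cross) terms.
#'
#' @param observations Data frame or matrix containing one column per input.
#' @param input_names Inputs to use; a subset of the TF parameters that must
#'   include `"tf_flexion"`.
#' @param order Polynomial order (>= 1).
#' @return Numeric matrix with `1 + order * length(input_names)` columns.
#' @examples
#' design_matrix(data.frame(tf_flexion = c(0, 10)), "tf_flexion", 2)
#' @export
design_matrix <- function(observations, input_names, order = 2L) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (!all(input_names %in% KP_TF) || !"tf_flexion" %in% input_names)
    stop("input_names must be TF parameters and include tf_flexion",
         call. = FALSE)
  observations <- as.data.frame(observations)
  missing <- setdiff(input_names, colnames(observations))
  if (length(missing))
    stop("observations lack input column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(observations[, input_names, drop = FALSE])
  polynomial_basis(X, order)
}

#' Fit a polynomial knee coupling model
#'
#' Fits, for every kinematic parameter not used as an input, an ordinary
#' least-squares polynomial in the chosen input rotations. Observations from
#' all trials of a cohort are pooled with equal weight. The system is solved
#' per output through a QR factorization of the design matrix (never the
#' normal equations); a rank-deficient design — e.g. an input held constant
#' across all observations — is a hard error rather than a silent
#' pseudo-inverse solution.
#'
#' @param data A [knee_cohort], a [knee_trial], or a data frame holding the
#'   12 canonical parameter columns (one row per pooled observation).
#' @param inputs Input parameter names; default the 2-DOF choice
#'   `c("tf_flexion", "tf_external_rotation")`. Must include `"tf_flexion"`.
#' @param order Polynomial order (default 2).
#' @return An object of class `c("knee_fit", "knee_model")`: a usable
#'   [knee_model] augmented with the training data size, per-parameter
#'   root-mean-square residuals, the joint-level residuals
#'   (`rmsr_tfj`, `rmsr_pfj`; see [rmsr_tf()]), per-output residual sums of
#'   squares (`sse`), and the residual matrix.
#' @examples
#' cohort <- simulate_cohort(n_participants = 2, seed = 1)
#' fit <- knee_fit(cohort)
#' summary(fit)
#' @export
knee_fit <- function(data, inputs = c("tf_flexion", "tf_external_rotation"),
                     order = 2L) {
  obs <- pooled_observations(data)
  order <- as.integer(order)
  X <- design_matrix(obs, inputs, order)
  outputs <- setdiff(KP_ALL, inputs)
  if (nrow(X) < ncol(X))
    stop("need at least ", ncol(X), " observations to fit ", ncol(X),
         " coefficients; got ", nrow(X), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix (rank ", qrX$rank, " < ", ncol(X),
         " columns); inputs carry too little variation to identify the ",
         "polynomial", call. = FALSE)
  Y <- as.matrix(obs[, outputs, drop = FALSE])
  beta <- qr.coef(qrX, Y)                  # terms x outputs
  fitted <- X %*% beta
  resid <- Y - fitted
  model <- knee_model(inputs, t(beta), order = order, provenance = "fitted")
  model$n_obs <- nrow(X)
  model$sse <- colSums(resid^2)
  model$per_parameter_rmse <- sqrt(model$sse / nrow(X))
  tf_out <- intersect(KP_TF, outputs)
  model$rmsr_tfj <- rmsr_tf(fitted[, tf_out, drop = FALSE],
                            Y[, tf_out, drop = FALSE],
                            n_inputs = length(inputs))
  model$rmsr_pfj <- rmsr_pf(fitted[, KP_PF, drop = FALSE],
                            Y[, KP_PF, drop = FALSE])
  model$residual_matrix <- resid
  class(model) <- c("knee_fit", class(model))
  model
}

# internal: coerce cohort/trial/data.frame to a pooled observation frame
pooled_observations <- function(data) {
  if (inherits(data, "knee_cohort"))
    return(as.data.frame(cohort_observations(data)))
  if (inherits(data, "knee_trial")) return(data$data)
  data <- as.data.frame(data)
  check_param_columns(data, "observations")
  data
}

#' @export
print.knee_fit <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf("  fitted on %d observations; RMSR TF %.3f deg|mm, PF %.3f deg|mm\n",
              x$n_obs, x$rmsr_tfj, x$rmsr_pfj))
  invisible(x)
}

#' @export
residuals.knee_fit <- function(object, ...) object$residual_matrix

#' Residual report for a fitted coupling model
#'
#' @param object A `knee_fit` object.
#' @param ... Unused.
#' @return A list of class `knee_residual_report`: per-parameter RMS
#'   residuals over the training observations (zero for input parameters,
#'   which are passed through by construction), the joint-level residuals
#'   `rmsr_tfj` and `rmsr_pfj`, and the problem size (`n_inputs`,
#'   `n_observations`).
#' @export
summary.knee_fit <- function(object, ...) {
  per <- setNames(numeric(length(KP_ALL)), KP_ALL)
  per[names(object$per_parameter_rmse)] <- object$per_parameter_rmse
  structure(
    list(per_parameter_rmse = per, rmsr_tfj = object$rmsr_tfj,
         rmsr_pfj = object$rmsr_pfj, n_inputs = length(object$input_names),
         n_observations = object$n_obs, input_names = object$input_names),
    class = "knee_residual_report"
  )
}

#' @export
print.knee_residual_report <- function(x, digits = 3, ...) {
  cat(sprintf("Residual report: %d-DOF model, %d observations\n",
              x$n_inputs, x$n_observations))
  cat(sprintf("  RMSR TF joint: %.*f deg|mm\n", digits, x$rmsr_tfj))
  cat(sprintf("  RMSR PF joint: %.*f deg|mm\n", digits, x$rmsr_pfj))
  cat("  per-parameter RMS residual (deg|mm):\n")
  print(round(x$per_parameter_rmse, digits))
  invisible(x)
}

#' Joint-level RMS residual for the tibiofemoral joint
#'
#' Pools the squared residuals of the `6 - n` predicted TF parameters over
#' all observations:
#' \deqn{\mathrm{RMSR_{TFJ}} = \sqrt{\frac{1}{(6-n)\,p}
#'   \sum_{i=1}^{6-n}\sum_{j=1}^{p} (y_{ij} - y'_{ij})^2}}
#' where `p` is the number of observations and `n` the number of model
#' inputs. Rotations (degrees) and translations (mm) are weighted equally,
#' so the result carries the combined unit deg|mm.
#'
#' @param fitted,measured Matrices (p x (6 - n)) of fitted and measured
#'   values of the predicted TF parameters.
#' @param n_inputs Number of input TF parameters n (1–5).
#' @return RMS residual in deg|mm.
#' @export
rmsr_tf <- function(fitted, measured, n_inputs) {
  fitted <- as.matrix(fitted); measured <- as.matrix(measured)
  if (!identical(dim(fitted), dim(measured)))
    stop("fitted and measured must have identical shape", call. = FALSE)
  if (nrow(fitted) == 0L) stop("no observations (p = 0)", call. = FALSE)
  if (ncol(fitted) != 6L - n_inputs)
    stop("expected ", 6L - n_inputs, " predicted TF parameters for ",
         n_inputs, " input(s); got ", ncol(fitted), call. = FALSE)
  sqrt(sum((fitted - measured)^2) / ((6L - n_inputs) * nrow(fitted)))
}

#' Joint-level RMS residual for the patellofemoral joint
#'
#' As [rmsr_tf()] but pooling all six PF parameters:
#' \deqn{\mathrm{RMSR_{PFJ}} = \sqrt{\frac{1}{6p}
#'   \sum_{i=1}^{6}\sum_{j=1}^{p} (y_{ij} - y'_{ij})^2}}
#'
#' @param fitted,measured Matrices (p x 6) of fitted and measured PF values.
#' @return RMS residual in deg|mm.
#' @export
rmsr_pf <- function(fitted, measured) {
  fitted <- as.matrix(fitted); measured <- as.matrix(measured)
  if (!identical(dim(fitted), dim(measured)))
    stop("fitted and measured must have identical shape", call. = FALSE)
  if (nrow(fitted) == 0L) stop("no observations (p = 0)", call. = FALSE)
  if (ncol(fitted) != 6L)
    stop("expected all 6 PF parameters; got ", ncol(fitted), call. = FALSE)
  sqrt(sum((fitted - measured)^2) / (6L * nrow(fitted)))
}
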