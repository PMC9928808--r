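# Model evaluation: pooled RMSE aggregation, leave-one-participant-out
# cross-validation, input-set enumeration and polynomial-order sweeps.

#' Pool per-parameter RMSEs into a single value
#'
#' Aggregates a set of per-parameter RMSE values into one pooled value by
#' taking the RMS of the values that remain after excluding the model's
#' input parameters (whose error is zero by construction and would
#' otherwise deflate the pooled value). With equal observation counts per
#' parameter this equals the RMSE computed by pooling all raw squared
#' errors.
#'
#' @param per_parameter_rmse Named numeric vector of RMSE values (deg|mm).
#' @param exclude Parameter names to drop (typically the model inputs).
#' @return Pooled RMSE in deg|mm.
#' @examples
#' pooled_rmse(c(tf_lateral_shift = 1.2, tf_anterior_drawer = 3.0,
#'               tf_joint_distraction = 1.6, tf_flexion = 0,
#'               tf_abduction = 3.6, tf_external_rotation = 10.0),
#'             exclude = "tf_flexion")
#' @export
pooled_rmse <- function(per_parameter_rmse, exclude = character()) {
  v <- per_parameter_rmse[setdiff(names(per_parameter_rmse), exclude)]
  if (!length(v))
    stop("no parameters left to pool after exclusion", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite RMSE values", call. = FALSE)
  sqrt(mean(v^2))
}

#' Leave-one-participant-out cross-validation
#'
#' For each participant in turn: fit the coupling model on the pooled
#' observations of all *other* participants, drive it with the left-out
#' participant's measured input channels, and score prediction error
#' against their measured outputs. Per-parameter RMSEs pool the raw squared
#' errors over all of the left-out participant's trials before the square
#' root. Input parameters have zero error by construction.
#'
#' @param cohort A [knee_cohort] with at least 2 participants.
#' @param inputs,order Model specification as in [knee_fit()].
#' @return An object of class `knee_cv` holding the per-participant x
#'   per-parameter RMSE table, the per-participant pooled values for the TF
#'   and PF panels (`all_tf`, `all_pf`; input parameters excluded), the
#'   cross-participant means, and any fold-level fitting errors.
#' @examples
#' cohort <- simulate_cohort(n_participants = 3, seed = 7)
#' cv <- knee_loocv(cohort)
#' cv
#' @export
knee_loocv <- function(cohort,
                       inputs = c("tf_flexion", "tf_external_rotation"),
                       order = 2L) {
  stopifnot(inherits(cohort, "knee_cohort"))
  participants <- cohort_participants(cohort)
  if (length(participants) < 2L)
    stop("leave-one-out needs at least 2 participants", call. = FALSE)
  per_param <- matrix(NA_real_, length(KP_ALL), length(participants),
                      dimnames = list(KP_ALL, participants))
  all_tf <- setNames(rep(NA_real_, length(participants)), participants)
  all_pf <- all_tf
  fold_errors <- list()
  for (p in participants) {
    train <- knee_cohort(Filter(function(t) t$participant != p, cohort))
    test <- Filter(function(t) t$participant == p, cohort)
    fit <- tryCatch(knee_fit(train, inputs = inputs, order = order),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      fold_errors[[p]] <- conditionMessage(fit)
      next
    }
    measured <- do.call(rbind, lapply(test, function(t) as.matrix(t$data)))
    predicted <- as.matrix(predict(fit, as.data.frame(measured)))
    sq <- (predicted - measured)^2
    per_param[, p] <- sqrt(colMeans(sq))[KP_ALL]
    outputs <- model_outputs(fit)
    tf_out <- intersect(KP_TF, outputs)
    pf_out <- intersect(KP_PF, outputs)
    all_tf[p] <- sqrt(mean(sq[, tf_out]))
    all_pf[p] <- sqrt(mean(sq[, pf_out]))
  }
  structure(
    list(input_names = inputs, order = as.integer(order),
         participants = participants, per_param = per_param,
         all_tf = all_tf, all_pf = all_pf,
         mean_param = rowMeans(per_param),
         mean_all_tf = mean(all_tf), mean_all_pf = mean(all_pf),
         fold_errors = fold_errors),
    class = "knee_cv"
  )
}

#' @export
print.knee_cv <- function(x, digits = 1, ...) {
  cat(sprintf("<knee_cv> leave-one-participant-out, %d-DOF model (order %d)\n",
              length(x$input_names), x$order))
  if (length(x$fold_errors))
    cat("  fold errors: ", paste(names(x$fold_errors), collapse = ", "),
        "\n", sep = "")
  print(round(as.data.frame(x), digits), ...)
  invisible(x)
}

#' Cross-validation report as a table
#'
#' Lays the LOOCV results out as the conventional report table: one column
#' per left-out participant plus a `Mean` column, one row per kinematic
#' parameter grouped in TF and PF panels, and an `all_tf` / `all_pf` pooled
#' row closing each panel (input parameters excluded from the pooling).
#'
#' @param x A `knee_cv` object.
#' @param ... Unused.
#' @return Data frame in the report layout (full precision; round for
#'   display).
#' @export
as.data.frame.knee_cv <- function(x, ...) {
  body <- cbind(x$per_param, Mean = x$mean_param)
  tf <- body[KP_TF, , drop = FALSE]
  pf <- body[KP_PF, , drop = FALSE]
  all_tf <- c(x$all_tf, Mean = x$mean_all_tf)
  all_pf <- c(x$all_pf, Mean = x$mean_all_pf)
  out <- rbind(tf, all_tf = all_tf, pf, all_pf = all_pf)
  as.data.frame(out)
}

#' Write a cross-validation report to CSV
#'
#' @param cv A `knee_cv` object.
#' @param path Output CSV path.
#' @param digits Decimal places for presentation (default 1, matching the
#'   convention of reporting joint kinematic errors to 0.1 deg|mm);
#'   use `NA` for full precision.
#' @return `path`, invisibly.
#' @export
write_cv <- function(cv, path, digits = 1) {
  df <- as.data.frame(cv)
  if (!is.na(digits)) df <- round(df, digits)
  utils::write.csv(cbind(parameter = rownames(df), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enumerate and score candidate input sets
#'
#' Fits one coupling model for every subset of the six TF parameters that
#' contains TF flexion and has at most `max_dof` members, and scores each
#' on the pooled training observations with the joint-level RMS residuals.
#' This reproduces the model-selection question "which (and how many) input
#' rotations buy the most predictive power?".
#'
#' @param data Cohort, trial or pooled observation data frame
#'   (see [knee_fit()]).
#' @param max_dof Largest input-set size to consider (1–6).
#' @param order Polynomial order for every candidate (default 2).
#' @return Data frame of class `knee_selection`, one row per candidate
#'   (`inputs`, `n_inputs`, `rmsr_tfj`, `rmsr_pfj`), sorted by increasing
#'   `rmsr_tfj`; failed fits carry `NA` residuals and the error message.
#' @export
enumerate_input_sets <- function(data, max_dof = 5L, order = 2L) {
  max_dof <- as.integer(max_dof)
  if (max_dof < 1L || max_dof > 6L)
    stop("max_dof must be between 1 and 6", call. = FALSE)
  others <- setdiff(KP_TF, "tf_flexion")
  candidates <- list()
  for (k in 0:(max_dof - 1L)) {
    combs <- utils::combn(others, k, simplify = FALSE)
    candidates <- c(candidates,
                    lapply(combs, function(s) c("tf_flexion", s)))
  }
  obs <- pooled_observations(data)
  rows <- lapply(candidates, function(inp) {
    fit <- tryCatch(knee_fit(obs, inputs = inp, order = order),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(inputs = paste(inp, collapse = "+"),
                        n_inputs = length(inp), rmsr_tfj = NA_real_,
                        rmsr_pfj = NA_real_,
                        error = conditionMessage(fit)))
    data.frame(inputs = paste(inp, collapse = "+"), n_inputs = length(inp),
               rmsr_tfj = fit$rmsr_tfj, rmsr_pfj = fit$rmsr_pfj,
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rmsr_tfj), ]
  rownames(out) <- NULL
  class(out) <- c("knee_selection", class(out))
  out
}

#' Sweep the polynomial order
#'
#' Fits the same input set at a series of polynomial orders and reports the
#' joint-level training residuals per order. Because the bases are nested,
#' training residuals are non-increasing in order; the sweep shows where
#' extra orders stop paying.
#'
#' @param data Cohort, trial or pooled observation data frame.
#' @param inputs Input parameter names (default the 2-DOF choice).
#' @param orders Integer vector of polynomial orders to try.
#' @return Data frame with one row per order: `order`, `rmsr_tfj`,
#'   `rmsr_pfj`.
#' @export
order_sweep <- function(data,
                        inputs = c("tf_flexion", "tf_external_rotation"),
                        orders = 1:4) {
  orders <- as.integer(orders)
  if (any(orders < 1L)) stop("orders must be >= 1", call. = FALSE)
  obs <- pooled_observations(data)
  rows <- lapply(orders, function(k) {
    fit <- knee_fit(obs, inputs = inputs, order = k)
    data.frame(order = k, rmsr_tfj = fit$rmsr_tfj, rmsr_pfj = fit$rmsr_pfj)
  })
  do.call(rbind, rows)
}
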