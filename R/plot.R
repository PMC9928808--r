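# Base-graphics display methods.

#' Plot a coupling model's predicted parameter curves
#'
#' Draws each predicted kinematic parameter against TF flexion over a
#' flexion range, holding any further inputs at fixed values. For a 2-DOF
#' model the secondary input defaults to its neutral value 0 deg.
#'
#' @param x A [knee_model].
#' @param flexion_range Range of TF flexion (deg) to sweep.
#' @param fixed_inputs Named values for inputs other than flexion
#'   (default: 0 for each).
#' @param parameters Which output parameters to draw (default: all).
#' @param ... Passed to [graphics::matplot()]-style panel plotting.
#' @return `x`, invisibly.
#' @export
plot.knee_model <- function(x, flexion_range = c(0, 120),
                            fixed_inputs = NULL, parameters = NULL, ...) {
  f <- seq(flexion_range[1], flexion_range[2], length.out = 200)
  nd <- data.frame(tf_flexion = f)
  for (nm in setdiff(x$input_names, "tf_flexion"))
    nd[[nm]] <- if (!is.null(fixed_inputs) && nm %in% names(fixed_inputs))
      fixed_inputs[[nm]] else 0
  pred <- predict(x, nd)
  pars <- if (is.null(parameters)) model_outputs(x) else parameters
  units <- ifelse(pars %in% KP_TRANSLATIONS, "mm", "deg")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_along(pars)) {
    graphics::plot(f, pred[[pars[k]]], type = "l",
                   xlab = "TF flexion (deg)",
                   ylab = paste0(pars[k], " (", units[k], ")"),
                   main = pars[k], ...)
  }
  invisible(x)
}

#' Plot a cross-validation report
#'
#' Bar chart of per-parameter mean RMSE across left-out participants, split
#' into TF and PF panels.
#'
#' @param x A `knee_cv` object from [knee_loocv()].
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.knee_cv <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(9, 4, 2, 1))
  on.exit(graphics::par(old))
  for (panel in list(c("TF", "tf"), c("PF", "pf"))) {
    nm <- if (panel[2] == "tf") KP_TF else KP_PF
    graphics::barplot(x$mean_param[nm], las = 2,
                      ylab = "mean RMSE (deg|mm)",
                      main = paste(panel[1], "joint"), ...)
  }
  invisible(x)
}
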