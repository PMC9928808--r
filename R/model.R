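# The polynomial coupling model: a set of per-output polynomial rows in one
# or more tibiofemoral input rotations, no cross terms. Class "knee_model".

# internal: basis term labels for a given input set and order,
# degree-major: (Intercept), x1, x2, ..., x1^2, x2^2, ...
basis_terms <- function(input_names, order) {
  c("(Intercept)",
    unlist(lapply(seq_len(order), function(k) {
      if (k == 1L) input_names else paste0(input_names, "^", k)
    })))
}

#' Construct a polynomial knee coupling model
#'
#' A model maps a small set of tibiofemoral input rotations (always including
#' TF flexion) to the remaining kinematic parameters of the knee-joint
#' complex. Each output parameter has its own polynomial row
#' \eqn{y = c_0 + \sum_i \sum_k c_{ki} x_i^k} with no cross terms; the basis
#' is \{1\} then all linear terms, then all quadratic terms, and so on up to
#' `order`. Input parameters are never modelled: prediction passes them
#' through unchanged.
#'
#' @param input_names Character vector of input parameter names; a subset of
#'   the six TF parameters that must contain `"tf_flexion"`.
#' @param coefficients Numeric matrix, one row per output parameter (row
#'   names = the 12 canonical parameters minus `input_names`), columns in
#'   basis order `(Intercept), x1, ..., x1^2, ...`.
#' @param order Polynomial order (default 2).
#' @param provenance Short label recording where the coefficients came from
#'   (e.g. `"packaged"` or `"fitted"`).
#' @param coef_strings Optional character matrix of the same shape holding
#'   the exact decimal strings the coefficients were parsed from, so that
#'   serialization can round-trip published values digit-for-digit.
#' @return An object of class `knee_model`.
#' @seealso [knee_package_model()] for the packaged reference models,
#'   [knee_fit()] to fit one, [predict.knee_model()].
#' @export
knee_model <- function(input_names, coefficients, order = 2L,
                       provenance = "user", coef_strings = NULL) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L)
    stop("order must be a positive integer", call. = FALSE)
  if (!length(input_names) || !all(input_names %in% KP_TF))
    stop("input_names must be a non-empty subset of the TF parameters: ",
         paste(KP_TF, collapse = ", "), call. = FALSE)
  if (anyDuplicated(input_names))
    stop("input_names contains duplicates", call. = FALSE)
  if (!"tf_flexion" %in% input_names)
    stop("input_names must contain tf_flexion (the primary motion)",
         call. = FALSE)
  outputs <- setdiff(KP_ALL, input_names)
  coefficients <- as.matrix(coefficients)
  if (is.null(rownames(coefficients)))
    stop("coefficients must have output parameter row names", call. = FALSE)
  if (!setequal(rownames(coefficients), outputs))
    stop("coefficient rows must be exactly the non-input parameters; ",
         "inputs never appear as outputs", call. = FALSE)
  terms <- basis_terms(input_names, order)
  if (ncol(coefficients) != length(terms))
    stop("expected ", length(terms), " coefficient columns for order ",
         order, " with ", length(input_names), " input(s); got ",
         ncol(coefficients), call. = FALSE)
  coefficients <- coefficients[outputs, , drop = FALSE]
  colnames(coefficients) <- terms
  storage.mode(coefficients) <- "double"
  if (any(!is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  if (!is.null(coef_strings)) {
    coef_strings <- as.matrix(coef_strings)
    stopifnot(identical(dim(coef_strings), dim(coefficients)))
    dimnames(coef_strings) <- dimnames(coefficients)
  }
  structure(
    list(input_names = input_names, order = order,
         coefficients = coefficients, coef_strings = coef_strings,
         provenance = as.character(provenance)[1L]),
    class = "knee_model"
  )
}

#' @export
print.knee_model <- function(x, digits = 4, ...) {
  cat(sprintf("<knee_model> %d-DOF polynomial coupling model (order %d, %s)\n",
              length(x$input_names), x$order, x$provenance))
  cat("  inputs : ", paste(x$input_names, collapse = ", "), "\n", sep = "")
  cat("  outputs: ", nrow(x$coefficients), " parameters\n", sep = "")
  print(round(x$coefficients, digits), ...)
  invisible(x)
}

#' @export
coef.knee_model <- function(object, ...) object$coefficients

# internal: output parameter names of a model
model_outputs <- function(model) rownames(model$coefficients)

#' Load a packaged reference coupling model
#'
#' Two reference coefficient sets ship with the package: `"table1_1dof"`,
#' an 11-output quadratic model driven by TF flexion alone, and
#' `"table1_2dof"`, a 10-output quadratic model driven by TF flexion and
#' external tibial rotation. Both were estimated from pooled biplane X-ray
#' kinematics of 10 healthy adults performing 6 activities of daily living;
#' coefficients are stored as decimal strings and reproduced exactly as
#' published. Units: inputs in degrees; outputs in mm (translations) or
#' degrees (rotations).
#'
#' @param name `"table1_1dof"` or `"table1_2dof"`.
#' @return A [knee_model] with provenance `"packaged"`.
#' @examples
#' m <- knee_package_model("table1_2dof")
#' predict(m, data.frame(tf_flexion = 30, tf_external_rotation = -5))
#' @export
knee_package_model <- function(name) {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "kneekin", mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = "character")
  if (!name %in% tab$model)
    stop("no such packaged model: '", name, "' (available: ",
         paste(unique(tab$model), collapse = ", "), ")", call. = FALSE)
  tab <- tab[tab$model == name, , drop = FALSE]
  inputs <- if (name == "table1_1dof") "tf_flexion" else
    c("tf_flexion", "tf_external_rotation")
  cols <- if (length(inputs) == 1L) c("c0", "c11", "c21") else
    c("c0", "c11", "c12", "c21", "c22")
  strs <- as.matrix(tab[, cols])
  rownames(strs) <- tab$parameter
  vals <- matrix(as.numeric(strs), nrow(strs), ncol(strs),
                 dimnames = dimnames(strs))
  knee_model(inputs, vals, order = 2L, provenance = "packaged",
             coef_strings = strs)
}

#' Predict knee kinematics from a coupling model
#'
#' Evaluates every output polynomial at the supplied input values and
#' returns the full 12-parameter description, with the input channels
#' passed through unchanged. Inputs are in degrees; supplying radians will
#' silently produce wrong values.
#'
#' @param object A [knee_model].
#' @param newdata A data frame (or matrix) containing one column per model
#'   input, a named numeric vector for a single observation, or a
#'   [knee_trial] whose input channels are used.
#' @param ... Unused.
#' @return A data frame with the 12 canonical parameter columns (one row per
#'   observation); if `newdata` is a `knee_trial`, a `knee_trial` whose
#'   output channels are the model predictions.
#' @examples
#' m1 <- knee_package_model("table1_1dof")
#' predict(m1, data.frame(tf_flexion = c(0, 45, 90)))
#' @export
predict.knee_model <- function(object, newdata, ...) {
  if (inherits(newdata, "knee_trial")) {
    pred <- predict(object, newdata$data)
    out <- newdata
    out$data <- pred
    return(out)
  }
  if (is.numeric(newdata) && !is.matrix(newdata))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$input_names, colnames(newdata))
  if (length(missing))
    stop("newdata is missing input value(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, object$input_names, drop = FALSE])
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("input values must be finite numerics (degrees)", call. = FALSE)
  B <- polynomial_basis(X, object$order)
  Y <- B %*% t(object$coefficients)          # rows x outputs
  res <- matrix(NA_real_, nrow(X), length(KP_ALL),
                dimnames = list(NULL, KP_ALL))
  res[, colnames(Y)] <- Y
  res[, object$input_names] <- X
  as.data.frame(res)
}

# internal: evaluate the cross-term-free polynomial basis at input matrix X
# (rows = observations, cols = inputs); degree-major column order.
polynomial_basis <- function(X, order) {
  X <- as.matrix(X)
  B <- cbind(1, do.call(cbind, lapply(seq_len(order), function(k) X^k)))
  colnames(B) <- basis_terms(colnames(X), order)
  B
}

#' Predict a full kinematic trial from input trajectories
#'
#' Convenience wrapper around [predict.knee_model()] for equal-length input
#' time series: returns the 12-parameter trajectory in which the input
#' channels are the supplied trajectories verbatim (so their prediction
#' error is zero by construction) and every other channel is the model
#' evaluation, sample by sample.
#'
#' @param model A [knee_model].
#' @param inputs Data frame (or named list of equal-length vectors) with one
#'   column per model input, in degrees.
#' @return Data frame with the 12 canonical parameter columns.
#' @export
predict_trial <- function(model, inputs) {
  n <- vapply(inputs, length, 1L)
  if (length(unique(n)) != 1L)
    stop("input trajectories must have equal length", call. = FALSE)
  predict(model, as.data.frame(inputs))
}
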