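# Plain-text serialization: trial CSV files and model JSON files.
#
# Trial CSV dialect (invented here; the source measurements were never
# deposited in a standard format): header row, UTF-8, columns
#   participant, activity, time_index, <12 canonical parameters>
# plus a bicondylar_width column (mm, constant within a trial). One row per
# time point; rows of one trial are contiguous in time_index order.

#' Read kinematic trials from CSV
#'
#' Parses a trial CSV (see Details) into a [knee_cohort], grouping rows by
#' (participant, activity) and ordering each trial by `time_index`.
#'
#' @details The file must contain the columns `participant`, `activity`,
#' `time_index` and the 12 canonical parameter names from
#' [knee_parameters()]. Bicondylar widths come from a `bicondylar_width`
#' column (constant within each trial) or, if that column is absent, from
#' the `default_width` argument. Missing columns, non-finite values and
#' duplicate (participant, activity, time_index) rows are hard errors that
#' name the offending column or row.
#'
#' @param path CSV file path.
#' @param default_width Fallback bicondylar width in mm used when the file
#'   has no `bicondylar_width` column; `NULL` (default) makes that an error.
#' @param sample_rate Sample rate in Hz for raw trials; `NA` (default) marks
#'   trials as normalized-time.
#' @return A [knee_cohort].
#' @export
read_trials <- function(path, default_width = NULL, sample_rate = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "activity", "time_index", KP_ALL)
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("trial file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  key <- paste(df$participant, df$activity, df$time_index, sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    stop("duplicate (participant, activity, time_index) at data row ", row,
         " of ", path, call. = FALSE)
  }
  vals <- as.matrix(df[, KP_ALL])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    stop("non-finite value in column ", KP_ALL[bad[1L, 2L]],
         ", data row ", bad[1L, 1L], " of ", path, call. = FALSE)
  }
  has_width <- "bicondylar_width" %in% colnames(df)
  if (!has_width && is.null(default_width))
    stop("trial file ", path, " has no bicondylar_width column; ",
         "supply default_width to read it anyway", call. = FALSE)
  groups <- split(seq_len(nrow(df)),
                  list(df$participant, df$activity), drop = TRUE)
  # keep first-appearance order rather than split()'s alphabetical order
  groups <- groups[order(vapply(groups, min, 1L))]
  trials <- lapply(groups, function(idx) {
    idx <- idx[order(df$time_index[idx])]
    w <- if (has_width) unique(df$bicondylar_width[idx]) else default_width
    if (length(w) != 1L)
      stop("bicondylar_width varies within trial ",
           df$participant[idx[1L]], "/", df$activity[idx[1L]], call. = FALSE)
    knee_trial(df$participant[idx[1L]], df$activity[idx[1L]],
               df[idx, KP_ALL], bicondylar_width = w,
               sample_rate = sample_rate, normalized = is.na(sample_rate))
  })
  knee_cohort(trials)
}

#' Write kinematic trials to CSV
#'
#' Inverse of [read_trials()]: writes one row per time point in the
#' canonical column order plus a `bicondylar_width` column.
#'
#' @param cohort A [knee_cohort] (or single [knee_trial]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  if (inherits(cohort, "knee_trial")) cohort <- knee_cohort(list(cohort))
  rows <- do.call(rbind, lapply(cohort, function(t) {
    cbind(as.data.frame(t), bicondylar_width = t$bicondylar_width)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: exact decimal strings for a model's coefficients
coef_strings_of <- function(model) {
  if (!is.null(model$coef_strings)) return(model$coef_strings)
  s <- matrix(sprintf("%.17g", model$coefficients),
              nrow(model$coefficients), ncol(model$coefficients),
              dimnames = dimnames(model$coefficients))
  s
}

#' Write a coupling model to JSON
#'
#' Serializes a [knee_model] with coefficients as decimal strings, so that
#' packaged reference coefficients survive a round trip digit-for-digit and
#' fitted coefficients round-trip to within one unit in the last place.
#'
#' @param model A [knee_model].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "knee_model"))
  s <- coef_strings_of(model)
  coeffs <- lapply(rownames(s), function(p) {
    list(terms = colnames(s), values = unname(s[p, ]))
  })
  names(coeffs) <- rownames(s)
  obj <- list(format = "kneekin-model", version = 1L,
              input_names = model$input_names, order = model$order,
              provenance = model$provenance, coefficients = coeffs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a coupling model from JSON
#'
#' @param path JSON file written by [write_model()] (or hand-authored in the
#'   same layout). Input/output consistency is validated: a model whose
#'   coefficient rows include one of its own inputs is rejected.
#' @return A [knee_model].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  need <- c("input_names", "order", "coefficients")
  if (!all(need %in% names(obj)))
    stop("model JSON missing field(s): ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  inputs <- unlist(obj$input_names)
  order <- as.integer(obj$order)
  outputs <- names(obj$coefficients)
  if (any(inputs %in% outputs))
    stop("invalid model JSON: input parameter(s) listed as outputs: ",
         paste(intersect(inputs, outputs), collapse = ", "), call. = FALSE)
  terms <- basis_terms(inputs, order)
  strs <- t(vapply(obj$coefficients, function(row) {
    got <- unlist(row$terms)
    if (!identical(got, terms))
      stop("invalid model JSON: basis term labels do not match inputs/order",
           call. = FALSE)
    as.character(unlist(row$values))
  }, character(length(terms))))
  vals <- matrix(as.numeric(strs), nrow(strs), ncol(strs))
  rownames(vals) <- rownames(strs) <- outputs
  if (any(!is.finite(vals)))
    stop("invalid model JSON: non-numeric coefficient value", call. = FALSE)
  knee_model(inputs, vals, order = order,
             provenance = if (!is.null(obj$provenance)) obj$provenance
             else "file",
             coef_strings = strs)
}
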