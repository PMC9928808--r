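# Containers for kinematic time series: one trial (participant x activity)
# and a cohort (list of trials).

#' Construct a kinematic trial
#'
#' A trial is one participant performing one activity: an ordered time series
#' of the 12 canonical knee parameters together with the participant's
#' femoral bicondylar width. Preprocessed trials live on a normalized time
#' grid of 201 points; raw trials carry a sample rate in Hz.
#'
#' @param participant Participant label (coerced to character).
#' @param activity One of [knee_activities()].
#' @param data Data frame or matrix with the 12 canonical parameter columns
#'   (see [knee_parameters()]); one row per time point; no missing values.
#' @param bicondylar_width Femoral bicondylar width in mm (> 0).
#' @param sample_rate Sampling rate in Hz for raw trials, or `NA` for trials
#'   on a normalized time grid.
#' @param normalized Logical; `TRUE` once the trial has been resampled to a
#'   normalized \[0, 1\] time grid.
#' @return An object of class `knee_trial`.
#' @examples
#' dat <- as.data.frame(matrix(0, 201, 12,
#'   dimnames = list(NULL, knee_parameters())))
#' dat$tf_flexion <- seq(0, 90, length.out = 201)
#' tr <- knee_trial("P1", "level_walk", dat, bicondylar_width = 81.7,
#'                  normalized = TRUE)
#' tr
#' @export
knee_trial <- function(participant, activity, data, bicondylar_width,
                       sample_rate = NA_real_, normalized = FALSE) {
  participant <- as.character(participant)
  activity <- as.character(activity)
  if (!activity %in% KP_ACTIVITIES)
    stop("unknown activity '", activity, "'; expected one of: ",
         paste(KP_ACTIVITIES, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)
  check_param_columns(data, "trial data")
  data <- data[, KP_ALL, drop = FALSE]
  rownames(data) <- NULL
  m <- as.matrix(data)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("trial data must be finite numeric values", call. = FALSE)
  if (nrow(m) < 1L) stop("trial has no samples", call. = FALSE)
  if (!is.numeric(bicondylar_width) || length(bicondylar_width) != 1L ||
      !is.finite(bicondylar_width) || bicondylar_width <= 0)
    stop("bicondylar_width must be a single positive number (mm)",
         call. = FALSE)
  structure(
    list(participant = participant, activity = activity,
         data = as.data.frame(m), bicondylar_width = bicondylar_width,
         sample_rate = sample_rate, normalized = isTRUE(normalized)),
    class = "knee_trial"
  )
}

#' @export
print.knee_trial <- function(x, ...) {
  cat(sprintf("<knee_trial> %s / %s: %d samples (%s), bicondylar width %.1f mm\n",
              x$participant, x$activity, nrow(x$data),
              if (x$normalized) "normalized time"
              else sprintf("%.0f Hz", x$sample_rate),
              x$bicondylar_width))
  invisible(x)
}

#' @export
as.data.frame.knee_trial <- function(x, ...) {
  cbind(
    data.frame(participant = x$participant, activity = x$activity,
               time_index = seq_len(nrow(x$data)) - 1L,
               stringsAsFactors = FALSE),
    x$data
  )
}

#' Construct a cohort of kinematic trials
#'
#' A cohort bundles trials from one or more participants; it is the input to
#' [knee_fit()], [knee_loocv()] and the preprocessing helpers. Duplicate
#' (participant, activity) pairs are rejected.
#'
#' @param trials List of [knee_trial] objects.
#' @return An object of class `knee_cohort` (a list of trials).
#' @seealso [simulate_cohort()] to generate one synthetically,
#'   [read_trials()] to load one from CSV.
#' @export
knee_cohort <- function(trials) {
  if (inherits(trials, "knee_trial")) trials <- list(trials)
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "knee_trial")))
    stop("trials must be a non-empty list of knee_trial objects",
         call. = FALSE)
  key <- vapply(trials, function(t) paste(t$participant, t$activity), "")
  if (anyDuplicated(key))
    stop("duplicate (participant, activity) trial(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  structure(unname(trials), class = "knee_cohort")
}

#' @export
print.knee_cohort <- function(x, ...) {
  p <- cohort_participants(x)
  cat(sprintf("<knee_cohort> %d trials, %d participant(s): %s\n",
              length(x), length(p), paste(p, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.knee_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, as.data.frame))
}

#' Participants present in a cohort
#' @param cohort A `knee_cohort`.
#' @return Character vector of unique participant labels, in first-seen order.
#' @export
cohort_participants <- function(cohort) {
  unique(vapply(cohort, function(t) t$participant, ""))
}

# internal: pooled observation matrix (rows x 12) across all trials
cohort_observations <- function(cohort) {
  as.matrix(do.call(rbind, lapply(cohort, function(t) t$data)))
}
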