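# Canonical 12-parameter vocabulary for the knee-joint complex.
# Order is fixed (6 tibiofemoral then 6 patellofemoral) and every tabular
# structure in the package uses it; rotations are degrees, translations mm.

KP_TF <- c("tf_lateral_shift", "tf_anterior_drawer", "tf_joint_distraction",
           "tf_flexion", "tf_abduction", "tf_external_rotation")
KP_PF <- c("pf_lateral_shift", "pf_anterior_translation",
           "pf_superior_translation", "pf_flexion", "pf_lateral_rotation",
           "pf_lateral_tilt")
KP_ALL <- c(KP_TF, KP_PF)

KP_TRANSLATIONS <- c("tf_lateral_shift", "tf_anterior_drawer",
                     "tf_joint_distraction", "pf_lateral_shift",
                     "pf_anterior_translation", "pf_superior_translation")
KP_ROTATIONS <- setdiff(KP_ALL, KP_TRANSLATIONS)

KP_ACTIVITIES <- c("open_flexion", "open_extension", "level_walk",
                   "downhill_walk", "stair_ascent", "stair_descent")

#' Canonical knee kinematic parameters
#'
#' The knee-joint complex is described by 12 kinematic parameters: six at the
#' tibiofemoral (TF) joint (lateral shift, anterior drawer, joint distraction,
#' flexion, abduction, external rotation) and six at the patellofemoral (PF)
#' joint (lateral shift, anterior translation, superior translation, flexion,
#' lateral rotation, lateral tilt). Translations are in millimetres,
#' rotations in degrees, and the order returned here is the canonical column
#' order used throughout the package.
#'
#' @param joint One of `"all"`, `"tf"`, `"pf"`.
#' @return Character vector of parameter names, or a data frame with units
#'   when `details = TRUE`.
#' @param details If `TRUE` return a data frame with `parameter`, `joint`,
#'   `kind` (rotation/translation) and `unit` columns.
#' @examples
#' knee_parameters("tf")
#' knee_parameters(details = TRUE)
#' @export
knee_parameters <- function(joint = c("all", "tf", "pf"), details = FALSE) {
  joint <- match.arg(joint)
  nm <- switch(joint, all = KP_ALL, tf = KP_TF, pf = KP_PF)
  if (!details) return(nm)
  data.frame(
    parameter = nm,
    joint = ifelse(nm %in% KP_TF, "tf", "pf"),
    kind = ifelse(nm %in% KP_TRANSLATIONS, "translation", "rotation"),
    unit = ifelse(nm %in% KP_TRANSLATIONS, "mm", "deg"),
    stringsAsFactors = FALSE
  )
}

#' Recognised activity labels
#'
#' The six functional activities a cohort may contain: open-chain knee
#' flexion and extension, level walking, downhill walking, stair ascent and
#' stair descent.
#'
#' @return Character vector of the six activity labels.
#' @export
knee_activities <- function() KP_ACTIVITIES

# internal: check a parameter matrix/data.frame has the 12 canonical columns
check_param_columns <- function(x, where = "data") {
  missing <- setdiff(KP_ALL, colnames(x))
  if (length(missing))
    stop(where, " is missing required parameter column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
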