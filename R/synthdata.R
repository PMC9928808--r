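# Synthetic cohorts and synthetic bone geometry with known ground truth.
# The generator is statistical: it emulates the shape of multi-activity
# knee kinematics (smooth flexion profiles, weakly coupled external
# rotation, participant-level coefficient variation, channel noise) without
# any biomechanical simulation.

# internal: deterministic substream seed for (participant i, trial j);
# counter-based so streams are independent of generation order
derive_seed <- function(seed, i, j = 0L) {
  as.integer(((seed %% 2147483629) * 1009 + i * 10007 + j * 101) %%
               2147483629)
}

# internal: stylized flexion profile (deg) on normalized time t in [0, 1].
# Open-chain: a single 0 -> amplitude (or reverse) sweep; gait activities:
# a small stance bump plus a large swing bump. Shapes are fixtures, not
# measurements.
flexion_profile <- function(activity, t) {
  bump <- function(c0, w) exp(-(t - c0)^2 / (2 * w^2))
  switch(activity,
    open_flexion = 100 * (1 - cos(pi * t)) / 2,
    open_extension = 100 * (1 + cos(pi * t)) / 2,
    level_walk = 3 + 15 * bump(0.15, 0.08) + 62 * bump(0.75, 0.09),
    downhill_walk = 4 + 22 * bump(0.18, 0.09) + 66 * bump(0.75, 0.09),
    stair_ascent = 8 + 52 * bump(0.05, 0.14) + 68 * bump(0.80, 0.10),
    stair_descent = 10 + 14 * bump(0.20, 0.10) + 75 * bump(0.78, 0.10),
    stop("no flexion profile for activity '", activity, "'", call. = FALSE))
}

#' Simulate a synthetic knee kinematics cohort
#'
#' Generates a cohort of trials from a known ground-truth coupling model so
#' that fitting, cross-validation and model selection can be exercised end
#' to end. Per participant, every ground-truth coefficient is perturbed
#' multiplicatively by `1 + N(0, participant_sd)`; per trial, a smooth
#' stylized flexion trajectory is generated for the activity, external
#' tibial rotation is built as a weakly flexion-coupled signal (squared
#' correlation with flexion approximately `coupling`, emulating the
#' observation that external rotation is only weakly related to flexion),
#' the perturbed model is evaluated at the inputs, and independent Gaussian
#' measurement noise is added to every *output* channel (rotations in deg,
#' translations in mm). Input channels are kept noise-free: they are the
#' signals that drive the model, and keeping them clean makes the
#' ordinary-least-squares sampling theory exact for parameter-recovery
#' checks. A bicondylar width is drawn per participant.
#'
#' The same `seed` always reproduces the same cohort, regardless of how
#' many participants or activities are requested, via counter-based
#' per-trial substreams.
#'
#' @param n_participants Number of participants (default 10).
#' @param activities Subset of [knee_activities()] (default: all 6).
#' @param n_points Samples per trial on the normalized grid (default 201).
#' @param ground_truth A [knee_model] (default: the packaged 2-DOF model).
#' @param participant_sd Relative SD of the per-participant multiplicative
#'   coefficient perturbation (0 = identical participants; default 0.1).
#' @param noise_sd_rotation,noise_sd_translation Measurement noise SD on
#'   output rotation (deg) and translation (mm) channels; defaults 0.5,
#'   commensurate with reported biplane X-ray kinematic accuracy.
#' @param coupling Target squared correlation between external rotation and
#'   flexion when external rotation is a model input (default 0.3).
#' @param ext_rot_mean,ext_rot_sd Mean and SD (deg) of the generated
#'   external-rotation signal (defaults -5 and 5).
#' @param width_mean,width_sd Bicondylar width distribution in mm
#'   (defaults 81.7 and 4; widths are truncated below at 40 mm).
#' @param seed Integer seed; fully determines the output.
#' @return A [knee_cohort] of normalized-time trials.
#' @examples
#' cohort <- simulate_cohort(n_participants = 2, seed = 42)
#' cohort
#' @export
simulate_cohort <- function(n_participants = 10L,
                            activities = knee_activities(),
                            n_points = 201L,
                            ground_truth = knee_package_model("table1_2dof"),
                            participant_sd = 0.1,
                            noise_sd_rotation = 0.5,
                            noise_sd_translation = 0.5,
                            coupling = 0.3,
                            ext_rot_mean = -5, ext_rot_sd = 5,
                            width_mean = 81.7, width_sd = 4,
                            seed = 1L) {
  stopifnot(n_participants >= 1L, n_points >= 2L,
            inherits(ground_truth, "knee_model"),
            participant_sd >= 0, noise_sd_rotation >= 0,
            noise_sd_translation >= 0, width_mean > 0, width_sd >= 0)
  if (coupling < 0 || coupling > 1)
    stop("coupling must be a squared correlation in [0, 1]", call. = FALSE)
  activities <- match.arg(activities, KP_ACTIVITIES, several.ok = TRUE)
  inputs <- ground_truth$input_names
  outputs <- model_outputs(ground_truth)
  tt <- seq(0, 1, length.out = n_points)
  trials <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    set.seed(derive_seed(seed, i, 0L))
    pert <- ground_truth$coefficients *
      (1 + stats::rnorm(length(ground_truth$coefficients),
                        sd = participant_sd))
    width <- max(40, stats::rnorm(1, width_mean, width_sd))
    for (j in seq_along(activities)) {
      act <- activities[j]
      set.seed(derive_seed(seed, i, j))
      f <- flexion_profile(act, tt)
      inp <- data.frame(tf_flexion = f)
      if ("tf_external_rotation" %in% inputs) {
        # smooth independent component: low-order random Fourier series
        amp <- stats::rnorm(3); phase <- stats::runif(3, 0, 2 * pi)
        g <- amp[1] * sin(2 * pi * tt + phase[1]) +
          amp[2] * sin(4 * pi * tt + phase[2]) +
          amp[3] * sin(6 * pi * tt + phase[3])
        z1 <- (f - mean(f)) / stats::sd(f)
        z2 <- (g - mean(g)) / stats::sd(g)
        # orthogonalize the independent component against flexion so the
        # per-trial squared correlation equals `coupling` exactly
        z2 <- z2 - mean(z2 * z1) / mean(z1 * z1) * z1
        z2 <- z2 / stats::sd(z2)
        inp$tf_external_rotation <- ext_rot_mean +
          ext_rot_sd * (sqrt(coupling) * z1 + sqrt(1 - coupling) * z2)
      }
      extra <- setdiff(inputs, names(inp))
      for (nm in extra) {  # other TF inputs: small smooth signals
        a <- stats::rnorm(2); ph <- stats::runif(2, 0, 2 * pi)
        inp[[nm]] <- 2 * (a[1] * sin(2 * pi * tt + ph[1]) +
                            a[2] * sin(4 * pi * tt + ph[2]))
      }
      Y <- polynomial_basis(as.matrix(inp[, inputs, drop = FALSE]),
                            ground_truth$order) %*% t(pert)
      noise_sd <- ifelse(colnames(Y) %in% KP_TRANSLATIONS,
                         noise_sd_translation, noise_sd_rotation)
      Y <- Y + matrix(stats::rnorm(length(Y)), nrow(Y), ncol(Y)) %*%
        diag(noise_sd, length(noise_sd))
      dat <- matrix(NA_real_, n_points, 12,
                    dimnames = list(NULL, KP_ALL))
      dat[, outputs] <- Y
      dat[, inputs] <- as.matrix(inp[, inputs])
      trials[[length(trials) + 1L]] <-
        knee_trial(pid, act, as.data.frame(dat), bicondylar_width = width,
                   normalized = TRUE)
    }
  }
  knee_cohort(trials)
}

#' Simulate a cohort from a fitted or packaged model
#'
#' `simulate()` method for [knee_model]: draws a synthetic cohort using the
#' model as ground truth. Equivalent to
#' `simulate_cohort(ground_truth = object, ...)`.
#'
#' @param object A [knee_model].
#' @param nsim Number of participants to simulate (default 10).
#' @param seed Integer seed (default 1).
#' @param ... Further arguments passed to [simulate_cohort()].
#' @return A [knee_cohort].
#' @export
simulate.knee_model <- function(object, nsim = 10L, seed = 1L, ...) {
  simulate_cohort(n_participants = nsim, ground_truth = object,
                  seed = if (is.null(seed)) 1L else seed, ...)
}

#' Sample synthetic bone surfaces with known frames
#'
#' Generates labelled point clouds for the structures the frame builders
#' consume — a posterior/distal condylar cylinder patch, femoral and tibial
#' diaphyseal cone patches, a patellar ellipsoid cloud — together with the
#' landmarks (notch apex, plateau centers, eminence midpoint, ridge
#' direction) and the exact bone frames this geometry implies. Optionally
#' adds isotropic Gaussian noise to the surface points and applies a rigid
#' motion to everything, so frame-builder accuracy and equivariance can be
#' tested against recorded ground truth.
#'
#' In the canonical (untransformed) pose the femoral and tibial ground-truth
#' frames are the identity basis at the origin and the patellar frame is the
#' identity basis at the patellar centroid.
#'
#' @param seed Integer seed.
#' @param noise_sd Isotropic point noise SD in mm (default 0; landmarks are
#'   never noised).
#' @param transform A [rigid_transform] applied to all points, landmarks
#'   and ground-truth frames (default: identity).
#' @param condyle_radius,cone_half_angle Geometry parameters (mm, radians).
#' @return List with point matrices (`condyle_points`,
#'   `femur_diaphysis_points`, `tibia_diaphysis_points`, `patella_points`),
#'   `landmarks` (list) and ground-truth `frames` (list of [bone_frame]).
#' @export
sample_bone_surfaces <- function(seed = 1L, noise_sd = 0,
                                 transform = rigid_transform(),
                                 condyle_radius = 20,
                                 cone_half_angle = 4 * pi / 180) {
  stopifnot(noise_sd >= 0, condyle_radius > 0, cone_half_angle > 0,
            cone_half_angle < pi / 2)
  set.seed(derive_seed(seed, 9999L, 0L))
  # condylar cylinder patch about the x axis, posterior-distal quadrant
  nx <- 20L; nth <- 10L
  xs <- seq(-25, 25, length.out = nx)
  ths <- seq(pi, 1.5 * pi, length.out = nth)
  condyle <- cbind(rep(xs, each = nth),
                   condyle_radius * cos(rep(ths, nx)),
                   condyle_radius * sin(rep(ths, nx)))
  # femoral diaphysis: cone opening proximally (+z), apex at z = -50
  cone_patch <- function(z_lo, z_hi, z_apex, sign_axis) {
    zs <- seq(z_lo, z_hi, length.out = 15L)
    phs <- seq(0, 2 * pi, length.out = 13L)[-13L]
    g <- expand.grid(z = zs, ph = phs)
    r <- abs(g$z - z_apex) * tan(cone_half_angle)
    cbind(r * cos(g$ph), r * sin(g$ph), g$z)
  }
  femur_shaft <- cone_patch(60, 140, -50)
  tibia_shaft <- cone_patch(-140, -60, -160)
  # patellar ellipsoid, symmetric parametric grid so the inertia axes are
  # exact; thinnest in y (anteroposterior) -> largest inertia about y
  us <- seq(-0.9, 0.9, length.out = 10L)
  phs <- seq(0, 2 * pi, length.out = 21L)[-21L]
  g <- expand.grid(u = us, ph = phs)
  semi <- c(22, 10, 25)
  pat_center <- c(0, 40, 10)
  patella <- cbind(semi[1] * sqrt(1 - g$u^2) * cos(g$ph),
                   semi[2] * sqrt(1 - g$u^2) * sin(g$ph),
                   semi[3] * g$u)
  patella <- sweep(patella, 2, pat_center, "+")
  landmarks <- list(
    notch_apex = c(0, -5, 0),
    plateau_centers = rbind(c(-20, 0, -2), c(20, 0, -2)),
    eminence_midpoint = c(0, 0, -1),
    ridge_direction = c(0, 0, 1),
    right_hint = c(1, 0, 0), proximal_hint = c(0, 0, 1),
    anterior_hint = c(0, 1, 0)
  )
  frames <- list(
    femur = bone_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    tibia = bone_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    patella = bone_frame(pat_center, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  )
  addnoise <- function(p) p + matrix(stats::rnorm(length(p), sd = noise_sd),
                                     nrow(p), ncol(p))
  if (noise_sd > 0) {
    condyle <- addnoise(condyle); femur_shaft <- addnoise(femur_shaft)
    tibia_shaft <- addnoise(tibia_shaft); patella <- addnoise(patella)
  }
  tp <- function(p) t(transform$R %*% t(p) + transform$t)
  tv <- function(v) as.numeric(transform$R %*% v)
  tpt <- function(v) as.numeric(transform$R %*% v + transform$t)
  tf_frame <- function(fr) bone_frame(tpt(fr$origin),
                                      tv(fr$axes[, 1]), tv(fr$axes[, 2]),
                                      tv(fr$axes[, 3]))
  list(
    condyle_points = tp(condyle),
    femur_diaphysis_points = tp(femur_shaft),
    tibia_diaphysis_points = tp(tibia_shaft),
    patella_points = tp(patella),
    landmarks = list(
      notch_apex = tpt(landmarks$notch_apex),
      plateau_centers = tp(landmarks$plateau_centers),
      eminence_midpoint = tpt(landmarks$eminence_midpoint),
      ridge_direction = tv(landmarks$ridge_direction),
      right_hint = tv(landmarks$right_hint),
      proximal_hint = tv(landmarks$proximal_hint),
      anterior_hint = tv(landmarks$anterior_hint)
    ),
    frames = lapply(frames, tf_frame)
  )
}
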