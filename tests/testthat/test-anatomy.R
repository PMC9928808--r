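# Surface fitting, frame construction, and the joint coordinate system.

cylinder_points <- function(n = 200, r = 20, noise = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n, -30, 30); th <- runif(n, 0, 2 * pi)
  pts <- cbind(x, r * cos(th), r * sin(th))
  pts + matrix(rnorm(3 * n, sd = noise), n, 3)
}

cone_points <- function(n = 300, half_angle = 5 * pi / 180, noise = 0,
                        seed = 1) {
  set.seed(seed)
  h <- runif(n, 20, 100); th <- runif(n, 0, 2 * pi)
  r <- h * tan(half_angle)
  pts <- cbind(r * cos(th), r * sin(th), h)
  pts + matrix(rnorm(3 * n, sd = noise), n, 3)
}

test_that("cylinder fitting recovers exact and noisy cylinders", {
  fit <- fit_cylinder(cylinder_points())
  expect_equal(abs(fit$axis[1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$axis[2:3])), 1e-8)
  expect_equal(fit$radius, 20, tolerance = 1e-8)
  expect_lt(max(abs(fit$point[2:3])), 1e-8)

  # noisy: radius unbiased within a few Monte-Carlo standard errors
  sigma <- 0.1; n <- 200
  radii <- vapply(1:5, function(s)
    fit_cylinder(cylinder_points(n, noise = sigma, seed = s))$radius, 0)
  expect_lt(max(abs(radii - 20)), 3 * sigma / sqrt(n) * 5)

  set.seed(4)
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(fit_cylinder(flat), "degenerate")
})

test_that("cone fitting recovers axis, apex and half-angle", {
  fit <- fit_cone(cone_points(), axis_hint = c(0, 0, 1))
  expect_equal(fit$axis, c(0, 0, 1), tolerance = 1e-6)
  expect_equal(fit$half_angle, 5 * pi / 180, tolerance = 1e-6)
  expect_lt(max(abs(fit$apex)), 1e-4)

  # noisy recovery within Monte-Carlo bound
  angles <- vapply(1:5, function(s)
    fit_cone(cone_points(noise = 0.05, seed = s))$half_angle, 0)
  expect_lt(max(abs(angles - 5 * pi / 180)), 0.2 * pi / 180)

  # near-cylindrical data: small recovered half-angle, no crash
  slim <- fit_cone(cone_points(half_angle = 0.25 * pi / 180, seed = 7))
  expect_lt(slim$half_angle, 1 * pi / 180)
})

test_that("principal axes recover box and rotated-ellipsoid orientations", {
  g <- as.matrix(expand.grid(x = seq(-3, 3), y = seq(-1, 1),
                             z = seq(-6, 6)))
  pa <- principal_axes(g)
  # largest inertia about the axis of least spread (y), smallest about z
  expect_equal(abs(pa$axes[, 1]), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(abs(pa$axes[, 3]), c(0, 0, 1), tolerance = 1e-10)

  set.seed(5)
  R <- random_rotation()
  rot <- t(R %*% t(g))
  pa2 <- principal_axes(rot)
  for (k in 1:3) {
    expect_equal(abs(sum(pa2$axes[, k] * (R %*% pa$axes[, k]))), 1,
                 tolerance = 1e-6)
  }

  # spherical point set: ambiguous by construction
  cube <- as.matrix(expand.grid(x = seq(-2, 2), y = seq(-2, 2),
                                z = seq(-2, 2)))
  expect_error(principal_axes(cube, tol = 1e-6), "ambiguous")
})

test_that("frame builders reproduce the constructed canonical geometry", {
  s <- sample_bone_surfaces(seed = 3)
  fem <- build_femoral_frame(s$condyle_points, s$femur_diaphysis_points,
                             s$landmarks$notch_apex)
  expect_equal(fem$axes, s$frames$femur$axes, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fem$origin, s$frames$femur$origin, tolerance = 1e-6)

  tib <- build_tibial_frame(s$tibia_diaphysis_points,
                            s$landmarks$plateau_centers,
                            s$landmarks$eminence_midpoint, fem)
  expect_equal(tib$axes, s$frames$tibia$axes, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tib$origin, s$frames$tibia$origin, tolerance = 1e-6)

  pat <- build_patellar_frame(s$patella_points, s$landmarks$ridge_direction)
  expect_equal(pat$axes, s$frames$patella$axes, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pat$origin, s$frames$patella$origin, tolerance = 1e-6)

  expect_error(build_tibial_frame(s$tibia_diaphysis_points,
                                  rbind(c(1, 2, 3), c(1, 2, 3)),
                                  s$landmarks$eminence_midpoint, fem),
               "coincide")
})

test_that("frame construction is equivariant under rigid motion", {
  set.seed(6)
  R <- random_rotation(); tvec <- c(12, -40, 7)
  s0 <- sample_bone_surfaces(seed = 3)
  s1 <- sample_bone_surfaces(seed = 3,
                             transform = rigid_transform(R, tvec))
  fem0 <- build_femoral_frame(s0$condyle_points, s0$femur_diaphysis_points,
                              s0$landmarks$notch_apex)
  fem1 <- build_femoral_frame(s1$condyle_points, s1$femur_diaphysis_points,
                              s1$landmarks$notch_apex,
                              right_hint = s1$landmarks$right_hint,
                              proximal_hint = s1$landmarks$proximal_hint)
  expect_equal(fem1$axes, R %*% fem0$axes, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fem1$origin, as.numeric(R %*% fem0$origin + tvec),
               tolerance = 1e-6)
})

test_that("degenerate femoral geometry (L1 parallel to X) is rejected", {
  s <- sample_bone_surfaces(seed = 3)
  # rotate the diaphysis so its long axis matches the cylinder axis
  Rxz <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
  shaft_along_x <- t(Rxz %*% t(s$femur_diaphysis_points))
  expect_error(build_femoral_frame(s$condyle_points, shaft_along_x,
                                   s$landmarks$notch_apex,
                                   proximal_hint = c(1, 0, 0)),
               "parallel")
})

test_that("JCS decomposition isolates single-axis motions", {
  parent <- bone_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # identical poses: all six parameters zero
  p0 <- jcs_decompose(parent, parent)
  expect_equal(unname(p0), rep(0, 6))

  # pure rotation about the parent fixed axis: flexion only
  spec <- jcs_spec()
  rel <- jcs_compose(c(shift = 0, drawer = 0, distraction = 0,
                       flexion = 30, abduction = 0, rotation = 0), spec)
  child <- bone_frame(rel$t, rel$R[, 1], rel$R[, 2], rel$R[, 3])
  p30 <- jcs_decompose(parent, child, spec)
  expect_equal(unname(p30),
               c(0, 0, 0, 30, 0, 0), tolerance = 1e-10)
  # and the relative rotation really is about the x axis
  expect_equal(abs(rel$R[1, 1]), 1, tolerance = 1e-12)

  # perturbing flexion only changes the parent-axis rotation
  rel2 <- jcs_compose(c(shift = 1, drawer = 2, distraction = 3,
                        flexion = 35, abduction = 5, rotation = -8), spec)
  rel3 <- jcs_compose(c(shift = 1, drawer = 2, distraction = 3,
                        flexion = 36, abduction = 5, rotation = -8), spec)
  d <- rel3$R %*% t(rel2$R)   # should be a rotation about parent x
  expect_equal(abs(d[1, 1]), 1, tolerance = 1e-9)
})

test_that("compose and decompose are mutual inverses away from gimbal lock", {
  set.seed(9)
  spec <- jcs_spec()
  for (k in 1:200) {
    params <- c(shift = runif(1, -20, 20), drawer = runif(1, -20, 20),
                distraction = runif(1, -20, 20),
                flexion = runif(1, -120, 120), abduction = runif(1, -45, 45),
                rotation = runif(1, -45, 45))
    rel <- jcs_compose(params, spec)
    back <- kneekin:::jcs_decompose_rel(rel, spec)
    expect_equal(back, params, tolerance = 1e-9)
  }
  expect_error(jcs_compose(c(shift = 0, drawer = 0, distraction = 0,
                             flexion = 0, abduction = 95, rotation = 0)),
               "below 90")
  # near-parallel fixed axes trip the singularity guard
  rel <- jcs_compose(c(shift = 0, drawer = 0, distraction = 0,
                       flexion = 0, abduction = 89.95, rotation = 0))
  expect_error(kneekin:::jcs_decompose_rel(rel), "singularity")
})

test_that("trajectory re-expression shifts and round-trips correctly", {
  co <- tiny_cohort(seed = 41)
  tr <- co[[1]]
  same <- reexpress_trajectory(tr)
  expect_equal(as.matrix(same$data), as.matrix(tr$data), tolerance = 1e-9)

  # shifting the tibial origin 10 mm along its own fixed axis adds 10 mm
  # of distraction and leaves every rotation unchanged
  off <- rigid_transform(t = c(0, 0, 10))
  shifted <- reexpress_trajectory(tr, tibia_offset = off)
  expect_equal(shifted$data$tf_joint_distraction,
               tr$data$tf_joint_distraction + 10, tolerance = 1e-9)
  for (p in c("tf_flexion", "tf_abduction", "tf_external_rotation"))
    expect_equal(shifted$data[[p]], tr$data[[p]], tolerance = 1e-9)

  # random offsets, then their inverses, restore the original trial
  set.seed(10)
  a5 <- 5 * pi / 180
  Rz5 <- rbind(c(cos(a5), -sin(a5), 0), c(sin(a5), cos(a5), 0), c(0, 0, 1))
  offs <- list(femur = rigid_transform(Rz5, c(1, -2, 3)),
               tibia = rigid_transform(t = c(-4, 2, 1)),
               patella = rigid_transform(t = c(2, 0, -1)))
  fwd <- reexpress_trajectory(tr, offs$femur, offs$tibia, offs$patella)
  back <- reexpress_trajectory(fwd, invert_rigid(offs$femur),
                               invert_rigid(offs$tibia),
                               invert_rigid(offs$patella))
  expect_equal(as.matrix(back$data), as.matrix(tr$data), tolerance = 1e-9)
})

test_that("PLY and OBJ geometry files round trip", {
  set.seed(12)
  pts <- matrix(rnorm(30), 10, 3)
  faces <- rbind(c(1, 2, 3), c(4, 5, 6))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_bone_points(pts, ply, faces = faces)
  got <- read_bone_points(ply)
  expect_equal(got$points, pts, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got$faces, faces, ignore_attr = TRUE)

  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(apply(pts, 1, function(p)
    paste("v", paste(sprintf("%.8f", p), collapse = " "))),
    "f 1 2 3"), obj)
  got2 <- read_bone_points(obj)
  expect_equal(got2$points, pts, tolerance = 1e-6, ignore_attr = TRUE)
})
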