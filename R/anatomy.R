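# Anatomical frame construction from bone surface geometry and the
# joint-coordinate-system (two body-fixed axes + one floating axis)
# parameterization of relative bone pose.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -cos(a) * 0 - sin(a), cos(a),
                              0, 0, 0, 1), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
# first nonzero component positive (deterministic direction sign)
lex_sign <- function(v, tol = 1e-12) {
  for (comp in v) if (abs(comp) > tol) return(if (comp < 0) -v else v)
  v
}

#' Rigid transform
#'
#' Minimal container for a proper rigid transform: rotation matrix `R`
#' (orthonormal, det +1) and translation `t` (mm). Used for bone poses and
#' frame offsets.
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R must be a proper rotation matrix", call. = FALSE)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b Transforms to compose: `compose_rigid(a, b)` applies `b`
#'   first, then `a`.
#' @export
compose_rigid <- function(a, b)
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' @rdname rigid_transform
#' @param x Transform to invert.
#' @export
invert_rigid <- function(x) rigid_transform(t(x$R), -as.numeric(t(x$R) %*% x$t))

#' Anatomical bone frame
#'
#' Origin plus three orthonormal right-handed direction vectors, all in lab
#' coordinates. Conventional anatomical meaning of the axes for a right
#' knee: X to the right (lateral), Y anterior, Z proximal/superior.
#'
#' @param origin Length-3 origin (mm, lab coordinates).
#' @param X,Y,Z Unit axis direction vectors; must be mutually orthogonal to
#'   1e-9 and right-handed (X x Y = Z).
#' @return Object of class `bone_frame`.
#' @export
bone_frame <- function(origin, X, Y, Z) {
  A <- cbind(X = as.numeric(X), Y = as.numeric(Y), Z = as.numeric(Z))
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("axes must be orthonormal (within 1e-9)", call. = FALSE)
  if (max(abs(cross3(A[, 1], A[, 2]) - A[, 3])) > 1e-9)
    stop("axes must be right-handed (X x Y = Z)", call. = FALSE)
  structure(list(origin = as.numeric(origin), axes = A),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat("<bone_frame> origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

# internal: coerce bone_frame or rigid_transform to pose (R, t)
as_pose <- function(x) {
  if (inherits(x, "bone_frame")) return(list(R = x$axes, t = x$origin))
  if (inherits(x, "rigid_transform")) return(list(R = x$R, t = x$t))
  stop("expected a bone_frame or rigid_transform", call. = FALSE)
}

# internal: reject degenerate (collinear / coplanar) point sets
check_nondegenerate <- function(pts, min_points, what) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  if (nrow(pts) < min_points)
    stop(what, " needs at least ", min_points, " points", call. = FALSE)
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1])
    stop(what, ": degenerate (coplanar or collinear) point set",
         call. = FALSE)
  pts
}

# internal: direction vector from spherical angles
dir_from_angles <- function(th, ph)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
angles_from_dir <- function(d) c(acos(max(-1, min(1, d[3]))),
                                 atan2(d[2], d[1]))

# internal: algebraic (Kasa) circle fit in 2D; returns center + radius
circle_fit <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  sol <- qr.coef(qr(A), rowSums(xy^2))
  c(sol[1], sol[2], sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 1e-12)))
}

#' Fit a cylinder to a 3-D point set
#'
#' Orthogonal-distance least-squares cylinder: minimizes the sum of squared
#' differences between each point's distance to the axis line and the
#' radius, by Levenberg–Marquardt iteration initialized from the
#' principal-component axes of the points. Used to extract the femoral
#' flexion axis from the posterior/distal condylar surfaces.
#'
#' @param points n x 3 matrix (n >= 6), non-degenerate.
#' @return List with `axis` (unit direction; deterministic sign: first
#'   nonzero component positive), `point` (a point on the axis), `radius`,
#'   `rms` (residual RMS distance) and `iterations`.
#' @export
fit_cylinder <- function(points) {
  pts <- check_nondegenerate(points, 6L, "cylinder fit")
  ctr <- colMeans(pts)
  pc <- svd(scale(pts, scale = FALSE))$v
  best <- NULL
  for (k in 1:3) {
    d0 <- pc[, k]
    # project onto plane perpendicular to the candidate axis, fit a circle
    b <- svd(diag(3) - tcrossprod(d0))$u[, 1:2]
    xy <- scale(pts, scale = FALSE) %*% b
    cf <- circle_fit(xy)
    start <- c(p1 = cf[1], p2 = cf[2],
               th = angles_from_dir(d0)[1], ph = angles_from_dir(d0)[2],
               r = cf[3])
    resid_fun <- function(par) {
      d <- dir_from_angles(par[3], par[4])
      c0 <- ctr + b %*% par[1:2]
      v <- sweep(pts, 2, c0)
      h <- as.numeric(v %*% d)
      sqrt(pmax(rowSums(v^2) - h^2, 0)) - par[5]
    }
    fit <- minpack.lm::nls.lm(start, fn = resid_fun,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ptol = 1e-10, ftol = 1e-12))
    if (is.null(best) || fit$deviance < best$fit$deviance)
      best <- list(fit = fit, basis = b)
  }
  fit <- best$fit
  if (fit$info == 0 || fit$info == 5)
    stop("cylinder fit did not converge after ", fit$niter,
         " iterations (deviance ", signif(fit$deviance, 4), ")",
         call. = FALSE)
  par <- fit$par
  d <- lex_sign(dir_from_angles(par[3], par[4]))
  list(axis = as.numeric(d),
       point = as.numeric(ctr + best$basis %*% par[1:2]),
       radius = abs(unname(par[5])),
       rms = sqrt(fit$deviance / nrow(pts)),
       iterations = fit$niter)
}

#' Fit a cone to a 3-D point set
#'
#' Orthogonal-distance least-squares cone (apex, unit axis, half-angle),
#' fitted by Levenberg–Marquardt from a principal-component initialization.
#' The signed distance of a point to the cone surface is
#' `rho * cos(alpha) - h * sin(alpha)` with `h` the coordinate along the
#' axis from the apex and `rho` the radial distance from the axis. Used to
#' extract long-bone (diaphyseal) axes.
#'
#' @param points n x 3 matrix (n >= 6), non-degenerate.
#' @param axis_hint Direction the returned axis should roughly point along
#'   (e.g. proximally); the fitted axis is flipped to have a positive dot
#'   product with it.
#' @return List with `axis` (unit, oriented per `axis_hint`), `apex`,
#'   `half_angle` (radians, >= 0), `rms` and `iterations`.
#' @export
fit_cone <- function(points, axis_hint = c(0, 0, 1)) {
  pts <- check_nondegenerate(points, 6L, "cone fit")
  ctr <- colMeans(pts)
  pc <- svd(scale(pts, scale = FALSE))$v
  best <- NULL
  for (k in 1:3) for (sgn in c(1, -1)) {
    d0 <- sgn * pc[, k]
    h0 <- as.numeric(sweep(pts, 2, ctr) %*% d0)
    rho0 <- sqrt(pmax(rowSums(sweep(pts, 2, ctr)^2) - h0^2, 0))
    # linear pre-fit rho ~ intercept + slope * h gives alpha and apex
    cf <- stats::coef(stats::lm(rho0 ~ h0))
    slope <- cf[2]
    if (!is.finite(slope)) next
    alpha0 <- atan(abs(slope))
    # apex sits where the fitted rho-line crosses zero
    h_apex <- if (abs(slope) > 1e-8) -cf[1] / slope else min(h0) - 1
    # cone must open away from the apex along +axis: require slope > 0
    if (slope <= 0) next
    apex0 <- ctr + h_apex * d0
    start <- c(a1 = apex0[1], a2 = apex0[2], a3 = apex0[3],
               th = angles_from_dir(d0)[1], ph = angles_from_dir(d0)[2],
               al = max(alpha0, 1e-3))
    resid_fun <- function(par) {
      d <- dir_from_angles(par[4], par[5])
      v <- sweep(pts, 2, par[1:3])
      h <- as.numeric(v %*% d)
      rho <- sqrt(pmax(rowSums(v^2) - h^2, 0))
      rho * cos(par[6]) - h * sin(par[6])
    }
    fit <- try(minpack.lm::nls.lm(start, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ptol = 1e-10,
                                    ftol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("cone fit failed: no usable initialization (near-cylindrical or ",
         "degenerate data?)", call. = FALSE)
  if (best$info == 0 || best$info == 5)
    stop("cone fit did not converge after ", best$niter, " iterations",
         call. = FALSE)
  par <- best$par
  d <- dir_from_angles(par[4], par[5])
  alpha <- abs(unname(par[6]))
  if (alpha > pi / 2) { alpha <- pi - alpha; d <- -d }
  if (sum(d * axis_hint) < 0) d <- -d
  list(axis = as.numeric(d), apex = as.numeric(par[1:3]),
       half_angle = alpha, rms = sqrt(best$deviance / nrow(pts)),
       iterations = best$niter)
}

#' Principal axes of inertia of a point set or closed mesh
#'
#' Computes the centroid and the eigenvectors of the inertia tensor, either
#' of unit point masses (`faces = NULL`) or of the uniform solid enclosed
#' by a closed triangulated mesh (`faces` given, 1-based vertex indices).
#' Axes are returned ordered by decreasing inertia eigenvalue; each axis
#' sign is resolved lexicographically, or by anatomical hint vectors when
#' supplied.
#'
#' @param points n x 3 vertex/point matrix.
#' @param faces Optional m x 3 integer matrix of triangle vertex indices
#'   for a closed mesh.
#' @param hints Optional list of up to 3 direction vectors; axis k is
#'   flipped to have positive dot product with `hints[[k]]` when non-NULL.
#' @param tol Relative eigenvalue separation below which the inertia is
#'   declared ambiguous (default 1e-6).
#' @return List with `centroid`, `axes` (columns, decreasing eigenvalue)
#'   and `eigenvalues`.
#' @export
principal_axes <- function(points, faces = NULL, hints = NULL, tol = 1e-6) {
  pts <- as.matrix(points)
  if (is.null(faces)) {
    if (nrow(pts) < 4L)
      stop("need at least 4 points for principal axes", call. = FALSE)
    ctr <- colMeans(pts)
    v <- sweep(pts, 2, ctr)
    C <- crossprod(v)                       # second-moment matrix
  } else {
    faces <- as.matrix(faces)
    # uniform-solid moments by signed tetrahedra against the origin
    vol <- 0; m1 <- c(0, 0, 0); C0 <- matrix(0, 3, 3)
    for (f in seq_len(nrow(faces))) {
      a <- pts[faces[f, 1], ]; b <- pts[faces[f, 2], ]; cc <- pts[faces[f, 3], ]
      dv <- det(cbind(a, b, cc)) / 6
      vol <- vol + dv
      m1 <- m1 + dv * (a + b + cc) / 4
      s <- a + b + cc
      C0 <- C0 + dv / 20 * (tcrossprod(a) + tcrossprod(b) + tcrossprod(cc) +
                              tcrossprod(s))
    }
    if (abs(vol) < 1e-12)
      stop("mesh encloses (near-)zero volume; is it closed?", call. = FALSE)
    ctr <- m1 / vol
    C <- C0 - vol * tcrossprod(ctr)         # translate to centroid
    if (vol < 0) C <- -C
  }
  I3 <- diag(sum(diag(C)), 3) - C           # inertia tensor
  eg <- eigen(I3, symmetric = TRUE)         # eigenvalues decreasing
  ev <- eg$values
  spread <- max(abs(ev))
  if (spread < 1e-12 || min(abs(diff(ev))) < tol * spread)
    stop("ambiguous principal axes: inertia eigenvalues are (nearly) ",
         "degenerate", call. = FALSE)
  axes <- eg$vectors
  for (k in 1:3) {
    hint <- if (!is.null(hints) && length(hints) >= k) hints[[k]] else NULL
    axes[, k] <- if (!is.null(hint)) {
      if (sum(axes[, k] * hint) < 0) -axes[, k] else axes[, k]
    } else lex_sign(axes[, k])
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(centroid = as.numeric(ctr), axes = axes, eigenvalues = ev)
}

#' Construct the femoral anatomical frame
#'
#' Builds the femoral frame from surface geometry: the X axis is the axis
#' of a cylinder fitted to the posterior/distal condylar surface (pointing
#' to the right), a long axis L1 comes from a cone fitted to the diaphysis
#' (pointing proximally), the Y axis is `normalize(L1 x X)` (anterior), the
#' Z axis `X x Y` (proximal), and the origin is the foot of the
#' perpendicular from the intercondylar notch apex onto the cylinder axis.
#'
#' @param condyle_points n x 3 points on the posterior/distal condyles.
#' @param diaphysis_points n x 3 points on the femoral shaft.
#' @param notch_apex Length-3 intercondylar notch apex (mm).
#' @param right_hint,proximal_hint Approximate lab directions of
#'   anatomical right and proximal, used only to orient the fitted axes.
#' @return A [bone_frame].
#' @export
build_femoral_frame <- function(condyle_points, diaphysis_points, notch_apex,
                                right_hint = c(1, 0, 0),
                                proximal_hint = c(0, 0, 1)) {
  cyl <- fit_cylinder(condyle_points)
  X <- cyl$axis
  if (sum(X * right_hint) < 0) X <- -X
  cone <- fit_cone(diaphysis_points, axis_hint = proximal_hint)
  L1 <- cone$axis
  yv <- cross3(L1, X)
  if (sqrt(sum(yv^2)) < 1e-6)
    stop("degenerate geometry: long axis L1 is parallel to the condylar ",
         "cylinder axis", call. = FALSE)
  Y <- unit3(yv)
  Z <- cross3(X, Y)
  h <- sum((notch_apex - cyl$point) * X)
  origin <- cyl$point + h * X
  bone_frame(origin, X, Y, Z)
}

#' Construct the tibial anatomical frame
#'
#' The Z axis is parallel to the diaphyseal cone axis L2 (proximal) and
#' passes through the midpoint of the intercondylar eminences; the Y axis
#' is `normalize(Z x L3)` with L3 the rightward vector joining the two
#' tibial plateau centers (anterior); X is `Y x Z` (right). The origin is
#' the intersection of the Z axis with the plane through the femoral
#' origin perpendicular to Z, and therefore depends on the reference
#' (e.g. CT) pose of the femur supplied.
#'
#' @param diaphysis_points n x 3 points on the tibial shaft.
#' @param plateau_centers 2 x 3 matrix: centers of the medial and lateral
#'   tibial plateau; the vector from row 1 to row 2 is oriented by
#'   `right_hint`.
#' @param eminence_midpoint Length-3 midpoint between the intercondylar
#'   eminences.
#' @param femoral_frame [bone_frame] of the femur in the reference pose.
#' @param right_hint,proximal_hint Orientation hints as in
#'   [build_femoral_frame()].
#' @return A [bone_frame].
#' @export
build_tibial_frame <- function(diaphysis_points, plateau_centers,
                               eminence_midpoint, femoral_frame,
                               right_hint = c(1, 0, 0),
                               proximal_hint = c(0, 0, 1)) {
  plateau_centers <- as.matrix(plateau_centers)
  stopifnot(identical(dim(plateau_centers), c(2L, 3L)))
  L3 <- plateau_centers[2, ] - plateau_centers[1, ]
  if (sqrt(sum(L3^2)) < 1e-9)
    stop("plateau centers coincide", call. = FALSE)
  if (sum(L3 * right_hint) < 0) L3 <- -L3
  cone <- fit_cone(diaphysis_points, axis_hint = proximal_hint)
  Z <- cone$axis
  yv <- cross3(Z, L3)
  if (sqrt(sum(yv^2)) < 1e-6 * sqrt(sum(L3^2)))
    stop("degenerate geometry: plateau vector L3 is parallel to the tibial ",
         "long axis", call. = FALSE)
  Y <- unit3(yv)
  X <- cross3(Y, Z)
  oF <- as_pose(femoral_frame)$t
  s <- sum((oF - eminence_midpoint) * Z)
  origin <- eminence_midpoint + s * Z
  bone_frame(origin, X, Y, Z)
}

#' Construct the patellar anatomical frame
#'
#' The Y axis is the principal axis of inertia of the patellar surface
#' points with the largest moment (the anteroposterior direction of the
#' flat bone), oriented anteriorly by the supplied hint; the X axis is
#' perpendicular to Y and to the posterior ridge direction (pointing
#' right); Z is `X x Y` (superior). The origin is the centroid.
#'
#' @param points n x 3 patellar surface points.
#' @param ridge_direction Direction of the posterior patellar ridge
#'   (superior-pointing landmark vector).
#' @param anterior_hint Approximate anterior direction.
#' @return A [bone_frame].
#' @export
build_patellar_frame <- function(points, ridge_direction,
                                 anterior_hint = c(0, 1, 0)) {
  pa <- principal_axes(points, hints = list(anterior_hint))
  Y <- pa$axes[, 1]
  xv <- cross3(Y, unit3(ridge_direction))
  if (sqrt(sum(xv^2)) < 1e-6)
    stop("degenerate geometry: ridge direction parallel to the patellar ",
         "principal axis", call. = FALSE)
  X <- unit3(xv)
  Z <- cross3(X, Y)
  bone_frame(pa$centroid, X, Y, Z)
}

#' Joint coordinate system specification
#'
#' Fixes the conventions used to turn a relative bone pose into six joint
#' parameters: the parent body-fixed axis is the parent frame's X, the
#' child body-fixed axis the child frame's Z, and the floating axis is
#' perpendicular to both. Rotation signs and translation signs are
#' configurable; defaults describe a right knee with flexion, abduction
#' and external rotation positive and translations positive along lateral
#' (parent X), anterior (floating) and proximal (child Z).
#'
#' @param rotation_signs Named numeric (+1/-1) for `flexion`, `abduction`,
#'   `rotation` (the child-fixed-axis rotation).
#' @param translation_signs Named numeric (+1/-1) for `shift` (parent
#'   axis), `drawer` (floating axis), `distraction` (child axis).
#' @return Object of class `jcs_spec`.
#' @export
jcs_spec <- function(rotation_signs = c(flexion = -1, abduction = -1,
                                        rotation = -1),
                     translation_signs = c(shift = 1, drawer = 1,
                                           distraction = 1)) {
  stopifnot(all(c("flexion", "abduction", "rotation") %in%
                  names(rotation_signs)),
            all(c("shift", "drawer", "distraction") %in%
                  names(translation_signs)),
            all(abs(rotation_signs) == 1), all(abs(translation_signs) == 1))
  structure(list(rotation_signs = rotation_signs,
                 translation_signs = translation_signs),
            class = "jcs_spec")
}

#' Decompose a bone pose pair into joint parameters
#'
#' Expresses the pose of a child bone relative to its parent as six joint
#' parameters: three rotations (about the parent-fixed X axis, the floating
#' axis, and the child-fixed Z axis — a Cardan X-Y-Z factorization of the
#' relative rotation) and three translations (the parent-to-child origin
#' vector decomposed in the non-orthogonal basis of parent-fixed, floating
#' and child-fixed axes). The abduction parameter equals the angle between
#' the two fixed axes minus 90 degrees, with sign per `spec`.
#'
#' @param parent_pose,child_pose [bone_frame] or [rigid_transform] giving
#'   each bone's pose in lab coordinates.
#' @param spec A [jcs_spec()].
#' @return Named numeric vector `shift`, `drawer`, `distraction` (mm) and
#'   `flexion`, `abduction`, `rotation` (deg).
#' @export
jcs_decompose <- function(parent_pose, child_pose, spec = jcs_spec()) {
  p <- as_pose(parent_pose); ch <- as_pose(child_pose)
  Rrel <- t(p$R) %*% ch$R
  jcs_decompose_rel(rigid_transform(Rrel,
                                    as.numeric(t(p$R) %*% (ch$t - p$t))),
                    spec)
}

# internal: decompose a relative transform (child in parent coordinates)
jcs_decompose_rel <- function(rel, spec = jcs_spec()) {
  R <- rel$R
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  # fixed axes parallel when |b| reaches 90 deg
  if (90 - abs(b) * 180 / pi < 0.1)
    stop("gimbal singularity: body-fixed axes are within 0.1 deg of ",
         "parallel", call. = FALSE)
  a <- atan2(-R[2, 3], R[3, 3])
  cc <- atan2(-R[1, 2], R[1, 1])
  rs <- spec$rotation_signs
  e1 <- c(1, 0, 0)                          # parent fixed axis
  e3 <- R[, 3]                              # child fixed axis
  e2 <- unit3(cross3(e3, e1))               # floating axis
  tcomp <- unname(solve(cbind(e1, e2, e3), rel$t))
  ts <- spec$translation_signs
  c(shift = ts[["shift"]] * tcomp[1],
    drawer = ts[["drawer"]] * tcomp[2],
    distraction = ts[["distraction"]] * tcomp[3],
    flexion = rs[["flexion"]] * a * 180 / pi,
    abduction = rs[["abduction"]] * b * 180 / pi,
    rotation = rs[["rotation"]] * cc * 180 / pi)
}

#' Compose joint parameters into a relative pose
#'
#' Inverse of [jcs_decompose()]: reconstructs the unique relative rigid
#' transform (child pose in parent coordinates) whose decomposition under
#' the same `spec` returns the given parameters.
#'
#' @param params Named vector as returned by [jcs_decompose()] (`shift`,
#'   `drawer`, `distraction` in mm; `flexion`, `abduction`, `rotation` in
#'   deg). `abduction` must satisfy |abduction| < 90.
#' @param spec A [jcs_spec()].
#' @return A [rigid_transform] (relative pose).
#' @export
jcs_compose <- function(params, spec = jcs_spec()) {
  need <- c("shift", "drawer", "distraction", "flexion", "abduction",
            "rotation")
  if (!all(need %in% names(params)))
    stop("params must be named: ", paste(need, collapse = ", "),
         call. = FALSE)
  rs <- spec$rotation_signs; ts <- spec$translation_signs
  if (abs(params[["abduction"]]) >= 90)
    stop("|abduction| must be below 90 deg", call. = FALSE)
  a <- rs[["flexion"]] * params[["flexion"]] * pi / 180
  b <- rs[["abduction"]] * params[["abduction"]] * pi / 180
  cc <- rs[["rotation"]] * params[["rotation"]] * pi / 180
  R <- rot_x(a) %*% rot_y(b) %*% rot_z(cc)
  e1 <- c(1, 0, 0); e3 <- R[, 3]
  e2 <- unit3(cross3(e3, e1))
  tcomp <- c(ts[["shift"]] * params[["shift"]],
             ts[["drawer"]] * params[["drawer"]],
             ts[["distraction"]] * params[["distraction"]])
  rigid_transform(R, as.numeric(cbind(e1, e2, e3) %*% tcomp))
}

#' Re-express a kinematic trial in shifted bone frames
#'
#' Applies constant frame offsets to the femoral, tibial and patellar
#' frames and recomputes all 12 joint parameters: each sample's TF and PF
#' relative pose is reconstructed with [jcs_compose()], conjugated with the
#' offsets (`new_rel = inv(parent_offset) o rel o child_offset`), and
#' re-decomposed. Identity offsets leave the trial unchanged.
#'
#' @param trial A [knee_trial].
#' @param femur_offset,tibia_offset,patella_offset [rigid_transform]
#'   offsets mapping each new bone frame to the old one (defaults:
#'   identity).
#' @param spec A [jcs_spec()] used for both joints.
#' @return The re-expressed [knee_trial].
#' @export
reexpress_trajectory <- function(trial,
                                 femur_offset = rigid_transform(),
                                 tibia_offset = rigid_transform(),
                                 patella_offset = rigid_transform(),
                                 spec = jcs_spec()) {
  stopifnot(inherits(trial, "knee_trial"))
  inv_f <- invert_rigid(femur_offset)
  remap <- function(block, child_offset) {
    t(apply(block, 1, function(row) {
      names(row) <- c("shift", "drawer", "distraction", "flexion",
                      "abduction", "rotation")
      rel <- jcs_compose(row, spec)
      new_rel <- compose_rigid(compose_rigid(inv_f, rel), child_offset)
      jcs_decompose_rel(new_rel, spec)
    }))
  }
  tf <- remap(as.matrix(trial$data[, KP_TF]), tibia_offset)
  pf <- remap(as.matrix(trial$data[, KP_PF]), patella_offset)
  out <- cbind(tf, pf)
  colnames(out) <- KP_ALL
  trial$data <- as.data.frame(out)
  trial
}
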