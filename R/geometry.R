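#' Helix axes, rigid rotations and umbrella/orientation schedules
#'
#' Sign conventions: a positive helical rotation is clockwise about the
#' helix long axis viewed from the N-terminus toward the C-terminus
#' (see [ROTATION_HANDEDNESS]). Crossing-angle changes rotate the mobile
#' helix about the vector joining the two helices' centers of mass.
#'
#' @name geometry
NULL

rodrigues <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle_rad); s0 <- sin(angle_rad)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

#' Fit the long axis of a helix fragment
#'
#' Averages cross products of successive second differences of the
#' C-alpha trace (exact for an ideal helix of any length, robust for
#' 12-17-residue near-ideal helices), with sign fixed so that the
#' projection of (last CA - first CA) onto the axis is positive
#' (N-to-C orientation).
#'
#' @param fragment an `hp_fragment` with at least 4 C-alpha atoms
#' @return unit 3-vector
#' @export
fit_helix_axis <- function(fragment) {
  ca <- calpha_coords(fragment)
  n <- nrow(ca)
  if (n < 4L) stop("helix axis undefined: fewer than 4 CA atoms")
  # second differences point radially inward and rotate with the helix
  # phase; consecutive cross products all point along the axis
  w <- diff(ca, differences = 2)
  u <- c(0, 0, 0)
  for (i in seq_len(nrow(w) - 1L))
    u <- u + pracma_cross(w[i, ], w[i + 1, ])
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("helix axis undefined: degenerate CA trace")
  u <- u / nu
  nc <- ca[n, ] - ca[1, ]
  if (sum(nc * u) < 0) u <- -u
  u
}

rotate_coords_about <- function(coords, axis, center, angle_deg,
                                handedness = ROTATION_HANDEDNESS) {
  R <- rodrigues(axis, handedness * angle_deg * pi / 180)
  sweep(sweep(coords, 2, center) %*% t(R), 2, center, `+`)
}

#' Rotate one fragment of a bundle about its helix long axis
#'
#' Rigid rotation of all of the fragment's atoms about the fitted helix
#' axis through the fragment's C-alpha centroid. Positive angles are
#' clockwise viewed from N toward C.
#'
#' @param bundle an `hp_bundle`
#' @param fragment_id name of the fragment to rotate
#' @param angle_deg signed rotation in degrees, in [-180, 180]
#' @return a new `hp_bundle`
#' @export
rotate_fragment <- function(bundle, fragment_id, angle_deg) {
  if (!fragment_id %in% names(bundle$fragments))
    stop("unknown fragment id: ", fragment_id)
  stopifnot(abs(angle_deg) <= 180)
  fr <- bundle$fragments[[fragment_id]]
  axis <- fit_helix_axis(fr)
  center <- colMeans(calpha_coords(fr))
  fr$coords <- rotate_coords_about(fr$coords, axis, center, angle_deg)
  bundle$fragments[[fragment_id]] <- fr
  bundle
}

#' An orientation label for a two-bundle system
#'
#' @param rotated_fragment fragment id, or "crossing" for crossing-angle
#'   changes
#' @param angle_deg signed degrees in [-180, 180]; 0 means native
#' @param description optional label
#' @export
new_orientation <- function(rotated_fragment, angle_deg, description = NULL) {
  stopifnot(abs(angle_deg) <= 180)
  structure(list(rotated_fragment = rotated_fragment,
                 angle_deg = angle_deg,
                 native = angle_deg == 0,
                 description = description %||%
                   sprintf("%s%+g deg", rotated_fragment, angle_deg)),
            class = "hp_orientation")
}

#' Restraint scheme for a two-bundle system
#'
#' Reference bundle C-alphas are position-restrained in all of x, y, z;
#' the mobile bundle only in y and z, leaving the inter-bundle x
#' displacement as the order parameter.
#'
#' @param k force constant, kJ/mol/nm^2 (default 1000)
#' @export
new_restraints <- function(k = 1000) {
  stopifnot(k >= 0)
  structure(list(k = k,
                 reference_axes = c("x", "y", "z"),
                 mobile_axes = c("y", "z")),
            class = "hp_restraints")
}

#' A two-bundle association system
#'
#' @param reference rigid `hp_bundle`, position-fixed
#' @param mobile rigid `hp_bundle`, free along x
#' @param orientation `hp_orientation` (default native)
#' @param restraints `hp_restraints`
#' @export
new_system <- function(reference, mobile,
                       orientation = new_orientation(
                         names(mobile$fragments)[1], 0, "native"),
                       restraints = new_restraints()) {
  shared <- intersect(
    unlist(lapply(reference$fragments, `[[`, "residue_ids")),
    unlist(lapply(mobile$fragments, `[[`, "residue_ids")))
  if (length(shared))
    stop("reference and mobile bundles share residue(s): ",
         paste(shared, collapse = ", "))
  structure(list(reference = reference, mobile = mobile,
                 orientation = orientation, restraints = restraints),
            class = "hp_system")
}

#' @export
print.hp_system <- function(x, ...) {
  cat(sprintf("<hp_system> orientation: %s\n", x$orientation$description))
  invisible(x)
}

#' Signed crossing angle between the two helix axes of a system
#'
#' The axes of the (single-helix) reference and mobile bundles are
#' projected onto the plane perpendicular to the inter-center-of-mass
#' vector; the reported angle is the signed angle from the reference to
#' the mobile projection, with sign matching [set_crossing_angle] (a
#' `+delta` crossing change increases the measured angle by `delta`).
#'
#' @param system an `hp_system` with single-helix bundles
#' @return degrees in (-180, 180]
#' @export
crossing_angle <- function(system) {
  v <- bundle_com(system$mobile) - bundle_com(system$reference)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("zero-length center-of-mass vector")
  v <- v / nv
  proj <- function(a) { p <- a - sum(a * v) * v; p / sqrt(sum(p^2)) }
  a1 <- proj(fit_helix_axis(system$reference$fragments[[1]]))
  a2 <- proj(fit_helix_axis(system$mobile$fragments[[1]]))
  ang <- atan2(sum(v * pracma_cross(a1, a2)), sum(a1 * a2)) * 180 / pi
  ROTATION_HANDEDNESS * ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Change the crossing angle of a two-helix system
#'
#' Rigidly rotates the mobile helix about the vector joining the two
#' bundles' centers of mass, through the mobile helix's center of mass.
#' Positive `delta_deg` is clockwise with respect to that vector
#' (reference-to-mobile direction), matching the helical-rotation
#' handedness convention.
#'
#' @param system an `hp_system`; both bundles single-helix
#' @param delta_deg signed degrees
#' @return modified `hp_system`
#' @export
set_crossing_angle <- function(system, delta_deg) {
  if (length(system$reference$fragments) != 1L ||
      length(system$mobile$fragments) != 1L)
    stop("crossing-angle changes require single-helix bundles")
  v <- bundle_com(system$mobile) - bundle_com(system$reference)
  if (sqrt(sum(v^2)) < 1e-12) stop("zero-length center-of-mass vector")
  fr <- system$mobile$fragments[[1]]
  center <- colMeans(calpha_coords(fr))
  fr$coords <- rotate_coords_about(fr$coords, v, center, delta_deg)
  system$mobile$fragments[[1]] <- fr
  so <- system$orientation
  system$orientation <- new_orientation("crossing",
                                        (so$angle_deg %||% 0) + delta_deg)
  system
}

#' Enumerate nonnative orientations of a two-fragment system
#'
#' One system per (rotatable fragment, +/- magnitude); the native state is
#' excluded, so `magnitudes` of length m yield `2 * 2 * m` systems.
#'
#' @param system native `hp_system`
#' @param magnitudes positive rotation magnitudes in degrees
#' @param fragments character vector of two rotatable fragment ids;
#'   defaults to the first fragment of each bundle
#' @return list of `hp_system`
#' @export
enumerate_orientations <- function(system, magnitudes,
                                   fragments = NULL) {
  if (any(magnitudes == 0))
    stop("magnitude 0 requested: the native state is not a nonnative orientation")
  stopifnot(all(magnitudes > 0))
  if (is.null(fragments))
    fragments <- c(names(system$reference$fragments)[1],
                   names(system$mobile$fragments)[1])
  stopifnot(length(fragments) == 2L)
  out <- list()
  for (fid in fragments) {
    in_ref <- fid %in% names(system$reference$fragments)
    for (mag in magnitudes) for (sgn in c(1, -1)) {
      ang <- sgn * mag
      sys2 <- system
      if (in_ref) {
        sys2$reference <- rotate_fragment(sys2$reference, fid, ang)
      } else {
        sys2$mobile <- rotate_fragment(sys2$mobile, fid, ang)
      }
      sys2$orientation <- new_orientation(fid, ang)
      out[[length(out) + 1L]] <- sys2
    }
  }
  out
}

#' An umbrella window
#'
#' @param d0 target inter-bundle displacement, nm (> 0)
#' @param k harmonic force constant, kJ/mol/nm^2 (> 0)
#' @export
new_window <- function(d0, k = 2000) {
  stopifnot(d0 > 0, k > 0)
  structure(list(d0 = d0, k = k), class = "hp_window")
}

#' Build an umbrella-window schedule
#'
#' Window centers at `dmin, dmin + step, ..., dmax` (endpoint included
#' when it falls within 1e-9 of the arithmetic grid); all windows share
#' the same force constant. The study design uses 39 windows spanning
#' 0.7 to 2.6 nm in 0.05 nm increments at k = 2000 kJ/mol/nm^2.
#'
#' @param dmin,dmax schedule limits, nm (dmin <= dmax)
#' @param step increment, nm (> 0)
#' @param k force constant, kJ/mol/nm^2
#' @return list of `hp_window`
#' @export
build_window_schedule <- function(dmin = 0.7, dmax = 2.6, step = 0.05,
                                  k = 2000) {
  if (step <= 0) stop("step must be positive")
  if (dmin > dmax) stop("dmin must not exceed dmax")
  n <- floor((dmax - dmin) / step + 1e-9) + 1
  centers <- dmin + step * (seq_len(n) - 1)
  lapply(centers, new_window, k = k)
}

#' Window centers of a schedule, nm
#' @param schedule list of `hp_window`
#' @export
window_centers <- function(schedule) {
  vapply(schedule, `[[`, numeric(1), "d0")
}

#' Measure the rotation of a fragment frame about the reference helix axis
#'
#' Finds the best-fit rotation angle (least-squares over C-alpha atoms) of
#' the frame's coordinates about the reference fragment's helix axis,
#' reported in the package sign convention, minus a baseline. The
#' baseline argument supports referencing against the weak-interaction
#' regime at large separations.
#'
#' @param frame_coords n_atoms x 3 coordinates (nm) in the reference's
#'   atom order
#' @param reference `hp_fragment` defining the axis and the zero angle
#' @param baseline_deg baseline angle to subtract (default 0)
#' @return signed degrees
#' @export
measure_rotation_angle <- function(frame_coords, reference,
                                   baseline_deg = 0) {
  frame_coords <- as.matrix(frame_coords)
  if (nrow(frame_coords) != nrow(reference$coords))
    stop("frame atom count does not match the reference fragment")
  u <- fit_helix_axis(reference)
  p <- calpha_coords(reference)
  q <- frame_coords[reference$calpha_index, , drop = FALSE]
  perp <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m - outer(drop(m %*% u), u)
  }
  P <- perp(p); Q <- perp(q)
  cross_u <- rowSums(cbind(
    P[, 2] * Q[, 3] - P[, 3] * Q[, 2],
    P[, 3] * Q[, 1] - P[, 1] * Q[, 3],
    P[, 1] * Q[, 2] - P[, 2] * Q[, 1]) %*% diag(u))
  theta_rh <- atan2(sum(cross_u), sum(P * Q)) * 180 / pi
  ROTATION_HANDEDNESS * theta_rh - baseline_deg
}
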