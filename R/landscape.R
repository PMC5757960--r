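#' Parametric free-energy landscapes over (d, theta1, theta2)
#'
#' A surrogate for the molecular free-energy surface governing the
#' association of two restrained helices: a repulsive wall at short
#' inter-bundle displacement d, an attractive well whose depth is
#' modulated by a two-basin function of the helix rotation angles, and a
#' flat plateau (G = 0) at large separation. Observable models attach
#' per-frame potential-energy components and system volume as smooth
#' functions of (d, theta1, theta2) plus Gaussian noise.
#'
#' @name landscape
NULL

#' Construct a landscape specification
#'
#' The landscape is
#' \deqn{G(d, \theta_1, \theta_2) = h_w e^{-(d - d_w)/w_w} - s(d)\,W(\theta_1, \theta_2)}
#' with envelope \eqn{s(d) = \exp(-(d - d_{well})^2 / 2\sigma_d^2)} and
#' angular well
#' \eqn{W = D_0 + \sum_b D_b \exp(-((\theta_1-c_{1b})^2 + (\theta_2-c_{2b})^2)/2 w_b^2)}.
#' Both terms vanish at large d, so the plateau level is exactly 0.
#'
#' @param temperature_K temperature, K (> 0)
#' @param wall_height,wall_pos,wall_width repulsive wall: height kJ/mol at
#'   `wall_pos` (nm), exponential decay length nm
#' @param well_center,well_width center (nm) and width (nm) of the
#'   attractive-well envelope
#' @param base_depth orientation-independent well depth D0, kJ/mol
#' @param angular_basins data.frame with columns `theta1`, `theta2`
#'   (degrees), `depth` (kJ/mol), `width` (degrees); may have 0 rows
#' @param observables list of observable-model parameters, see
#'   [default_observables()]
#' @return object of class `hp_landscape`
#' @export
new_landscape <- function(temperature_K = DEFAULT_TEMPERATURE_K,
                          wall_height = 60, wall_pos = 0.9,
                          wall_width = 0.045,
                          well_center = 1.15, well_width = 0.13,
                          base_depth = 25,
                          angular_basins = data.frame(
                            theta1 = numeric(), theta2 = numeric(),
                            depth = numeric(), width = numeric()),
                          observables = default_observables()) {
  stopifnot(temperature_K > 0, well_width > 0, wall_width > 0,
            all(angular_basins$width > 0), all(angular_basins$depth >= 0),
            base_depth >= 0)
  structure(list(temperature_K = temperature_K,
                 RT = GAS_CONSTANT_KJ * temperature_K,
                 wall_height = wall_height, wall_pos = wall_pos,
                 wall_width = wall_width,
                 well_center = well_center, well_width = well_width,
                 base_depth = base_depth,
                 angular_basins = angular_basins,
                 observables = observables),
            class = "hp_landscape")
}

#' Angular well depth W(theta1, theta2), kJ/mol (vectorised)
#' @param spec an `hp_landscape`
#' @param theta1,theta2 degrees
#' @export
angular_well <- function(spec, theta1, theta2) {
  W <- rep(spec$base_depth, length(theta1))
  b <- spec$angular_basins
  if (nrow(b)) for (i in seq_len(nrow(b))) {
    W <- W + b$depth[i] * exp(-((theta1 - b$theta1[i])^2 +
                                (theta2 - b$theta2[i])^2) /
                              (2 * b$width[i]^2))
  }
  W
}

#' Evaluate the landscape free energy, kJ/mol (vectorised)
#'
#' @param spec an `hp_landscape`
#' @param d displacement, nm
#' @param theta1,theta2 rotation angles, degrees
#' @export
eval_landscape <- function(spec, d, theta1 = 0, theta2 = 0) {
  stopifnot(all(d > 0))
  wall <- spec$wall_height * exp(-(d - spec$wall_pos) / spec$wall_width)
  env <- exp(-(d - spec$well_center)^2 / (2 * spec$well_width^2))
  wall - env * angular_well(spec, theta1, theta2)
}

#' Default observable models
#'
#' Conditional means of the energy components and the system volume as
#' functions of (d, theta1, theta2). The total potential energy tracks
#' the free energy plus an entropy-compensated Gaussian bump centered at
#' `enthalpy_barrier_pos` (so the PMF stays barrierless while the
#' enthalpy profile shows a desolvation-like barrier); the volume model
#' has a Gaussian barrier at `volume_barrier_pos`. Class weights split
#' the total into LJ/Coulomb x molecular-species components that sum to
#' the total exactly.
#'
#' @param u_offset baseline potential energy, kJ/mol
#' @param enthalpy_barrier_height,enthalpy_barrier_pos,enthalpy_barrier_width
#'   Gaussian enthalpic barrier: kJ/mol, nm, nm
#' @param u_noise_sd per-frame Gaussian noise on each energy component, kJ/mol
#' @param v_offset baseline system volume, nm^3
#' @param volume_barrier_height,volume_barrier_pos,volume_barrier_width
#'   Gaussian volume barrier: nm^3, nm, nm
#' @param v_noise_sd per-frame volume noise, nm^3
#' @export
default_observables <- function(u_offset = -500,
                                enthalpy_barrier_height = 15,
                                enthalpy_barrier_pos = 1.5,
                                enthalpy_barrier_width = 0.09,
                                u_noise_sd = 4,
                                v_offset = 100,
                                volume_barrier_height = 0.06,
                                volume_barrier_pos = 1.45,
                                volume_barrier_width = 0.08,
                                v_noise_sd = 0.03) {
  list(u_offset = u_offset,
       enthalpy_barrier_height = enthalpy_barrier_height,
       enthalpy_barrier_pos = enthalpy_barrier_pos,
       enthalpy_barrier_width = enthalpy_barrier_width,
       u_noise_sd = u_noise_sd,
       v_offset = v_offset,
       volume_barrier_height = volume_barrier_height,
       volume_barrier_pos = volume_barrier_pos,
       volume_barrier_width = volume_barrier_width,
       v_noise_sd = v_noise_sd)
}

#' Energy-component classes recorded in window samples
#' @export
energy_classes <- function() {
  c("intra_ref", "intra_mob", "inter_bundle",
    "solv_ref", "solv_mob", "solv_solv")
}

# Fractional split of the interaction part of U across (class, LJ/Coulomb).
# Chosen so inter-bundle LJ carries most of the well, solvent-solvent
# electrostatics carries most of the compensated barrier; rows sum to 1.
component_weights <- function() {
  w <- rbind(
    intra_ref    = c(lj = 0.05, coul = 0.05),
    intra_mob    = c(lj = 0.05, coul = 0.05),
    inter_bundle = c(lj = 0.35, coul = 0.10),
    solv_ref     = c(lj = 0.03, coul = 0.07),
    solv_mob     = c(lj = 0.03, coul = 0.07),
    solv_solv    = c(lj = 0.05, coul = 0.10))
  stopifnot(abs(sum(w) - 1) < 1e-12)
  w
}

#' Conditional mean of total potential energy, kJ/mol (vectorised)
#'
#' `U(d, theta) = u_offset + G(d, theta) + bump(d)`; the bump is the
#' entropy-compensated enthalpic barrier (absent from G).
#'
#' @param spec an `hp_landscape`
#' @param d,theta1,theta2 state
#' @export
mean_potential <- function(spec, d, theta1 = 0, theta2 = 0) {
  ob <- spec$observables
  ob$u_offset + eval_landscape(spec, d, theta1, theta2) +
    ob$enthalpy_barrier_height *
      exp(-(d - ob$enthalpy_barrier_pos)^2 /
            (2 * ob$enthalpy_barrier_width^2))
}

#' Conditional mean of system volume, nm^3 (vectorised)
#' @param spec an `hp_landscape`
#' @param d displacement, nm
#' @export
mean_volume <- function(spec, d) {
  ob <- spec$observables
  ob$v_offset + ob$volume_barrier_height *
    exp(-(d - ob$volume_barrier_pos)^2 / (2 * ob$volume_barrier_width^2))
}

# Draw per-frame observables for states (d, theta1, theta2). Components
# are split by class weights and carry independent Gaussian noise; the
# recorded total U is the exact sum of the components, so decomposition
# closure holds frame by frame.
draw_observables <- function(spec, d, theta1, theta2) {
  ob <- spec$observables
  n <- length(d)
  mu_u <- mean_potential(spec, d, theta1, theta2)
  w <- component_weights()
  interaction <- mu_u - ob$u_offset
  cls <- energy_classes()
  out <- list()
  for (ci in cls) for (term in c("lj", "coul")) {
    base <- if (ci == cls[1] && term == "lj") ob$u_offset else 0
    out[[paste0("E_", term, "_", ci)]] <-
      base + w[ci, term] * interaction + stats::rnorm(n, 0, ob$u_noise_sd)
  }
  comp <- do.call(cbind, out)
  U <- rowSums(comp)
  V <- mean_volume(spec, d) + stats::rnorm(n, 0, ob$v_noise_sd)
  cbind(as.data.frame(comp), U_total = U, V_nm3 = V)
}
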