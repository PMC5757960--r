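#' Enthalpy/entropy/volume decomposition and energy breakdowns
#'
#' Resolves distance-dependent PMFs into enthalpic and entropic
#' components using the same reweighting weights as the PMF, extracts
#' volume profiles, and decomposes potential energies by interaction
#' class and by residue pair.
#'
#' @name thermo
NULL

# WHAM frame weights for unbiased conditional averages: each frame t in
# window w gets weight 1 / sum_k N_k exp((g_k - u_k(d_t)) / RT).
wham_frame_weights <- function(samples, pmf) {
  d0 <- vapply(samples, function(s) s$window$d0, numeric(1))
  kk <- vapply(samples, function(s) s$window$k, numeric(1))
  g <- pmf$window_free_energies
  RT <- RT_300K
  n_w <- vapply(samples, function(s) nrow(s$series), numeric(1))
  lapply(samples, function(s) {
    dd <- s$series$d_nm
    A <- vapply(seq_along(d0), function(k)
      log(n_w[k]) + (g[k] - kk[k] / 2 * (dd - d0[k])^2) / RT,
      numeric(length(dd)))
    if (is.null(dim(A))) A <- matrix(A, nrow = 1)
    m <- apply(A, 1, max)
    exp(-(m + log(rowSums(exp(A - m)))))
  })
}

# Reweighted per-bin conditional mean of an observable plus block SEM.
reweighted_profile <- function(samples, pmf, values_fn, n_blocks = 5) {
  w_list <- wham_frame_weights(samples, pmf)
  dd <- unlist(lapply(samples, function(s) s$series$d_nm))
  ww <- unlist(w_list)
  oo <- unlist(lapply(samples, values_fn))
  blk <- unlist(lapply(samples, function(s) {
    n <- nrow(s$series); size <- floor(n / max(n_blocks, 1))
    b <- ceiling(seq_len(n) / max(size, 1))
    pmin(b, n_blocks)
  }))
  half <- pmf$bin_width / 2
  centers <- pmf$profile$d
  bin <- findInterval(dd, c(centers - half, centers[length(centers)] + half))
  ok <- bin >= 1 & bin <= length(centers)
  agg <- function(sel) {
    num <- tapply(ww[sel] * oo[sel], bin[sel], sum)
    den <- tapply(ww[sel], bin[sel], sum)
    out <- rep(NA_real_, length(centers))
    out[as.integer(names(num))] <- num / den
    out
  }
  mean_all <- agg(ok)
  if (n_blocks >= 2) {
    per_block <- vapply(seq_len(n_blocks), function(b) agg(ok & blk == b),
                        numeric(length(centers)))
    nfin <- rowSums(is.finite(per_block))
    sem <- rep(NA_real_, length(centers))
    idx <- nfin == n_blocks
    sem[idx] <- apply(per_block[idx, , drop = FALSE], 1, stats::sd) /
      sqrt(n_blocks)
  } else sem <- rep(NA_real_, length(centers))
  list(mean = mean_all, sem = sem)
}

#' Distance-dependent enthalpy profile
#'
#' `DeltaH(d) = <U + pV>_d - <U + pV>_plateau`, with per-bin averages
#' reweighted by the same WHAM weights as the PMF and standard errors by
#' block averaging. The pV term is retained for NPT-style bookkeeping;
#' at 1 bar it is numerically negligible but the contract is explicit.
#'
#' @param samples list of `hp_window_samples` carrying `U_total` and
#'   `V_nm3`
#' @param pmf the `hp_pmf` estimated from the same samples (supplies
#'   weights, grid and the plateau range)
#' @param pressure_bar pressure for the pV term (default 1; 0 drops it)
#' @param n_blocks blocks for the SEM
#' @return data.frame `d`, `dH`, `sem` (kJ/mol), zero-referenced over
#'   the PMF's plateau range
#' @export
enthalpy_profile <- function(samples, pmf, pressure_bar = 1, n_blocks = 5) {
  if (!all(c("U_total", "V_nm3") %in% names(samples[[1]]$series)))
    stop("samples lack U_total / V_nm3 observables")
  # 1 bar * 1 nm^3 = 1e5 Pa * 1e-27 m^3 * N_A = 0.0602214 kJ/mol
  pv_per_nm3 <- pressure_bar * 0.0602214
  prof <- reweighted_profile(samples, pmf, function(s)
    s$series$U_total + pv_per_nm3 * s$series$V_nm3, n_blocks)
  ref <- reference_bins(pmf$profile$d, prof$mean, pmf$reference_range)
  data.frame(d = pmf$profile$d,
             dH = prof$mean - mean(prof$mean[ref]),
             sem = prof$sem)
}

#' Distance-dependent entropic free-energy profile
#'
#' `-T DeltaS(d) = DeltaG(d) - DeltaH(d)` pointwise on the shared grid;
#' standard errors combined in quadrature.
#'
#' @param pmf an `hp_pmf`
#' @param dh data.frame from [enthalpy_profile()] on the same grid
#' @return data.frame `d`, `minus_TdS`, `sem`
#' @export
entropy_profile <- function(pmf, dh) {
  if (nrow(dh) != nrow(pmf$profile) ||
      any(abs(dh$d - pmf$profile$d) > 1e-9))
    stop("grid mismatch between PMF and enthalpy profile")
  data.frame(d = pmf$profile$d,
             minus_TdS = pmf$profile$G - dh$dH,
             sem = sqrt(pmf$profile$sem^2 + dh$sem^2))
}

#' Distance-dependent volume profile
#'
#' `DeltaV(d) = <V>_d - <V>_plateau` with reweighted averages and block
#' standard errors.
#'
#' @param samples list of `hp_window_samples` with a `V_nm3` series
#' @param pmf matching `hp_pmf`
#' @param n_blocks blocks for the SEM
#' @return data.frame `d`, `dV` (nm^3), `sem`
#' @export
volume_profile <- function(samples, pmf, n_blocks = 5) {
  if (!"V_nm3" %in% names(samples[[1]]$series))
    stop("samples lack the V_nm3 observable")
  prof <- reweighted_profile(samples, pmf, function(s) s$series$V_nm3,
                             n_blocks)
  ref <- reference_bins(pmf$profile$d, prof$mean, pmf$reference_range)
  data.frame(d = pmf$profile$d,
             dV = prof$mean - mean(prof$mean[ref]),
             sem = prof$sem)
}

#' Full thermodynamic profile (ThermoProfile)
#'
#' Convenience wrapper bundling [wham_pmf()] output with
#' [enthalpy_profile()], [entropy_profile()] and [volume_profile()] on a
#' common grid and reference. The identity `dG = dH + minus_TdS` holds
#' on every grid point by construction.
#'
#' @inheritParams enthalpy_profile
#' @return data.frame `d`, `dG`, `dG_sem`, `dH`, `dH_sem`, `minus_TdS`,
#'   `minus_TdS_sem`, `dV`, `dV_sem`
#' @export
thermo_profile <- function(samples, pmf, pressure_bar = 1, n_blocks = 5) {
  dh <- enthalpy_profile(samples, pmf, pressure_bar, n_blocks)
  ts <- entropy_profile(pmf, dh)
  dv <- volume_profile(samples, pmf, n_blocks)
  data.frame(d = pmf$profile$d,
             dG = pmf$profile$G, dG_sem = pmf$profile$sem,
             dH = dh$dH, dH_sem = dh$sem,
             minus_TdS = ts$minus_TdS, minus_TdS_sem = ts$sem,
             dV = dv$dV, dV_sem = dv$sem)
}

#' Nonbonded parameter table
#'
#' Per-atom partial charges and Lennard-Jones parameters for
#' [pair_energies()]. Parameters are supplied by the user (no
#' force-field file parsing).
#'
#' @param charge numeric, e units, one per atom
#' @param sigma numeric, nm
#' @param epsilon numeric, kJ/mol (>= 0)
#' @param combination "geometric" (OPLS-style) or "lorentz"
#' @export
nonbonded_params <- function(charge, sigma, epsilon,
                             combination = c("geometric", "lorentz")) {
  combination <- match.arg(combination)
  stopifnot(length(charge) == length(sigma),
            length(sigma) == length(epsilon), all(epsilon >= 0))
  structure(list(charge = charge, sigma = sigma, epsilon = epsilon,
                 combination = combination), class = "hp_nonbonded")
}

pair_lj_coul <- function(coords, params, idx_i, idx_j, cutoff = 1.0) {
  e_lj <- 0; e_coul <- 0
  for (a in idx_i) {
    dv <- sweep(coords[idx_j, , drop = FALSE], 2, coords[a, ])
    r <- sqrt(rowSums(dv^2))
    if (any(r < 1e-6)) stop("coincident atoms in pair energy evaluation")
    sig <- if (params$combination == "geometric")
      sqrt(params$sigma[a] * params$sigma[idx_j]) else
      (params$sigma[a] + params$sigma[idx_j]) / 2
    eps <- sqrt(params$epsilon[a] * params$epsilon[idx_j])
    sr6 <- (sig / r)^6
    lj <- 4 * eps * (sr6^2 - sr6)
    lj[r > cutoff] <- 0
    e_lj <- e_lj + sum(lj)
    e_coul <- e_coul + sum(COULOMB_KJ_NM * params$charge[a] *
                             params$charge[idx_j] / r)
  }
  c(lj = e_lj, coul = e_coul)
}

#' Residue-pair nonbonded energies for two orientation ensembles
#'
#' Sums Lennard-Jones (truncated at `cutoff`, no smoothing) and bare
#' Coulomb `1/r` terms over inter-residue atom pairs, averaged over
#' frames, for a native and a nonnative ensemble; reports the per-term
#' change `dE = nonnative - native` and flags pairs with
#' `|dE| >` [PAIR_ENERGY_FLAG_KJ] in either term.
#'
#' @param frames_native,frames_nonnative lists of coordinate matrices
#'   (n_atoms x 3, nm), identical atom ordering
#' @param params `hp_nonbonded` for the same atoms
#' @param atom_resno integer residue id per atom
#' @param pairs data.frame with columns `res_i`, `res_j`
#' @param cutoff LJ cutoff, nm (default 1.0)
#' @return data.frame per pair: native/nonnative LJ and Coulomb means,
#'   `dE_lj`, `dE_coul`, `flagged`
#' @export
pair_energies <- function(frames_native, frames_nonnative, params,
                          atom_resno, pairs, cutoff = 1.0) {
  n_atoms <- nrow(frames_native[[1]])
  stopifnot(length(params$charge) == n_atoms,
            length(atom_resno) == n_atoms)
  avg <- function(frames, ri, rj) {
    idx_i <- which(atom_resno == ri); idx_j <- which(atom_resno == rj)
    if (!length(idx_i) || !length(idx_j))
      stop("no atoms for residue pair ", ri, "-", rj)
    acc <- vapply(frames, pair_lj_coul, numeric(2), params = params,
                  idx_i = idx_i, idx_j = idx_j, cutoff = cutoff)
    rowMeans(acc)
  }
  out <- lapply(seq_len(nrow(pairs)), function(p) {
    ri <- pairs$res_i[p]; rj <- pairs$res_j[p]
    en <- avg(frames_native, ri, rj)
    eo <- avg(frames_nonnative, ri, rj)
    data.frame(res_i = ri, res_j = rj,
               E_lj_native = en["lj"], E_coul_native = en["coul"],
               E_lj_nonnative = eo["lj"], E_coul_nonnative = eo["coul"],
               dE_lj = eo["lj"] - en["lj"], dE_coul = eo["coul"] - en["coul"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$flagged <- abs(out$dE_lj) > PAIR_ENERGY_FLAG_KJ |
    abs(out$dE_coul) > PAIR_ENERGY_FLAG_KJ
  out
}

#' Component-energy decomposition by interaction class
#'
#' Means and block standard errors of the LJ and Coulomb energy series
#' per molecular-species class, plus a `sum` row that must equal the
#' recorded total within numerical tolerance.
#'
#' @param samples an `hp_window_samples` whose series carries
#'   `E_lj_<class>` / `E_coul_<class>` columns and `U_total`
#' @param n_blocks blocks for the SEM
#' @return data.frame with columns `class`, `lj`, `lj_sem`, `coul`,
#'   `coul_sem`; the last row is `sum`
#' @export
component_decomposition <- function(samples, n_blocks = 5) {
  ser <- samples$series
  cls <- energy_classes()
  need <- c(paste0("E_lj_", cls), paste0("E_coul_", cls), "U_total")
  miss <- setdiff(need, names(ser))
  if (length(miss)) stop("missing component series: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(cls, function(ci) {
    lj <- ser[[paste0("E_lj_", ci)]]
    cl <- ser[[paste0("E_coul_", ci)]]
    data.frame(class = ci, lj = mean(lj), lj_sem = block_sem(lj, n_blocks),
               coul = mean(cl), coul_sem = block_sem(cl, n_blocks))
  })
  out <- do.call(rbind, rows)
  total_from_classes <- sum(out$lj) + sum(out$coul)
  if (abs(total_from_classes - mean(ser$U_total)) > 1e-6)
    stop("component classes do not sum to the recorded total")
  rbind(out, data.frame(class = "sum",
                        lj = sum(out$lj), lj_sem = NA_real_,
                        coul = sum(out$coul), coul_sem = NA_real_))
}
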