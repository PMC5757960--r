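make_thermo_samples <- function(scenario = "frustrated-H1H2", n = 4000,
                                seed = 211, obs = NULL) {
  tr <- default_landscape(scenario)
  if (!is.null(obs)) tr$spec$observables <- obs
  sched <- build_window_schedule(0.8, 2.6, 0.1, 2000)
  smp <- sample_schedule_direct(tr, sched, c(0, 0), n = n, seed = seed)
  list(truth = tr, samples = smp, pmf = wham_pmf(smp))
}

test_that("enthalpy profile recovers the constructed barrier and the pV arithmetic", {
  fx <- make_thermo_samples()
  dh <- enthalpy_profile(fx$samples, fx$pmf)
  # barrier of the enthalpic (not free-energy) surface at 1.5 nm:
  # location of max(dH - dG) within one bin
  excess <- dh$dH - fx$pmf$profile$G
  ok <- fx$pmf$profile$n > 100
  d_peak <- fx$pmf$profile$d[ok][which.max(excess[ok])]
  expect_lt(abs(d_peak - 1.5), fx$pmf$bin_width + 1e-9)

  # p = 0 vs p = 1 bar differ exactly by the p<V> term
  dh0 <- enthalpy_profile(fx$samples, fx$pmf, pressure_bar = 0)
  dv <- volume_profile(fx$samples, fx$pmf)
  expect_lt(max(abs((dh$dH - dh0$dH) - 0.0602214 * dv$dV), na.rm = TRUE),
            1e-9)
  expect_error(enthalpy_profile(list(fixture_samples(
    data.frame(step = 1:10, d_nm = rep(1, 10)))), fx$pmf), "observables")
})

test_that("with an athermal observable model the enthalpy equals the PMF", {
  # distance-only landscape (no angular basins) with noiseless U = G:
  # the conditional mean of U then equals the marginal free energy
  obs <- default_observables(enthalpy_barrier_height = 0, u_noise_sd = 0,
                             v_noise_sd = 0, volume_barrier_height = 0)
  spec <- new_landscape(base_depth = 25, observables = obs)
  tr <- structure(list(spec = spec, scenario = "athermal", angle_k = 0.1),
                  class = "hp_truth")
  sched <- build_window_schedule(0.8, 2.6, 0.05, 2000)
  smp <- sample_schedule_direct(tr, sched, c(0, 0), n = 3000, seed = 212)
  pmf <- wham_pmf(smp, bin_width = 0.01)
  dh <- enthalpy_profile(smp, pmf, n_blocks = 0)
  # fine bins, away from the steep repulsive wall where histogram
  # discretisation dominates both estimators differently
  ok <- pmf$profile$n > 200 & pmf$profile$d > 1.05
  expect_lt(sqrt(mean((dh$dH[ok] - pmf$profile$G[ok])^2)), 0.35)
})

test_that("entropy profile closes the thermodynamic identity exactly", {
  fx <- make_thermo_samples(seed = 213, n = 1500)
  dh <- enthalpy_profile(fx$samples, fx$pmf)
  ts <- entropy_profile(fx$pmf, dh)
  expect_equal(dh$dH + ts$minus_TdS, fx$pmf$profile$G, tolerance = 1e-12)
  tp <- thermo_profile(fx$samples, fx$pmf)
  expect_equal(tp$dH + tp$minus_TdS, tp$dG, tolerance = 1e-12)
  # compensated barrier: -TdS shows an equal and opposite dip at 1.5 nm
  ok <- fx$pmf$profile$n > 100
  i_dip <- which.min(tp$minus_TdS[ok])
  expect_lt(abs(tp$d[ok][i_dip] - 1.5), 3 * fx$pmf$bin_width)
  expect_error(entropy_profile(fx$pmf, dh[-1, ]), "grid mismatch")
})

test_that("volume profile recovers the barrier, is unbiased, and can be flat", {
  fx <- make_thermo_samples(seed = 214)
  dv <- volume_profile(fx$samples, fx$pmf)
  ok <- fx$pmf$profile$n > 100
  expect_lt(abs(dv$d[ok][which.max(dv$dV[ok])] - 1.45),
            fx$pmf$bin_width + 1e-9)

  # doubling the noise leaves the mean profile unchanged within 3 SEM
  obs2 <- default_observables(v_noise_sd = 0.06)
  fx2 <- make_thermo_samples(obs = obs2, seed = 214)
  dv2 <- volume_profile(fx2$samples, fx2$pmf)
  ok2 <- ok & fx2$pmf$profile$n > 100 & is.finite(dv2$sem) & is.finite(dv$sem)
  comb <- sqrt(dv$sem[ok2]^2 + dv2$sem[ok2]^2)
  expect_true(all(abs(dv2$dV[ok2] - dv$dV[ok2]) <
                    pmax(3.5 * comb, 0.01)))

  obs0 <- default_observables(volume_barrier_height = 0)
  fx0 <- make_thermo_samples(obs = obs0, seed = 215, n = 2000)
  dv0 <- volume_profile(fx0$samples, fx0$pmf)
  ok0 <- fx0$pmf$profile$n > 100 & is.finite(dv0$sem)
  expect_true(all(abs(dv0$dV[ok0]) < pmax(3.5 * dv0$sem[ok0], 0.005)))
})

test_that("pair energies match closed forms and a brute-force double loop", {
  # two neutral atoms at the LJ minimum: E_LJ = -eps, E_coul = 0
  sig <- 0.35; eps <- 0.6
  r_min <- 2^(1 / 6) * sig
  coords <- rbind(c(0, 0, 0), c(r_min, 0, 0))
  par <- nonbonded_params(charge = c(0, 0), sigma = c(sig, sig),
                          epsilon = c(eps, eps))
  tab <- pair_energies(list(coords), list(coords), par,
                       atom_resno = c(1L, 2L),
                       pairs = data.frame(res_i = 1L, res_j = 2L))
  expect_equal(tab$E_lj_native, -eps, tolerance = 1e-12)
  expect_equal(tab$E_coul_native, 0)
  expect_false(tab$flagged)

  # unit charges at 1 nm: bare Coulomb prefactor
  par_q <- nonbonded_params(charge = c(1, -1), sigma = c(0.3, 0.3),
                            epsilon = c(0, 0))
  coords_q <- rbind(c(0, 0, 0), c(1, 0, 0))
  tab_q <- pair_energies(list(coords_q), list(coords_q), par_q,
                         atom_resno = c(1L, 2L),
                         pairs = data.frame(res_i = 1L, res_j = 2L))
  expect_equal(tab_q$E_coul_native, -138.935485, tolerance = 1e-9)

  # brute-force double loop oracle on a random two-residue system
  set.seed(99)
  n_at <- 8
  coords_r <- matrix(runif(3 * n_at, 0, 0.8), n_at, 3)
  resno <- rep(c(1L, 2L), each = 4)
  par_r <- nonbonded_params(charge = runif(n_at, -0.5, 0.5),
                            sigma = runif(n_at, 0.25, 0.4),
                            epsilon = runif(n_at, 0.1, 0.8))
  cutoff <- 1.0
  brute_lj <- 0; brute_coul <- 0
  for (i in which(resno == 1L)) for (j in which(resno == 2L)) {
    r <- sqrt(sum((coords_r[i, ] - coords_r[j, ])^2))
    sij <- sqrt(par_r$sigma[i] * par_r$sigma[j])
    eij <- sqrt(par_r$epsilon[i] * par_r$epsilon[j])
    if (r <= cutoff) brute_lj <- brute_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    brute_coul <- brute_coul + 138.935485 * par_r$charge[i] *
      par_r$charge[j] / r
  }
  tab_r <- pair_energies(list(coords_r), list(coords_r), par_r,
                         atom_resno = resno,
                         pairs = data.frame(res_i = 1L, res_j = 2L))
  expect_equal(tab_r$E_lj_native, brute_lj, tolerance = 1e-10)
  expect_equal(tab_r$E_coul_native, brute_coul, tolerance = 1e-10)
  expect_equal(tab_r$dE_lj, 0)
  expect_equal(tab_r$dE_coul, 0)
})

test_that("component decomposition closes on the total and localises changes", {
  tr <- default_landscape("frustrated-H1H2")
  s_nat <- sample_window_direct(tr, new_window(1.1, 2000), n = 3000,
                                seed = 61)
  dec <- component_decomposition(s_nat)
  sum_row <- dec[dec$class == "sum", ]
  expect_equal(sum_row$lj + sum_row$coul, mean(s_nat$series$U_total),
               tolerance = 1e-9)

  # permuting class labels permutes the output rows correspondingly
  s_perm <- s_nat
  nm <- names(s_perm$series)
  a <- "E_lj_inter_bundle"; b <- "E_lj_solv_solv"
  names(s_perm$series)[match(c(a, b), nm)] <- c(b, a)
  dec_p <- component_decomposition(s_perm)
  expect_equal(dec_p$lj[dec_p$class == "inter_bundle"],
               dec$lj[dec$class == "solv_solv"])
  expect_equal(dec_p$lj[dec_p$class == "solv_solv"],
               dec$lj[dec$class == "inter_bundle"])

  # constructed 5 kJ/mol drop in nonnative inter-bundle LJ
  s_non <- s_nat
  s_non$series$E_lj_inter_bundle <- s_non$series$E_lj_inter_bundle - 5
  s_non$series$U_total <- s_non$series$U_total - 5
  dec_n <- component_decomposition(s_non)
  delta <- dec_n$lj[dec_n$class == "inter_bundle"] -
    dec$lj[dec$class == "inter_bundle"]
  expect_equal(delta, -5, tolerance = 1e-9)

  s_bad <- s_nat
  s_bad$series$E_coul_solv_ref <- NULL
  expect_error(component_decomposition(s_bad), "missing component")
})
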