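test_that("ideal helices have the constructed geometry", {
  h <- build_ideal_helix("AELKLAELKLAELKLAELKL")  # 20 residues
  expect_lt(max(abs(fit_helix_axis(h) - c(0, 0, 1))), 1e-6)
  ca <- calpha_coords(h)
  gaps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(gaps - 0.38) < 0.01))
  # helical-wheel phase repeats every 18 residues at 100 deg/residue
  expect_equal(wheel_phase(1), wheel_phase(19))
  expect_equal(wheel_phase(4), (wheel_phase(22 - 18) + 0) %% 360)
  expect_error(build_ideal_helix("AXZ"), "unknown residue")
  expect_error(build_ideal_helix(""), "non-empty")
  # glycine has no CB
  g <- build_ideal_helix("GAG")
  expect_equal(sum(g$atom_names == "CB"), 1L)
})

test_that("the scenario catalogue encodes the intended thermodynamics", {
  expect_setequal(landscape_scenarios(),
                  c("frustrated-H1H2", "native-favoring", "flat"))
  expect_error(default_landscape("nope"), "unknown scenario")

  fl <- default_landscape("flat")
  expect_true(truth_delta_g(fl, c(0, 0))$no_basin)

  fr <- default_landscape("frustrated-H1H2")
  dd <- truth_delta_g(fr, c(19, 4))$value - truth_delta_g(fr, c(0, 0))$value
  expect_lt(abs(dd - (-10)), 0.25)
  # second nonnative basin also beats native
  expect_lt(truth_delta_g(fr, c(-20, -20))$value,
            truth_delta_g(fr, c(0, 0))$value)

  nf <- default_landscape("native-favoring")
  expect_lt(truth_delta_g(nf, c(0, 0))$value,
            truth_delta_g(nf, c(19, 4))$value)

  # quadrature stability under 2x grid refinement
  a <- truth_delta_g(fr, c(0, 0), d_step = 0.002)$value
  b <- truth_delta_g(fr, c(0, 0), d_step = 0.001)$value
  expect_lt(abs(a - b), 0.01)
})

test_that("direct window sampling reproduces the analytic biased density", {
  tr <- default_landscape("frustrated-H1H2")
  w <- new_window(1.2, 2000)
  s <- sample_window_direct(tr, w, n = 10000, seed = 17)
  # analytic biased marginal over coarse d bins, integrating the fine
  # grid the density lives on
  dg <- seq(0.95, 1.45, by = 0.025)
  th <- expand.grid(t1 = seq(-22, 22, 0.5), t2 = seq(-22, 22, 0.5))
  b <- tr$angle_k / 2 * (th$t1^2 + th$t2^2)
  cell_weight <- function(d0)
    sum(exp(-(eval_landscape(tr$spec, d0, th$t1, th$t2) +
                w$k / 2 * (d0 - w$d0)^2 + b) / tr$spec$RT))
  marg <- vapply(seq_len(length(dg) - 1), function(i) {
    fine <- seq(dg[i] + 0.00125, dg[i + 1] - 0.00125, by = 0.0025)
    sum(vapply(fine, cell_weight, numeric(1)))
  }, numeric(1))
  counts <- table(cut(s$series$d_nm, dg))
  inside <- s$series$d_nm > dg[1] & s$series$d_nm <= dg[length(dg)]
  expect_gt(mean(inside), 0.99)
  p <- marg / sum(marg)
  keep <- p * sum(counts) > 5
  chi <- suppressWarnings(chisq.test(as.numeric(counts[keep]),
                                     p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.01)

  # determinism and seed sensitivity
  expect_identical(sample_window_direct(tr, w, n = 200, seed = 5)$series,
                   sample_window_direct(tr, w, n = 200, seed = 5)$series)
  expect_false(identical(
    sample_window_direct(tr, w, n = 200, seed = 5)$series$d_nm,
    sample_window_direct(tr, w, n = 200, seed = 6)$series$d_nm))
})

test_that("AR(1) thinning controls autocorrelation without changing the law", {
  tr <- default_landscape("frustrated-H1H2")
  w <- new_window(1.2, 2000)
  s0 <- sample_window_direct(tr, w, n = 8000, seed = 19, autocorrelation = 0)
  s5 <- sample_window_direct(tr, w, n = 8000, seed = 19, autocorrelation = 0.5)
  ac0 <- acf(s0$series$d_nm, plot = FALSE)$acf[2]
  ac5 <- acf(s5$series$d_nm, plot = FALSE)$acf[2]
  expect_lt(abs(ac0), 0.05)
  expect_lt(abs(ac5 - 0.5), 0.1)
  # marginal unchanged
  ks <- suppressWarnings(ks.test(s0$series$d_nm, s5$series$d_nm))
  expect_gt(ks$p.value, 0.01)
})

test_that("window samples survive a serialisation round trip", {
  tr <- default_landscape("frustrated-H1H2")
  s <- sample_window_direct(tr, new_window(1.1, 2000), n = 50, seed = 23)
  dir <- tempfile(); dir.create(dir)
  f <- file.path(dir, "w1.tsv")
  write_window_samples(s, f)
  s2 <- read_window_samples(f)
  expect_equal(s2$window$d0, s$window$d0)
  expect_equal(s2$series$d_nm, s$series$d_nm, tolerance = 1e-9)
  expect_equal(s2$seed, s$seed)

  man <- write_campaign(list(s, s), dir)
  back <- read_campaign(man)
  expect_length(back, 2L)
  expect_equal(back[[1]]$series$U_total, s$series$U_total, tolerance = 1e-9)
})

test_that("rigid-body jitter has the designed spread and zero-amplitude identity", {
  sys <- build_helix_dimer(1.0)
  bundle <- new_bundle(c(sys$reference$fragments, sys$mobile$fragments))
  frozen <- jittered_trajectory(bundle, amplitude = 0, n_frames = 3, seed = 2)
  expect_identical(frozen[[1]], frozen[[3]])
  expect_equal(frozen[[1]], bundle_coords(bundle))

  # axial rotation jitter around an applied +30 target
  rot <- rotate_fragment(sys$mobile, "H2", 30)
  frames <- jittered_trajectory(rot, amplitude = 0, n_frames = 40,
                                seed = 3, rot_sd_deg = 4)
  ref <- sys$mobile$fragments$H2
  angles <- vapply(frames, measure_rotation_angle, numeric(1),
                   reference = ref)
  expect_lt(abs(mean(angles) - 30), 10)
  expect_lt(abs(sd(angles) - 4), 2)
})
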