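test_that("WHAM recovers the analytic landscape from biased window samples", {
  tr <- default_landscape("frustrated-H1H2")
  sched <- build_window_schedule(0.7, 2.6, 0.05, 2000)
  smp <- sample_schedule_direct(tr, sched, c(0, 0), n = 5000, seed = 101)
  pmf <- wham_pmf(smp, orientation = "native")
  truth <- truth_profile(tr, c(0, 0))
  g_true <- approx(truth$d, truth$G, xout = pmf$profile$d)$y
  well <- pmf$profile$n > 100 & is.finite(g_true)
  # align the truth to the same plateau reference
  ref <- pmf$profile$d >= 2.3 & pmf$profile$d <= 2.6 & well
  g_true <- g_true - mean(g_true[ref])
  rms <- sqrt(mean((pmf$profile$G[well] - g_true[well])^2))
  expect_lt(rms, 0.5)

  dg <- delta_g_bind(pmf)
  dg_true <- truth_delta_g(tr, c(0, 0))
  expect_false(dg$no_basin)
  expect_lt(abs(dg$value - dg_true$value), 0.5)
})

test_that("flat landscapes give flat PMFs and no bound basin", {
  tr <- default_landscape("flat")
  sched <- build_window_schedule(1.2, 2.6, 0.1, 2000)
  smp <- sample_schedule_direct(tr, sched, c(0, 0), n = 3000, seed = 55)
  pmf <- wham_pmf(smp, orientation = "flat")
  well <- pmf$profile$n > 100 & is.finite(pmf$profile$sem)
  expect_true(all(abs(pmf$profile$G[well]) <
                    pmax(3 * pmf$profile$sem[well], 0.3)))
  expect_true(delta_g_bind(pmf)$no_basin)
})

test_that("a single stiff window reproduces the closed-form quadratic PMF", {
  # oracle: iid draws from the product-of-Gaussians density; the
  # underlying landscape is quadratic with curvature a
  a <- 500; c0 <- 1.5; k <- 4000; d0 <- 1.55
  prec <- a + k
  mu <- (a * c0 + k * d0) / prec
  set.seed(77)
  d <- rnorm(40000, mu, sqrt(RT_300K / prec))
  smp <- fixture_samples(data.frame(step = seq_along(d), d_nm = d),
                         d0 = d0, k = k)
  pmf <- wham_pmf(list(smp), bin_width = 0.005, reference_range = NULL,
                  n_blocks = 0)
  well <- pmf$profile$n > 200
  g_est <- pmf$profile$G[well]
  g_true <- a / 2 * (pmf$profile$d[well] - c0)^2
  g_true <- g_true - mean(g_true) + mean(g_est)  # common reference
  expect_lt(sqrt(mean((g_est - g_true)^2)), 0.2)
})

test_that("WHAM names the gap when adjacent windows do not overlap", {
  tr <- default_landscape("flat")
  w1 <- sample_window_direct(tr, new_window(1.0, 5e4), n = 500, seed = 1)
  w2 <- sample_window_direct(tr, new_window(2.5, 5e4), n = 500, seed = 2)
  expect_error(wham_pmf(list(w1, w2)), "overlap")
})

test_that("basin integration matches direct summation and flags empty basins", {
  d <- seq(1, 2.6, by = 0.05)
  flat <- fixture_pmf(d, rep(0, length(d)), reference_range = c(2.3, 2.6))
  expect_true(delta_g_bind(flat)$no_basin)

  # single-bin basin of depth G0 with bin width = l_ref: value = G0
  G <- rep(0, length(d)); G[6] <- -12
  one <- fixture_pmf(d, G, reference_range = c(2.3, 2.6))
  got <- delta_g_bind(one, l_ref = 0.05)
  expect_equal(got$value, -12, tolerance = 1e-9)

  # deep two-bin basin: brute-force -RT log sum over those bins
  G2 <- rep(0, length(d)); G2[6] <- -20; G2[7] <- -18
  two <- fixture_pmf(d, G2, reference_range = c(2.3, 2.6))
  got2 <- delta_g_bind(two, l_ref = 0.05)
  brute <- -RT_300K * log((exp(20 / RT_300K) + exp(18 / RT_300K)) *
                            0.05 / 0.05)
  expect_equal(got2$value, brute, tolerance = 1e-9)
  expect_equal(got2$basin_range, c(d[6], d[7]))
})

test_that("ddG bookkeeping reproduces printed arithmetic and combines errors", {
  native <- binding_value(-33, 0.3, "native")
  rot <- binding_value(-43, 1, "+30")
  d <- ddg(native, rot)
  expect_equal(d$value, -10)
  expect_equal(d$sem, sqrt(0.3^2 + 1^2))
  expect_equal(ddg(rot, rot)$value, 0)

  # fragment comparison mode
  dA <- binding_value(-49, 1, "H2/H4")
  dB <- binding_value(-75, 1, "H2LH3LH4C")
  expect_equal(ddg(dA, dB)$value, -26)

  expect_error(ddg(binding_value(NA), rot), "no bound basin")
})

test_that("population ratio is the Boltzmann factor of the stabilization", {
  expect_equal(population_ratio(0), 1)
  expect_equal(population_ratio(RT_300K * log(50)), 50, tolerance = 1e-9)
  expect_equal(population_ratio(-RT_300K * log(50)), 50, tolerance = 1e-9)
  expect_equal(population_ratio(10), exp(10 / 2.4943), tolerance = 1e-4)
  expect_gt(population_ratio(10), 50)
})

test_that("block SEM matches the iid law and inflates under autocorrelation", {
  set.seed(123)
  sems <- replicate(100, block_sem(rnorm(1e4, 0, 2), 20))
  expect_lt(abs(mean(sems) / (2 / sqrt(1e4)) - 1), 0.2)
  expect_equal(block_sem(rep(3.3, 100), 5), 0)
  # AR(1) with phi = 0.9: block SEM must exceed the naive iid SEM
  phi <- 0.9
  x <- as.numeric(arima.sim(list(ar = phi), 2e4))
  expect_gt(block_sem(x, 20), sd(x) / sqrt(length(x)))
  expect_error(block_sem(1:5, 5), "too short")
})

test_that("convergence scan is stable on stationary data and detects drift", {
  tr <- default_landscape("frustrated-H1H2")
  sched <- build_window_schedule(0.8, 2.6, 0.1, 2000)
  smp <- sample_schedule_direct(tr, sched, c(0, 0), n = 2000, seed = 31)
  full_pmf <- wham_pmf(smp, n_blocks = 5)
  full <- delta_g_bind(full_pmf)
  scan <- convergence_scan(smp, window_length = 1000)
  expect_gte(nrow(scan), 2)
  expect_true(all(abs(scan$dG - full$value) < 3 * pmax(full$sem, 0.15)))

  single <- convergence_scan(smp, window_length = 2000)
  expect_equal(nrow(single), 1L)
  full0 <- wham_pmf(smp, n_blocks = 0)
  expect_equal(single$dG, delta_g_bind(full0)$value, tolerance = 1e-9)

  # constructed drift: first half sampled from a much shallower landscape
  tr2 <- default_landscape("flat")
  smp_drift <- lapply(seq_along(sched), function(i) {
    s1 <- sample_window_direct(tr2, sched[[i]], n = 1000, seed = 400 + i)
    s2 <- smp[[i]]
    s2$series <- rbind(s1$series, s2$series[1:1000, ])
    s2$series$step <- seq_len(nrow(s2$series))
    s2
  })
  scan2 <- convergence_scan(smp_drift, window_length = 1000)
  expect_gt(max(scan2$dG) - min(scan2$dG), 3 * max(full$sem, 0.15))
})

test_that("PMF reference invariance and basin-depth monotonicity hold", {
  d <- seq(1, 2.6, by = 0.05)
  G <- -15 * exp(-(d - 1.3)^2 / (2 * 0.04))
  G <- G - mean(G[d >= 2.3 & d <= 2.6])  # zero-referenced at the plateau
  pmf <- fixture_pmf(d, G, reference_range = c(2.3, 2.6))
  base <- delta_g_bind(pmf)

  shifted <- pmf
  shifted$profile$G <- shifted$profile$G + 7.5
  refb <- shifted$profile$d >= 2.3 & shifted$profile$d <= 2.6
  shifted$profile$G <- shifted$profile$G - mean(shifted$profile$G[refb])
  expect_equal(delta_g_bind(shifted)$value, base$value, tolerance = 1e-12)

  deeper <- pmf
  deeper$profile$G <- ifelse(pmf$profile$G < 0, pmf$profile$G * 1.25,
                             pmf$profile$G)
  expect_lt(delta_g_bind(deeper)$value, base$value)
})

test_that("2D packing landscape takes per-geometry minima on a shared reference", {
  tr <- default_landscape("frustrated-H1H2")
  targets <- rbind(c(0, 0), c(19, 4), c(-20, -20), c(30, -10))
  profiles <- lapply(seq_len(nrow(targets)), function(i) {
    prof <- truth_profile(tr, targets[i, ], d_grid = seq(0.8, 2.6, 0.02))
    fixture_pmf(prof$d, prof$G, reference_range = c(2.3, 2.6),
                orientation = sprintf("t%d", i)) |>
      (\(p) { p$angle_targets <- targets[i, ]; p })()
  })
  map <- assemble_pmf2d(profiles)
  expect_equal(sum(map$sampled), 4L)
  # minima equal brute-force scans of each profile
  for (i in seq_len(nrow(targets))) {
    r <- match(targets[i, 1], map$theta1); c <- match(targets[i, 2], map$theta2)
    expect_equal(map$G[r, c], min(profiles[[i]]$profile$G))
  }
  expect_equal(unname(pmf2d_argmin(map)), c(19, 4))

  single <- assemble_pmf2d(profiles[2])
  expect_equal(dim(single$G), c(1L, 1L))
  expect_equal(single$G[1, 1], min(profiles[[2]]$profile$G))

  bad <- profiles
  bad[[2]]$reference_range <- c(2.0, 2.4)
  expect_error(assemble_pmf2d(bad), "referencing")
})
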