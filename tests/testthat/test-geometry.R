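test_that("helix axis fit recovers construction, sign and equivariance", {
  h <- fixture_helix(12)
  expect_lt(max(abs(fit_helix_axis(h) - c(0, 0, 1))), 1e-6)

  # flip the helix end-over-end (proper rotation about x): N->C now -z
  hf <- h
  hf$coords[, 2] <- -hf$coords[, 2]
  hf$coords[, 3] <- -hf$coords[, 3]
  expect_lt(max(abs(fit_helix_axis(hf) - c(0, 0, -1))), 1e-6)

  # equivariance under a known rotation
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE) %*%
       matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)),
              3, 3, byrow = TRUE)
  hr <- h
  hr$coords <- h$coords %*% t(R)
  expect_lt(max(abs(fit_helix_axis(hr) - drop(R %*% c(0, 0, 1)))), 1e-6)

  short <- fixture_residue(1, c(0, 0, 0))
  expect_error(fit_helix_axis(short), "fewer than 4")
})

test_that("fragment rotation is rigid, invertible and identity at zero", {
  b <- new_bundle(list(H1 = fixture_helix(12)))
  expect_equal(rotate_fragment(b, "H1", 0)$fragments$H1$coords,
               b$fragments$H1$coords)
  back <- rotate_fragment(rotate_fragment(b, "H1", 30), "H1", -30)
  expect_lt(max(abs(back$fragments$H1$coords - b$fragments$H1$coords)), 1e-9)
  # rigidity: brute-force pairwise distance matrices
  d0 <- as.matrix(dist(b$fragments$H1$coords))
  d1 <- as.matrix(dist(rotate_fragment(b, "H1", 30)$fragments$H1$coords))
  expect_lt(max(abs(d1 - d0)), 1e-9)
  expect_error(rotate_fragment(b, "H9", 10), "unknown fragment")
})

test_that("rotation measurement round-trips applied angles within 0.5 degrees", {
  ref <- fixture_helix(14)
  b <- new_bundle(list(H = ref))
  for (ang in seq(-50, 50, by = 10)) {
    rb <- rotate_fragment(b, "H", ang)
    expect_lt(abs(measure_rotation_angle(rb$fragments$H$coords, ref) - ang),
              0.5)
  }
  expect_equal(measure_rotation_angle(ref$coords, ref), 0, tolerance = 1e-9)
  expect_equal(measure_rotation_angle(ref$coords, ref, baseline_deg = 5), -5,
               tolerance = 1e-9)
  expect_error(measure_rotation_angle(ref$coords[-1, ], ref), "atom count")
})

test_that("crossing-angle changes are invertible and shift the measured angle", {
  sys <- build_helix_dimer(separation_nm = 1.2)
  same <- set_crossing_angle(sys, 0)
  expect_equal(same$mobile$fragments$H2$coords, sys$mobile$fragments$H2$coords)
  rt <- set_crossing_angle(set_crossing_angle(sys, 40), -40)
  expect_lt(max(abs(rt$mobile$fragments$H2$coords -
                    sys$mobile$fragments$H2$coords)), 1e-9)
  native <- crossing_angle(sys)
  after <- crossing_angle(set_crossing_angle(sys, 30))
  delta <- (after - native + 180) %% 360 - 180
  expect_lt(abs(delta - 30), 0.5)
})

test_that("window schedule matches the 39-window design and brute-force grid", {
  sched <- build_window_schedule(0.7, 2.6, 0.05, 2000)
  expect_length(sched, 39L)
  expect_equal(vapply(sched, `[[`, numeric(1), "k"), rep(2000, 39))
  # independent loop construction of the center list
  centers <- c(); x <- 0.7
  while (x <= 2.6 + 1e-9) { centers <- c(centers, x); x <- x + 0.05 }
  expect_equal(window_centers(sched), centers, tolerance = 1e-12)

  expect_length(build_window_schedule(1.0, 1.0, 0.05), 1L)
  expect_equal(build_window_schedule(1.0, 1.0, 0.05)[[1]]$d0, 1.0)
  expect_error(build_window_schedule(0.7, 2.6, 0), "positive")

  # count formula against brute-force enumeration on varied grids
  for (case in list(c(0.7, 2.6, 0.05), c(1, 2, 0.3), c(0.5, 0.8, 0.07))) {
    n_formula <- floor((case[2] - case[1]) / case[3] + 1e-9) + 1
    expect_length(build_window_schedule(case[1], case[2], case[3]), n_formula)
  }
})

test_that("orientation enumeration yields 2 x 2 x m distinct nonnative states", {
  sys <- build_helix_dimer()
  full <- enumerate_orientations(sys, c(10, 20, 30, 40, 50))
  expect_length(full, 20L)
  one <- enumerate_orientations(sys, 30)
  expect_length(one, 4L)
  labs <- t(vapply(full, function(s)
    c(s$orientation$rotated_fragment,
      as.character(s$orientation$angle_deg)), character(2)))
  expect_false(any(duplicated(labs)))
  expect_true(all(vapply(full, function(s) !s$orientation$native, logical(1))))
  expect_error(enumerate_orientations(sys, c(0, 30)), "native")
})

test_that("PDB round trip preserves fragments and flags bad ranges", {
  sys <- build_helix_dimer()
  tf <- tempfile(fileext = ".pdb")
  write_bundles_pdb(list(sys$reference, sys$mobile), tf)
  pdb <- bio3d::read.pdb(tf)
  b <- extract_fragments(pdb, list(c(1, 12)), chain = "A")
  fr <- b$fragments[[1]]
  expect_length(fr$residue_ids, 12L)
  expect_length(fr$calpha_index, 12L)
  expect_lt(max(abs(calpha_coords(fr) -
                    calpha_coords(sys$reference$fragments$H1)[1:12, ])),
            1e-3)
  expect_error(extract_fragments(pdb, list()), "empty range")
  expect_error(extract_fragments(pdb, list(c(90, 95)), chain = "A"),
               "missing")
})
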