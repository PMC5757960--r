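#' PMF estimation and binding free-energy bookkeeping
#'
#' Self-consistent histogram reweighting (WHAM) over harmonic umbrella
#' biases yields a distance-dependent PMF per orientation, zero-referenced
#' over an unbound plateau range. Binding free energies integrate the
#' Boltzmann population of the bound basin; differences between
#' orientations or binding partners are carried with block-averaged
#' standard errors combined in quadrature.
#'
#' @name free_energy
NULL

wham_solve <- function(counts, n_w, bias_b_w, RT, tol, max_iter,
                       g_init = NULL) {
  # counts: B x W histogram; bias_b_w: B x W bias energies at bin centers
  B <- nrow(counts); W <- ncol(counts)
  g <- g_init %||% rep(0, W)            # window free energies, kJ/mol
  Nb <- rowSums(counts)
  logN_w <- log(n_w)
  for (it in seq_len(max_iter)) {
    # log denominator per bin: log sum_w N_w exp((g_w - u_bw)/RT)
    A <- sweep(-bias_b_w, 2, g, `+`) / RT
    A <- sweep(A, 2, logN_w, `+`)
    m <- A[cbind(seq_len(B), max.col(A, ties.method = "first"))]
    log_den <- m + log(rowSums(exp(A - m)))
    logP <- ifelse(Nb > 0, log(Nb) - log_den, -Inf)
    # update window free energies: g_w = -RT log sum_b P_b exp(-u_bw/RT)
    Bmat <- logP - bias_b_w / RT
    mb <- apply(Bmat, 2, max)
    g_new <- -RT * (mb + log(colSums(exp(sweep(Bmat, 2, mb)))))
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < tol) {
      logP <- logP - max(logP)
      return(list(logP = logP, g = g, iter = it, residual = delta))
    }
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
               max_iter, delta))
}

#' Estimate a distance-dependent PMF by WHAM
#'
#' @param samples list of `hp_window_samples` with overlapping d
#'   histograms (a single window degenerates to direct Boltzmann
#'   inversion of its biased histogram)
#' @param bin_width histogram bin width, nm (default 0.02)
#' @param tol convergence tolerance on window free energies, kJ/mol
#' @param max_iter iteration cap
#' @param reference_range nm interval over which the PMF is
#'   zero-referenced (unbound plateau; default 2.3-2.6 nm); NULL
#'   references to the mean over all finite bins (profiles defined up
#'   to a constant only)
#' @param n_blocks contiguous blocks for the per-bin standard error
#' @param orientation label attached to the profile
#' @return object of class `hp_pmf`: data.frame `profile` with columns
#'   `d`, `G`, `sem`, `n` plus metadata
#' @export
wham_pmf <- function(samples, bin_width = 0.02, tol = 1e-6,
                     max_iter = 50000, reference_range = c(2.3, 2.6),
                     n_blocks = 5, orientation = "native") {
  stopifnot(length(samples) >= 1L)
  ord <- order(vapply(samples, function(s) s$window$d0, numeric(1)))
  samples <- samples[ord]
  d_list <- lapply(samples, function(s) s$series$d_nm)
  d0 <- vapply(samples, function(s) s$window$d0, numeric(1))
  kk <- vapply(samples, function(s) s$window$k, numeric(1))
  RT <- RT_300K
  rng <- range(unlist(d_list))
  # adjacent-window overlap check before binning
  for (i in seq_len(length(samples) - 1L)) {
    if (min(d_list[[i + 1]]) > max(d_list[[i]]) + bin_width)
      stop(sprintf(
        "no histogram overlap between windows at d0 = %.3f and %.3f nm (gap %.3f-%.3f nm)",
        d0[i], d0[i + 1], max(d_list[[i]]), min(d_list[[i + 1]])))
  }
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  B <- length(centers); W <- length(samples)
  counts <- vapply(d_list, function(dd)
    tabulate(findInterval(dd, breaks, rightmost.closed = TRUE), nbins = B),
    integer(B))
  n_w <- colSums(counts)
  bias_b_w <- outer(centers, seq_len(W),
                    function(b, w) kk[w] / 2 * (b - d0[w])^2)
  fit <- wham_solve(counts, n_w, bias_b_w, RT, tol, max_iter)
  G <- -RT * fit$logP
  keep <- is.finite(G)
  ref <- reference_bins(centers, G, reference_range)
  G <- G - mean(G[ref])
  # per-bin SEM by block averaging: refit WHAM per contiguous block
  sem <- rep(NA_real_, B)
  if (n_blocks >= 2) {
    blockG <- matrix(NA_real_, B, n_blocks)
    for (b in seq_len(n_blocks)) {
      cb <- vapply(d_list, function(dd) {
        n <- length(dd); size <- floor(n / n_blocks)
        sl <- dd[seq((b - 1) * size + 1, b * size)]
        tabulate(findInterval(sl, breaks, rightmost.closed = TRUE), nbins = B)
      }, integer(B))
      fb <- try(wham_solve(cb, colSums(cb), bias_b_w, RT,
                           tol * 10, max_iter, g_init = fit$g), silent = TRUE)
      if (!inherits(fb, "try-error")) {
        Gb <- -RT * fb$logP
        refb <- reference_bins(centers, Gb, reference_range)
        blockG[, b] <- Gb - mean(Gb[refb])
      }
    }
    ok <- rowSums(is.finite(blockG)) == n_blocks
    sem[ok] <- apply(blockG[ok, , drop = FALSE], 1, stats::sd) /
      sqrt(n_blocks)
  }
  structure(list(profile = data.frame(d = centers[keep], G = G[keep],
                                      sem = sem[keep],
                                      n = rowSums(counts)[keep]),
                 bin_width = bin_width,
                 reference_range = reference_range,
                 orientation = orientation,
                 angle_targets = samples[[1]]$angle_bias$targets,
                 window_free_energies = fit$g,
                 iterations = fit$iter,
                 temperature_K = DEFAULT_TEMPERATURE_K),
            class = "hp_pmf")
}

reference_bins <- function(centers, G, reference_range) {
  if (is.null(reference_range)) return(which(is.finite(G)))
  ref <- which(centers >= reference_range[1] &
               centers <= reference_range[2] & is.finite(G))
  if (!length(ref))
    stop("no finite PMF bins inside the reference (plateau) range")
  ref
}

#' @export
print.hp_pmf <- function(x, ...) {
  cat(sprintf(
    "<hp_pmf> %s: %d bins (%.2f-%.2f nm), min G = %.2f kJ/mol at %.2f nm\n",
    x$orientation, nrow(x$profile), min(x$profile$d), max(x$profile$d),
    min(x$profile$G), x$profile$d[which.min(x$profile$G)]))
  invisible(x)
}

#' Basin-integrated binding free energy from a PMF
#'
#' `DeltaG_bind = -RT log( sum_basin exp(-G/RT) * dd / l_ref )`, where
#' the basin is the maximal contiguous set of bins containing the global
#' PMF minimum (ties broken toward smaller d) with `G` below
#' `threshold`, restricted to `d <= d_cap`. With a common `l_ref` across
#' systems, differences between orientations are independent of `l_ref`;
#' absolute values are relative, not standard-state, quantities.
#'
#' @param pmf an `hp_pmf`, zero-referenced at the plateau
#' @param temperature_K temperature, K
#' @param l_ref reference length, nm (default one window spacing,
#'   0.05 nm)
#' @param threshold basin membership threshold, kJ/mol; default plateau
#'   value (0) minus RT/2
#' @param d_cap hard upper bound on basin extent, nm
#' @return object of class `hp_binding` with fields `value`, `sem`,
#'   `basin_range`, `no_basin`, `orientation`
#' @export
delta_g_bind <- function(pmf, temperature_K = DEFAULT_TEMPERATURE_K,
                         l_ref = 0.05, threshold = NULL, d_cap = 2.0) {
  stopifnot(temperature_K > 0)
  RT <- GAS_CONSTANT_KJ * temperature_K
  threshold <- threshold %||% (-RT / 2)
  pr <- pmf$profile
  elig <- pr$G < threshold & pr$d <= d_cap
  if (!any(elig)) {
    return(structure(list(value = NA_real_, sem = NA_real_,
                          basin_range = c(NA_real_, NA_real_),
                          no_basin = TRUE, orientation = pmf$orientation),
                     class = "hp_binding"))
  }
  gmin <- min(pr$G[elig])
  i_min <- which(elig & pr$G == gmin)[1]  # smallest-d tie break
  basin <- i_min
  i <- i_min
  while (i > 1 && elig[i - 1]) { i <- i - 1; basin <- c(i, basin) }
  i <- i_min
  while (i < nrow(pr) && elig[i + 1]) { i <- i + 1; basin <- c(basin, i) }
  dd <- pmf$bin_width
  val <- -RT * log(sum(exp(-pr$G[basin] / RT)) * dd / l_ref)
  w <- exp(-pr$G[basin] / RT); w <- w / sum(w)
  sems <- pr$sem[basin]
  sem <- if (all(is.finite(sems))) sqrt(sum((w * sems)^2)) else NA_real_
  structure(list(value = val, sem = sem,
                 basin_range = range(pr$d[basin]),
                 no_basin = FALSE, orientation = pmf$orientation),
            class = "hp_binding")
}

#' @export
print.hp_binding <- function(x, ...) {
  if (x$no_basin) {
    cat(sprintf("<hp_binding> %s: no bound basin\n", x$orientation))
  } else {
    cat(sprintf("<hp_binding> %s: DG_bind = %.2f +/- %.2f kJ/mol (basin %.2f-%.2f nm)\n",
                x$orientation, x$value, x$sem,
                x$basin_range[1], x$basin_range[2]))
  }
  invisible(x)
}

#' Construct a binding free energy from printed values
#'
#' Wraps externally reported (e.g. tabulated) binding free energies in
#' the container used by [ddg()], for bookkeeping against published
#' per-orientation values.
#'
#' @param value kJ/mol
#' @param sem kJ/mol
#' @param orientation label
#' @export
binding_value <- function(value, sem = 0, orientation = "") {
  structure(list(value = value, sem = sem,
                 basin_range = c(NA_real_, NA_real_),
                 no_basin = is.na(value), orientation = orientation),
            class = "hp_binding")
}

#' Difference of two binding free energies
#'
#' `ddG = b - a` with the standard errors combined in quadrature. In the
#' orientation comparison `a` is the native state; in the fragment
#' comparison `a` is fragment A.
#'
#' @param a,b `hp_binding` objects (both defined)
#' @param label comparison label
#' @return object of class `hp_ddg` with `value`, `sem`, `label`
#' @export
ddg <- function(a, b, label = NULL) {
  if (isTRUE(a$no_basin) || isTRUE(b$no_basin))
    stop("ddg undefined: one input has no bound basin")
  structure(list(value = b$value - a$value,
                 sem = sqrt(a$sem^2 + b$sem^2),
                 label = label %||%
                   paste0(a$orientation, " -> ", b$orientation)),
            class = "hp_ddg")
}

#' @export
print.hp_ddg <- function(x, ...) {
  cat(sprintf("<hp_ddg> %s: %.2f +/- %.2f kJ/mol\n", x$label, x$value, x$sem))
  invisible(x)
}

#' Boltzmann population fold-change for a stabilization
#'
#' `exp(|ddG| / RT)`: the factor by which the bound population grows for
#' a stabilization of magnitude `|ddG|` at temperature T.
#'
#' @param ddg_value kJ/mol (sign ignored)
#' @param temperature_K temperature, K (> 0)
#' @export
population_ratio <- function(ddg_value, temperature_K = DEFAULT_TEMPERATURE_K) {
  stopifnot(temperature_K > 0)
  exp(abs(ddg_value) / (GAS_CONSTANT_KJ * temperature_K))
}

#' Block-averaged standard error of the mean
#'
#' Splits a (possibly autocorrelated) series into `n_blocks` contiguous
#' blocks and reports the standard deviation of the block means divided
#' by `sqrt(n_blocks)`.
#'
#' @param series numeric vector, length >= 2 * n_blocks
#' @param n_blocks number of blocks (default 5)
#' @export
block_sem <- function(series, n_blocks = 5) {
  n <- length(series)
  if (n < 2 * n_blocks)
    stop("series too short for ", n_blocks, " blocks")
  size <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b)
    mean(series[seq((b - 1) * size + 1, b * size)]), numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}

#' Sliding-window convergence scan of the binding free energy
#'
#' Recomputes `DeltaG_bind` on sliding slices of the window time series
#' (the same frame range in every window) to judge stationarity of the
#' estimate.
#'
#' @param samples list of `hp_window_samples`
#' @param window_length slice length in frames
#' @param step slide step in frames (default half the slice)
#' @param ... passed to [wham_pmf()] / [delta_g_bind()] (`bin_width`,
#'   `reference_range`, `l_ref`, ...)
#' @return data.frame with `start`, `end` (frame indices) and `dG`
#' @export
convergence_scan <- function(samples, window_length,
                             step = max(1L, floor(window_length / 2)),
                             ...) {
  n <- min(vapply(samples, function(s) nrow(s$series), integer(1)))
  stopifnot(window_length <= n)
  starts <- seq(1L, n - window_length + 1L, by = step)
  args <- list(...)
  wham_args <- args[names(args) %in%
                    c("bin_width", "tol", "max_iter", "reference_range")]
  bind_args <- args[names(args) %in%
                    c("temperature_K", "l_ref", "threshold", "d_cap")]
  dG <- vapply(starts, function(s0) {
    sl <- lapply(samples, function(s) {
      s$series <- s$series[seq(s0, s0 + window_length - 1L), , drop = FALSE]
      s
    })
    pmf <- do.call(wham_pmf, c(list(samples = sl, n_blocks = 0), wham_args))
    do.call(delta_g_bind, c(list(pmf = pmf), bind_args))$value
  }, numeric(1))
  data.frame(start = starts, end = starts + window_length - 1L, dG = dG)
}

#' Assemble a 2D packing-angle landscape from per-orientation PMFs
#'
#' For each (theta1, theta2) restraint target, the plotted value is the
#' minimum over d of that geometry's distance-dependent PMF. All
#' profiles must share the same plateau reference range (one global
#' reference); grid cells without a profile are masked, never
#' interpolated.
#'
#' @param profiles list of `hp_pmf`, each carrying its `angle_targets`
#' @return object of class `hp_pmf2d`: `theta1`, `theta2` grids, matrix
#'   `G` (kJ/mol), logical matrix `sampled`
#' @export
assemble_pmf2d <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  refs <- unique(lapply(profiles, `[[`, "reference_range"))
  if (length(refs) != 1L)
    stop("inconsistent referencing: profiles use different plateau ranges")
  tgt <- t(vapply(profiles, `[[`, numeric(2), "angle_targets"))
  th1 <- sort(unique(tgt[, 1])); th2 <- sort(unique(tgt[, 2]))
  G <- matrix(NA_real_, length(th1), length(th2),
              dimnames = list(th1, th2))
  sampled <- matrix(FALSE, length(th1), length(th2))
  for (i in seq_along(profiles)) {
    r <- match(tgt[i, 1], th1); c <- match(tgt[i, 2], th2)
    G[r, c] <- min(profiles[[i]]$profile$G)
    sampled[r, c] <- TRUE
  }
  structure(list(theta1 = th1, theta2 = th2, G = G, sampled = sampled),
            class = "hp_pmf2d")
}

#' Location of the global minimum of a 2D landscape
#' @param pmf2d an `hp_pmf2d`
#' @return named vector c(theta1, theta2)
#' @export
pmf2d_argmin <- function(pmf2d) {
  idx <- which(pmf2d$G == min(pmf2d$G, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(theta1 = pmf2d$theta1[idx[1]], theta2 = pmf2d$theta2[idx[2]])
}
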