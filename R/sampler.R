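#' Umbrella-sampling walkers with equilibrium bias exchange
#'
#' Desk-scale surrogate for restrained molecular dynamics: Metropolis
#' walkers on an [hp_landscape][new_landscape] over (d, theta1, theta2),
#' harmonically biased to an umbrella ladder in d and to target rotation
#' angles, with optional replica-exchange-style swapping of adjacent
#' umbrella biases. Exchange leaves every window's target density
#' invariant; it only accelerates mixing.
#'
#' @name sampler
NULL

#' Harmonic angle bias
#'
#' @param targets length-2 vector of target angles (theta1, theta2), degrees
#' @param k stiffness, kJ/mol/deg^2; the default keeps sampled angles
#'   within about +/-10 degrees of target at 300 K
#' @export
new_angle_bias <- function(targets = c(0, 0), k = 0.1) {
  stopifnot(length(targets) == 2L, k >= 0)
  list(targets = as.numeric(targets), k = k)
}

bias_energy_d <- function(window, d) window$k / 2 * (d - window$d0)^2

biased_energy <- function(spec, window, angle_bias, d, th1, th2) {
  eval_landscape(spec, d, th1, th2) +
    bias_energy_d(window, d) +
    angle_bias$k / 2 * ((th1 - angle_bias$targets[1])^2 +
                        (th2 - angle_bias$targets[2])^2)
}

#' Construct a WindowSamples container
#' @param window `hp_window`
#' @param angle_bias angle restraint (see [new_angle_bias()])
#' @param series data.frame of per-frame observables
#' @param stride recording stride
#' @param seed RNG seed used
#' @keywords internal
new_window_samples <- function(window, angle_bias, series, stride, seed) {
  structure(list(window = window, angle_bias = angle_bias,
                 series = series, stride = stride, seed = seed),
            class = "hp_window_samples")
}

#' @export
print.hp_window_samples <- function(x, ...) {
  cat(sprintf("<hp_window_samples> d0 = %.3f nm, k = %g, %d frames (seed %d)\n",
              x$window$d0, x$window$k, nrow(x$series), x$seed))
  invisible(x)
}

# Core vectorised Metropolis chain over a set of windows moving in
# lockstep. Returns per-window series plus the exchange log. States are
# swapped between adjacent windows (equivalent to swapping biases) under
# the Metropolis rule on bias energies only.
mh_campaign <- function(spec, schedule, angle_bias, nsteps, seed,
                        exchange_interval = Inf, stride = 1L,
                        d_init = NULL) {
  W <- length(schedule)
  set.seed(as.integer(seed))
  d0 <- window_centers(schedule)
  kk <- vapply(schedule, `[[`, numeric(1), "k")
  RT <- spec$RT
  d <- if (is.null(d_init)) d0 else rep_len(d_init, W)
  th1 <- rep(angle_bias$targets[1], W)
  th2 <- rep(angle_bias$targets[2], W)
  sd_d <- pmin(0.03, 0.6 * sqrt(RT / kk))
  sd_t <- min(4, 0.6 * sqrt(RT / max(angle_bias$k, 1e-6)))
  e_cur <- mapply(function(i) biased_energy(spec, schedule[[i]], angle_bias,
                                            d[i], th1[i], th2[i]),
                  seq_len(W))
  keep <- seq(stride, nsteps, by = stride)
  out_d <- matrix(NA_real_, length(keep), W)
  out_t1 <- out_t2 <- out_d
  n_pairs <- max(W - 1L, 0L)
  ex_attempts <- ex_accepts <- integer(n_pairs)
  do_exchange <- is.finite(exchange_interval) && W >= 2L
  if (do_exchange) stopifnot(exchange_interval >= 1)
  row <- 0L
  for (step in seq_len(nsteps)) {
    dp <- d + stats::rnorm(W, 0, sd_d)
    t1p <- th1 + stats::rnorm(W, 0, sd_t)
    t2p <- th2 + stats::rnorm(W, 0, sd_t)
    ok <- dp > 0.05
    e_prop <- rep(Inf, W)
    if (any(ok)) {
      e_prop[ok] <- eval_landscape(spec, dp[ok], t1p[ok], t2p[ok]) +
        kk[ok] / 2 * (dp[ok] - d0[ok])^2 +
        angle_bias$k / 2 * ((t1p[ok] - angle_bias$targets[1])^2 +
                            (t2p[ok] - angle_bias$targets[2])^2)
    }
    if (any(!is.finite(e_prop) & ok))
      stop("sampler divergence: non-finite energy at d = ",
           paste(signif(dp[!is.finite(e_prop) & ok], 4), collapse = ", "))
    acc <- log(stats::runif(W)) < (e_cur - e_prop) / RT
    d[acc] <- dp[acc]; th1[acc] <- t1p[acc]; th2[acc] <- t2p[acc]
    e_cur[acc] <- e_prop[acc]
    if (do_exchange && step %% exchange_interval == 0) {
      for (parity in c(1L, 0L)) {
        idx <- seq_len(n_pairs)
        idx <- idx[idx %% 2L == parity]
        for (i in idx) {
          j <- i + 1L
          # bias-energy difference for swapping states between windows i, j
          delta <- (bias_energy_d(schedule[[i]], d[j]) +
                    bias_energy_d(schedule[[j]], d[i]) -
                    bias_energy_d(schedule[[i]], d[i]) -
                    bias_energy_d(schedule[[j]], d[j])) / RT
          ex_attempts[i] <- ex_attempts[i] + 1L
          if (log(stats::runif(1)) < -delta) {
            ex_accepts[i] <- ex_accepts[i] + 1L
            tmp <- d[i]; d[i] <- d[j]; d[j] <- tmp
            tmp <- th1[i]; th1[i] <- th1[j]; th1[j] <- tmp
            tmp <- th2[i]; th2[i] <- th2[j]; th2[j] <- tmp
            e_cur[c(i, j)] <- mapply(function(w) biased_energy(
              spec, schedule[[w]], angle_bias, d[w], th1[w], th2[w]), c(i, j))
          }
        }
      }
    }
    if (step %% stride == 0L) {
      row <- row + 1L
      out_d[row, ] <- d; out_t1[row, ] <- th1; out_t2[row, ] <- th2
    }
  }
  samples <- lapply(seq_len(W), function(i) {
    obs <- draw_observables(spec, out_d[, i], out_t1[, i], out_t2[, i])
    series <- cbind(data.frame(step = keep, d_nm = out_d[, i],
                               theta1_deg = out_t1[, i],
                               theta2_deg = out_t2[, i]), obs)
    new_window_samples(schedule[[i]], angle_bias, series, stride,
                       as.integer(seed))
  })
  exchange <- data.frame(pair = seq_len(n_pairs),
                         attempts = ex_attempts, acceptances = ex_accepts)
  list(samples = samples, exchange = exchange,
       exchange_interval = exchange_interval)
}

#' Sample one umbrella window by Metropolis dynamics
#'
#' Draws from the stationary density proportional to
#' `exp(-(G + k/2 (d - d0)^2 + angle biases) / RT)`. Reproducible for a
#' fixed seed; two different seeds give different series.
#'
#' @param spec `hp_landscape`
#' @param window `hp_window`
#' @param angle_bias see [new_angle_bias()]
#' @param nsteps number of Metropolis steps (> 0)
#' @param seed integer RNG seed
#' @param stride record every `stride`-th step
#' @param d_init optional starting displacement (defaults to the window
#'   target)
#' @return an `hp_window_samples`
#' @export
run_window <- function(spec, window, angle_bias = new_angle_bias(),
                       nsteps = 10000, seed = 1, stride = 1L,
                       d_init = NULL) {
  stopifnot(nsteps > 0)
  mh_campaign(spec, list(window), angle_bias, nsteps, seed,
              exchange_interval = Inf, stride = stride,
              d_init = d_init)$samples[[1]]
}

#' Metropolis acceptance for swapping two umbrella biases
#'
#' The swap of biases between walkers at states `d_i`, `d_j` is accepted
#' with probability `min(1, exp(-beta * delta))` where `delta` is the
#' change in total bias energy; only bias energies enter, so the
#' unbiased landscape cancels and each window's target density is left
#' invariant.
#'
#' @param d_i,d_j current displacements of the two walkers, nm
#' @param window_i,window_j their umbrella windows
#' @param RT thermal energy, kJ/mol
#' @return list with `p_accept` (analytic probability) and `swapped`
#'   (logical draw using the session RNG)
#' @export
attempt_exchange <- function(d_i, d_j, window_i, window_j, RT = RT_300K) {
  delta <- (bias_energy_d(window_i, d_j) + bias_energy_d(window_j, d_i) -
            bias_energy_d(window_i, d_i) - bias_energy_d(window_j, d_j)) / RT
  p <- min(1, exp(-delta))
  list(p_accept = p, swapped = stats::runif(1) < p)
}

#' Run an umbrella campaign over a window schedule
#'
#' One walker per window, stepping in lockstep, with nearest-neighbour
#' bias exchange attempted every `exchange_interval` steps (all `W - 1`
#' adjacent pairs per sweep, odd pairs then even pairs). With
#' `exchange_interval = Inf` the campaign reduces to independent
#' [run_window()] calls with per-window seeds `seed + window index - 1`.
#'
#' @param spec `hp_landscape`
#' @param schedule list of `hp_window` (>= 2 for exchange)
#' @param angle_bias see [new_angle_bias()]
#' @param nsteps steps per window
#' @param exchange_interval steps between exchange sweeps (Inf disables)
#' @param seed integer RNG seed
#' @param stride recording stride
#' @return list with `samples` (one `hp_window_samples` per window),
#'   `exchange` (per-pair attempt/acceptance counts), `exchange_interval`
#' @export
run_campaign <- function(spec, schedule, angle_bias = new_angle_bias(),
                         nsteps = 10000, exchange_interval = 100,
                         seed = 1, stride = 1L) {
  stopifnot(nsteps > 0, exchange_interval > 0)
  if (is.finite(exchange_interval) && length(schedule) < 2L)
    stop("exchange requires at least 2 windows")
  if (!is.finite(exchange_interval)) {
    samples <- lapply(seq_along(schedule), function(i)
      run_window(spec, schedule[[i]], angle_bias, nsteps,
                 seed = seed + i - 1L, stride = stride))
    return(list(samples = samples,
                exchange = data.frame(pair = integer(), attempts = integer(),
                                      acceptances = integer()),
                exchange_interval = Inf))
  }
  mh_campaign(spec, schedule, angle_bias, nsteps, seed,
              exchange_interval = exchange_interval, stride = stride)
}
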