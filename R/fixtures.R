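#' Synthetic morphology point clouds
#'
#' Deterministic (seeded) generators for the four actin network archetypes:
#' `"ring"` (a great-circle band of angular width `band_width` on the
#' droplet surface), `"disc"` (a filled oblate slab about the equatorial
#' plane), `"tight_shell"` (a full spherical shell with small radial spread)
#' and `"loose_shell"` (a shell with large radial spread).  Gaussian
#' positional noise of standard deviation `noise_sd` is added to every
#' point.
#'
#' @param kind morphology label.
#' @param n number of points.
#' @param radius sphere radius R (µm).
#' @param band_width angular width of the ring band (radians).
#' @param slab_sd out-of-plane thickness (standard deviation, µm) of the
#'   disc slab.
#' @param shell_sd radial spread of the shell kinds (µm); defaults 0.02
#'   (tight) / 0.25 (loose).
#' @param noise_sd isotropic positional noise (µm).
#' @param seed RNG seed.
#' @return list with `points` (n x 3), `label`, and `spec` (the generating
#'   parameters).
#' @export
gen_morphology_cloud <- function(kind = c("ring", "disc", "tight_shell",
                                          "loose_shell"),
                                 n = 2000, radius = 1, band_width = 0.15,
                                 slab_sd = 0.1, shell_sd = NULL,
                                 noise_sd = 0.01, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n > 0, radius > 0, band_width > 0, noise_sd >= 0)
  set.seed(seed)
  pts <- switch(kind,
    ring = {
      phi <- stats::runif(n, 0, 2 * pi)
      z <- radius * sin(stats::runif(n, -band_width / 2, band_width / 2))
      rho <- sqrt(pmax(radius^2 - z^2, 0))
      cbind(rho * cos(phi), rho * sin(phi), z)
    },
    disc = {
      rho <- radius * sqrt(stats::runif(n))
      phi <- stats::runif(n, 0, 2 * pi)
      cbind(rho * cos(phi), rho * sin(phi), stats::rnorm(n, 0, slab_sd))
    },
    tight_shell = {
      if (is.null(shell_sd)) shell_sd <- 0.02
      d <- matrix(stats::rnorm(3 * n), n, 3)
      d <- d / sqrt(rowSums(d^2))
      d * pmax(radius + stats::rnorm(n, 0, shell_sd), 1e-3)
    },
    loose_shell = {
      if (is.null(shell_sd)) shell_sd <- 0.25
      d <- matrix(stats::rnorm(3 * n), n, 3)
      d <- d / sqrt(rowSums(d^2))
      d * pmax(radius + stats::rnorm(n, 0, shell_sd), 1e-3)
    })
  pts <- pts + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  list(points = pts, label = kind,
       spec = list(kind = kind, n = n, radius = radius,
                   band_width = band_width, slab_sd = slab_sd,
                   shell_sd = shell_sd, noise_sd = noise_sd, seed = seed))
}

#' Labeled feature sets for the classification pipeline
#'
#' Generates `n_per_class` morphology clouds per archetype (with slight
#' parameter jitter between replicates) and summarizes each cloud by the
#' same descriptors the simulation analysis produces: surface fraction,
#' gyration spans and alignment angle.
#'
#' @param n_per_class clouds per morphology.
#' @param n_points points per cloud.
#' @param radius droplet radius (µm).
#' @param seed RNG seed.
#' @return data frame with feature columns plus the ground-truth `label`.
#' @export
fixture_feature_set <- function(n_per_class = 10, n_points = 1500,
                                radius = 1, seed = 1) {
  kinds <- c("ring", "disc", "tight_shell", "loose_shell")
  set.seed(seed)
  sub_seeds <- sample.int(1e6, n_per_class * length(kinds))
  rows <- list()
  i <- 0
  for (k in kinds) for (r in seq_len(n_per_class)) {
    i <- i + 1
    cl <- gen_morphology_cloud(k, n = n_points, radius = radius,
                               band_width = stats::runif(1, 0.12, 0.2),
                               slab_sd = stats::runif(1, 0.08, 0.14),
                               noise_sd = 0.01, seed = sub_seeds[i])
    sp <- gyration_spans(cl$points)
    rows[[i]] <- data.frame(
      label = k,
      surface_fraction = surface_fraction(cl$points, rep(radius, 3)),
      span_a = sp[1], span_b = sp[2], span_c = sp[3],
      alignment_angle = alignment_angle(sp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic power-law dataset
#'
#' `y = a * x^b * exp(N(0, noise_sd))` on a grid of distinct x values with
#' replication, plus per-row aspect ratios of which a configurable fraction
#' falls inside the standard `[1.5, 2]` fitting window.
#'
#' @param a,b power-law parameters.
#' @param noise_sd lognormal noise scale (0 = exact).
#' @param n total rows (>= 10).
#' @param x_range range of x values (µm).
#' @param n_x number of distinct x values.
#' @param ar_in_fraction fraction of rows with aspect ratio inside the
#'   window.
#' @param seed RNG seed.
#' @return data frame with columns `x`, `y`, `ar`.
#' @export
gen_powerlaw_dataset <- function(a = 3, b = 1.5, noise_sd = 0.1, n = 200,
                                 x_range = c(0.5, 4), n_x = 8,
                                 ar_in_fraction = 1, seed = 1) {
  stopifnot(n >= 10, a > 0)
  set.seed(seed)
  xs <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_x))
  x <- sample(xs, n, replace = TRUE)
  y <- a * x^b * exp(stats::rnorm(n, 0, noise_sd))
  inside <- stats::runif(n) < ar_in_fraction
  ar <- ifelse(inside, stats::runif(n, 1.5, 2.0), stats::runif(n, 1.0, 1.4))
  data.frame(x = x, y = y, ar = ar)
}

#' Synthetic radial intensity profile of an actin ring
#'
#' A top-hat ring of width `ring_width` centered at `center` is convolved
#' analytically with a Gaussian point-spread function of standard deviation
#' `psf_sigma` (difference of normal CDFs) and Gaussian noise at the given
#' signal-to-noise ratio is added.
#'
#' @param ring_width true ring width (µm); 0 gives a line source whose
#'   profile is the PSF itself.
#' @param psf_sigma PSF standard deviation (µm).
#' @param snr peak signal-to-noise ratio; `Inf` for noiseless.
#' @param center ring center radius (µm).
#' @param r_max,dr profile extent and sampling (µm).
#' @param seed RNG seed.
#' @return data frame `r`, `intensity` with attribute `"truth"`.
#' @export
gen_intensity_profile <- function(ring_width = 0.2, psf_sigma = 0.1,
                                  snr = Inf, center = 1, r_max = 2,
                                  dr = 0.005, seed = 1) {
  stopifnot(ring_width >= 0, psf_sigma > 0)
  set.seed(seed)
  r <- seq(0, r_max, by = dr)
  I <- if (ring_width == 0) {
    stats::dnorm(r, center, psf_sigma) / stats::dnorm(0, 0, psf_sigma)
  } else {
    stats::pnorm(r, center - ring_width / 2, psf_sigma) -
      stats::pnorm(r, center + ring_width / 2, psf_sigma)
  }
  if (is.finite(snr)) I <- I + stats::rnorm(length(r), 0, max(I) / snr)
  out <- data.frame(r = r, intensity = I)
  attr(out, "truth") <- list(ring_width = ring_width, psf_sigma = psf_sigma,
                             psf_fwhm = 2 * sqrt(2 * log(2)) * psf_sigma,
                             center = center, snr = snr)
  out
}

#' Exact two-state telegraph (capping) process
#'
#' Gillespie simulation of the capped/uncapped switch with rates `k_cap`
#' (uncapped -> capped) and `k_uncap` (capped -> uncapped): exponential
#' dwell times, discretized onto a regular grid.  Serves as the independent
#' oracle for the engine's per-step capping scheme.
#'
#' @param k_cap,k_uncap switching rates (1/s).
#' @param duration total time (s).
#' @param dt sampling interval (s).
#' @param seed RNG seed.
#' @param start initial state, `"uncapped"` or `"capped"`.
#' @return data frame `time`, `capped` (logical); attribute `"dwells"` holds
#'   the exact sojourn times by state.
#' @export
gen_two_state_series <- function(k_cap, k_uncap, duration = 1000, dt = 0.1,
                                 seed = 1, start = "uncapped") {
  stopifnot(k_cap >= 0, k_uncap >= 0, duration > 0, dt > 0)
  set.seed(seed)
  t <- 0
  capped <- identical(start, "capped")
  switch_times <- numeric(0)
  dwell_capped <- numeric(0); dwell_uncapped <- numeric(0)
  while (t < duration) {
    k <- if (capped) k_uncap else k_cap
    if (k == 0) break
    tau <- stats::rexp(1, k)
    if (capped) dwell_capped <- c(dwell_capped, tau)
    else dwell_uncapped <- c(dwell_uncapped, tau)
    t <- t + tau
    if (t < duration) switch_times <- c(switch_times, t)
    capped <- !capped
  }
  grid <- seq(0, duration, by = dt)
  state0 <- identical(start, "capped")
  nsw <- findInterval(grid, switch_times)
  capped_series <- xor(state0, nsw %% 2 == 1)
  out <- data.frame(time = grid, capped = capped_series)
  attr(out, "dwells") <- list(capped = dwell_capped,
                              uncapped = dwell_uncapped)
  out
}
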