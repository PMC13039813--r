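#' Gyration-tensor spans of a point cloud
#'
#' The gyration tensor is the second-moment matrix of the centered positions
#' (normalized by the number of points).  Its eigenvalues
#' `lambda_1 >= lambda_2 >= lambda_3` define ellipsoidal spans
#' `sqrt(5 * lambda_i)` (the semi-axis relation of a uniform solid
#' ellipsoid), which approximate the actin network as an ellipsoid with
#' span a >= span b >= span c.
#'
#' @param points n x 3 matrix (µm); n >= 1.
#' @return named numeric `c(a, b, c)` in µm, sorted decreasing.
#' @export
gyration_spans <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) < 1) stop("need at least one point")
  cen <- scale(points, scale = FALSE)
  S <- crossprod(cen) / nrow(points)
  ev <- sort(pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  stats::setNames(sqrt(5 * ev), c("a", "b", "c"))
}

#' Alignment angle of an actin network
#'
#' `theta = atan(span_c / span_a)` in degrees: 0 for a perfectly flat
#' (planar) network such as a ring, 45 for a perfectly spherical (isotropic)
#' one such as a shell.  Scale-invariant.
#'
#' @param spans numeric length-3 spans (any order) or an n x 3 point matrix,
#'   in which case spans are computed first.
#' @return angle in degrees, in `[0, 45]`.
#' @export
alignment_angle <- function(spans) {
  if (is.matrix(spans) && ncol(spans) == 3 && nrow(spans) > 3)
    spans <- gyration_spans(spans)
  s <- sort(spans, decreasing = TRUE)
  if (s[1] <= 0) stop("all spans zero: alignment angle undefined")
  unname(atan(s[3] / s[1]) * 180 / pi)
}

#' Effective spherical diameter of an ellipsoidal droplet
#'
#' `D = (a * b^2)^(1/3)` with `a` the major and `b` the minor axis length,
#' the diameter of the sphere matching a prolate droplet's volume.
#' @param a major axis length (µm).
#' @param b minor axis length (µm).
#' @return effective diameter (µm).
#' @export
effective_diameter <- function(a, b) {
  stopifnot(all(a >= b), all(b > 0))
  (a * b^2)^(1 / 3)
}

#' Molar concentration of N molecules in a spherical droplet
#' @param count number of molecules.
#' @param radius droplet radius (µm).
#' @return concentration in µM.
#' @export
concentration_uM <- function(count, radius) {
  stopifnot(count >= 0, radius > 0)
  volume_um3 <- 4 / 3 * pi * radius^3
  count / (6.02214076e23 * volume_um3 * 1e-15) * 1e6
}

# ----------------------------------------------------------------- icosphere

#' Icosphere triangulation of the unit sphere
#'
#' Starts from a regular icosahedron and subdivides each face `subdivision`
#' times (4-way), projecting new vertices back to the unit sphere; level 3
#' gives 1280 triangles.
#'
#' @param subdivision non-negative integer.
#' @return list with `vertices` (V x 3, unit norm) and `faces` (F x 3 vertex
#'   indices).
#' @export
icosphere <- function(subdivision = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision)) {
    mid_cache <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      assign(key, idx, envir = mid_cache)
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    r <- 0L
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[r + 1, ] <- c(a, ab, ca); nf[r + 2, ] <- c(b, bc, ab)
      nf[r + 3, ] <- c(c3, ca, bc); nf[r + 4, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, faces = f)
}

# distances from points to the ellipsoid surface (exact where it matters):
# the cheap radial distance is used as an upper bound and points that cannot
# be within `threshold` are rejected by an aspect-ratio-safe margin.
.surface_distance_within <- function(points, semi_axes, threshold) {
  sc <- sqrt(rowSums((points / matrix(semi_axes, nrow(points), 3,
                                      byrow = TRUE))^2))
  rad <- sqrt(rowSums(points^2))
  ub <- rad * abs(1 / sc - 1)                      # radial distance
  ar <- max(semi_axes) / min(semi_axes)
  within <- ub <= threshold
  borderline <- which(!within & ub <= threshold * ar * 1.5)
  if (length(borderline)) {
    b <- boundary(semi_axes)
    for (i in borderline) {
      pr <- surface_projection(points[i, ], b)
      within[i] <- sqrt(sum((points[i, ] - pr$surface_point)^2)) <= threshold
    }
  }
  within
}

#' Actin-covered surface fraction
#'
#' The droplet surface is discretized as an icosphere whose unit vertices
#' are stretched onto the current ellipsoid.  Every point of the
#' monomer-level filament cloud lying within `threshold` of the surface is
#' assigned to its nearest triangle centroid; the returned value is the
#' fraction of triangles that received at least one point.
#'
#' @param points n x 3 matrix of filament sample points (µm); use
#'   [frame_points()] or [discretize()] to build it.
#' @param semi_axes droplet semi-axes, or a [boundary()].
#' @param subdivision icosphere subdivision level (default 3, 1280
#'   triangles).
#' @param threshold capture distance from the surface (µm).
#' @return fraction in `[0, 1]`.
#' @export
surface_fraction <- function(points, semi_axes, subdivision = 3,
                             threshold = 0.1) {
  if (inherits(semi_axes, "boundary")) semi_axes <- semi_axes$semi_axes
  ico <- icosphere(subdivision)
  if (nrow(ico$faces) == 0) stop("icosphere has no triangles")
  if (is.null(points) || nrow(points) == 0) return(0)
  keep <- .surface_distance_within(points, semi_axes, threshold)
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(0)
  vdef <- ico$vertices * matrix(semi_axes, nrow(ico$vertices), 3, byrow = TRUE)
  cent <- (vdef[ico$faces[, 1], ] + vdef[ico$faces[, 2], ] +
           vdef[ico$faces[, 3], ]) / 3
  occupied <- logical(nrow(cent))
  chunk <- 2000L
  c2 <- rowSums(cent^2)
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), c2, "+") - 2 * block %*% t(cent)
    occupied[unique(max.col(-d2))] <- TRUE
  }
  mean(occupied)
}

# ------------------------------------------------------- length distribution

#' Smoothed filament length distributions
#'
#' Lengths are histogrammed into 130 bins of width 0.05 µm on [0, 6.5] µm.
#' The distribution is smoothed over time by pooling the samples of the
#' +/- 5 neighbouring frames (an 11-frame window, truncated at the series
#' ends), and a Gaussian kernel density estimate of the pooled sample gives
#' the probability density at each frame.
#'
#' @param length_series list of numeric vectors, one per frame (µm).
#' @param window half-width of the temporal pooling window in frames.
#' @param bw KDE bandwidth rule passed to [stats::density()]; the default
#'   `"nrd"` is Scott's rule.
#' @return list of class `"length_pdf"`, one element per frame with `breaks`,
#'   `counts`, `density` (histogram) and `kde` (data frame `x`, `y`), or
#'   `NULL` with attribute `"empty"` for frames whose window has no lengths.
#' @export
length_pdf <- function(length_series, window = 5, bw = "nrd") {
  breaks <- seq(0, 6.5, by = 0.05)
  nfr <- length(length_series)
  out <- lapply(seq_len(nfr), function(f) {
    lo <- max(1, f - window); hi <- min(nfr, f + window)
    pooled <- unlist(length_series[lo:hi])
    if (length(pooled) == 0)
      return(structure(list(breaks = breaks, counts = NULL, density = NULL,
                            kde = NULL), empty = TRUE))
    h <- graphics::hist(pmin(pooled, 6.5 - 1e-9), breaks = breaks,
                        right = FALSE, plot = FALSE)
    kde <- if (length(pooled) >= 2 && stats::sd(pooled) > 0) {
      d <- stats::density(pooled, bw = bw)
      data.frame(x = d$x, y = d$y)
    } else {
      data.frame(x = pooled[1], y = Inf)
    }
    list(breaks = breaks, counts = h$counts, density = h$density, kde = kde)
  })
  class(out) <- "length_pdf"
  out
}

# ------------------------------------------------------------ ring thickness

#' Ring thickness from a radial intensity profile
#'
#' Fits a Gaussian (amplitude, center, sigma, baseline) to the profile by
#' least squares, converts to full width at half maximum
#' (`FWHM = 2*sqrt(2*log(2)) * sigma`), and subtracts the diffraction limit,
#' flooring at zero (sub-resolution rings are flagged).
#'
#' @param profile data frame with columns `r` (µm) and `intensity`.
#' @param diffraction_limit optical resolution to subtract (µm).
#' @return list with `thickness` (µm), `fwhm`, `sigma`, `center`,
#'   `converged`, and `sub_resolution` flags.
#' @export
ring_thickness <- function(profile, diffraction_limit = 0.25) {
  stopifnot(all(c("r", "intensity") %in% names(profile)))
  r <- profile$r; I <- profile$intensity
  i0 <- which.max(I)
  start <- list(A = max(I) - min(I), mu = r[i0],
                sigma = max(diff(range(r)) / 10, 1e-3), b = min(I))
  fit <- tryCatch({
    if (requireNamespace("minpack.lm", quietly = TRUE))
      minpack.lm::nlsLM(intensity ~ A * exp(-(r - mu)^2 / (2 * sigma^2)) + b,
                        data = profile, start = start)
    else
      stats::nls(intensity ~ A * exp(-(r - mu)^2 / (2 * sigma^2)) + b,
                 data = profile, start = start,
                 control = stats::nls.control(warnOnly = TRUE))
  }, error = function(e) NULL)
  if (is.null(fit))
    return(list(thickness = NA_real_, fwhm = NA_real_, sigma = NA_real_,
                center = NA_real_, converged = FALSE, sub_resolution = NA))
  cf <- stats::coef(fit)
  sig <- abs(cf[["sigma"]])
  fwhm <- 2 * sqrt(2 * log(2)) * sig
  list(thickness = max(fwhm - diffraction_limit, 0), fwhm = fwhm,
       sigma = sig, center = cf[["mu"]], converged = TRUE,
       sub_resolution = fwhm <= diffraction_limit)
}

# -------------------------------------------------------------- power laws

#' Fit a power law y = a * x^b
#'
#' Rows are first filtered to final aspect ratios inside `ar_window`
#' (when `ar` is supplied); x values left with fewer than `min_per_x`
#' surviving rows are excluded; then ordinary least squares on
#' `log(y) ~ log(x)` gives `a = exp(intercept)`, `b = slope` and the R² on
#' the log scale.
#'
#' @param x positive predictor (e.g. initial droplet diameter, µm).
#' @param y positive response (e.g. filament count or ring thickness).
#' @param ar optional per-row final aspect ratios used for filtering.
#' @param ar_window inclusive aspect-ratio window (default `c(1.5, 2)`).
#' @param min_per_x minimum surviving rows per distinct x value.
#' @return object of class `"power_law_fit"`: list with `a`, `b`,
#'   `r_squared`, `n`, and a `filter` record.
#' @export
fit_power_law <- function(x, y, ar = NULL, ar_window = c(1.5, 2),
                          min_per_x = 10) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  keep <- rep(TRUE, length(x))
  if (!is.null(ar)) keep <- ar >= ar_window[1] & ar <= ar_window[2]
  x1 <- x[keep]; y1 <- y[keep]
  ux <- unique(x1)
  cnt <- vapply(ux, function(v) sum(x1 == v), numeric(1))
  good_x <- ux[cnt >= min_per_x]
  keep2 <- x1 %in% good_x
  x2 <- x1[keep2]; y2 <- y1[keep2]
  if (length(unique(x2)) < 3 || length(x2) < 3)
    stop(sprintf("power-law fit refused: only %d points (%d distinct x) survive filtering",
                 length(x2), length(unique(x2))))
  fit <- stats::lm(log(y2) ~ log(x2))
  # noiseless inputs give an exact fit; the summary warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  ci <- tryCatch(suppressWarnings(unname(stats::confint(fit)[2, ])),
                 error = function(e) c(NA, NA))
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n = length(x2),
                 b_ci = ci,
                 filter = list(ar_window = ar_window, min_per_x = min_per_x,
                               dropped_ar = sum(!keep),
                               dropped_sparse_x = sum(!keep2))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law y = a x^b: a = %.4g, b = %.4g (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

# --------------------------------------------------------- trajectory-level

#' Crosslinker bound-state fractions of a frame
#'
#' Tetramer mode returns `f0 ... f4` (fraction of linkers bound to 0-4
#' filaments); monomer mode returns the six fractions `0F, 0B, 1F, 1B, 2F,
#' 2B`.  The fractions sum to 1.
#'
#' @param frame engine state (an element of `traj$frames`).
#' @param mode `"tetramer"` or `"monomer"`.
#' @return named numeric vector of fractions.
#' @export
state_fractions <- function(frame, mode = c("tetramer", "monomer")) {
  mode <- match.arg(mode)
  n <- nrow(frame$linker_pos)
  if (n == 0) stop("frame has no linkers")
  al <- frame$actin_links
  nbound <- tabulate(al[, 1], nbins = n)
  if (mode == "tetramer") {
    f <- vapply(0:4, function(k) sum(nbound == k), numeric(1)) / n
    return(stats::setNames(f, paste0("f", 0:4)))
  }
  pl <- frame$partner_links
  npart <- tabulate(c(pl[, 1], pl[, 2]), nbins = n)
  lab <- paste0(npart, ifelse(nbound > 0, "B", "F"))
  lv <- as.vector(outer(0:2, c("F", "B"), paste0))
  stats::setNames(vapply(lv, function(s) mean(lab == s), numeric(1)), lv)
}

#' Per-snapshot feature and shape table of a trajectory
#'
#' For each of the last `n_last` snapshots computes the classification
#' features (actin-covered surface fraction and crosslinker state fractions)
#' together with gyration spans, alignment angle and droplet aspect ratio.
#'
#' @param traj a `"droplet_trajectory"`.
#' @param n_last number of trailing snapshots to summarize (default 5, as
#'   used for clustering input; use 30 for state-fraction reporting).
#' @param spacing filament resampling interval for the surface fraction and
#'   gyration tensor (µm).
#' @param subdivision,threshold see [surface_fraction()].
#' @return data frame, one row per snapshot.
#' @export
trajectory_features <- function(traj, n_last = 5, spacing = 0.01,
                                subdivision = 3, threshold = 0.1) {
  nfr <- length(traj$frames)
  idx <- seq(max(1, nfr - n_last + 1), nfr)
  mode <- traj$config$linker_mode
  rows <- lapply(idx, function(i) {
    fr <- traj$frames[[i]]
    pts <- frame_points(traj, i, spacing = spacing)
    sf <- surface_fraction(pts, fr$semi_axes, subdivision, threshold)
    sp <- if (!is.null(pts) && nrow(pts) >= 2) gyration_spans(pts)
          else c(a = 0, b = 0, c = 0)
    ang <- if (sp[1] > 0) alignment_angle(sp) else NA_real_
    base <- data.frame(time = traj$times[i], surface_fraction = sf,
                       span_a = sp[1], span_b = sp[2], span_c = sp[3],
                       alignment_angle = ang,
                       aspect_ratio = aspect_ratio(fr$semi_axes))
    if (mode %in% c("tetramer", "monomer") && nrow(fr$linker_pos) > 0) {
      fs <- state_fractions(fr, mode)
      base <- cbind(base, as.data.frame(t(fs)))
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-row shape summary of a trajectory frame
#' @param traj a `"droplet_trajectory"`.
#' @param frame frame index (default: last).
#' @param spacing resampling interval (µm).
#' @return data frame row with spans, alignment angle, aspect ratio and
#'   surface fraction.
#' @export
shape_summary <- function(traj, frame = length(traj$frames), spacing = 0.01) {
  sub <- structure(list(times = traj$times[seq_len(frame)],
                        frames = traj$frames[seq_len(frame)],
                        config = traj$config),
                   class = "droplet_trajectory")
  trajectory_features(sub, n_last = 1, spacing = spacing)[1, , drop = FALSE]
}
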