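test_that("gyration spans follow closed-form second moments", {
  # two points at +-1 on x: single-axis variance 1 -> spans (sqrt 5, 0, 0)
  sp <- gyration_spans(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(unname(sp), c(sqrt(5), 0, 0), tolerance = 1e-12)
  # uniform great circle of radius R: lambda = (R^2/2, R^2/2, 0)
  th <- seq(0, 2 * pi, length.out = 4001)[-1]
  circ <- cbind(2 * cos(th), 2 * sin(th), 0)
  spc <- gyration_spans(circ)
  expect_equal(unname(spc), c(sqrt(5 / 2) * 2, sqrt(5 / 2) * 2, 0),
               tolerance = 1e-3)
  # rotation invariance
  set.seed(8)
  pts <- matrix(rnorm(300), 100, 3)
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(gyration_spans(pts %*% qr_r), gyration_spans(pts),
               tolerance = 1e-10)
})

test_that("alignment angle spans [0, 45] and is scale invariant", {
  expect_equal(alignment_angle(c(1, 1, 1)), 45)
  expect_equal(alignment_angle(rbind(c(-3, 0, 0), c(0, 0, 0), c(5, 0, 0),
                                     c(1, 0, 0))), 0)
  expect_equal(alignment_angle(c(2, 1.5, 1)), atan(0.5) * 180 / pi)
  expect_equal(round(alignment_angle(c(2, 1.5, 1)), 3), 26.565)
  set.seed(9)
  for (i in 1:10) {
    s <- sort(runif(3, 0.1, 3), decreasing = TRUE)
    a <- alignment_angle(s)
    expect_gte(a, 0); expect_lte(a, 45)
    expect_equal(alignment_angle(s * 7.3), a, tolerance = 1e-12)
  }
  expect_error(alignment_angle(c(0, 0, 0)), "undefined")
})

test_that("effective diameter and concentration bookkeeping", {
  expect_equal(effective_diameter(1, 1), 1)
  expect_equal(effective_diameter(2, 1), 2^(1 / 3))
  expect_equal(round(effective_diameter(2, 1), 4), 1.2599)
  expect_gt(effective_diameter(2.5, 1), effective_diameter(2, 1))
  expect_gt(effective_diameter(2, 1.2), effective_diameter(2, 1))
  expect_equal(concentration_uM(1000, 1), 0.3964, tolerance = 1e-3)
  expect_equal(round(concentration_uM(1000, 1), 1), 0.4)
  # doubling R at fixed concentration needs 8x the count
  expect_equal(concentration_uM(8000, 2), concentration_uM(1000, 1),
               tolerance = 1e-12)
})

test_that("icosphere subdivision produces the expected triangulation", {
  ico <- icosphere(0)
  expect_equal(nrow(ico$faces), 20)
  ico3 <- icosphere(3)
  expect_equal(nrow(ico3$faces), 1280)
  expect_equal(sqrt(rowSums(ico3$vertices^2)), rep(1, nrow(ico3$vertices)),
               tolerance = 1e-12)
})

test_that("surface fraction saturates for shells and tracks band area for rings", {
  expect_equal(surface_fraction(matrix(0, 0, 3), c(1, 1, 1)), 0)
  # dense uniform shell hugging the surface
  set.seed(13)
  d <- matrix(rnorm(3 * 20000), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  expect_gte(surface_fraction(d, c(1, 1, 1)), 0.99)
  # great-circle band of angular half-width asin(0.05): area fraction = 0.05
  z <- runif(40000, -0.05, 0.05)
  phi <- runif(40000, 0, 2 * pi)
  rho <- sqrt(1 - z^2)
  band <- cbind(rho * cos(phi), rho * sin(phi), z)
  frac <- surface_fraction(band, c(1, 1, 1))
  # nearest-centroid assignment broadens the band by about one centroid
  # spacing (~sqrt(4 pi / 1280) = 0.1), so the occupied fraction lies
  # between the true band area and the band widened by 2 spacings
  expect_gte(frac, 0.05 - 0.01)
  expect_lte(frac, (0.1 + 2 * sqrt(4 * pi / 1280)) / 2)
  # non-decreasing in the threshold distance
  pts <- d[1:5000, ] * 0.92
  f1 <- surface_fraction(pts, c(1, 1, 1), threshold = 0.05)
  f2 <- surface_fraction(pts, c(1, 1, 1), threshold = 0.1)
  f3 <- surface_fraction(pts, c(1, 1, 1), threshold = 0.2)
  expect_lte(f1, f2); expect_lte(f2, f3)
})

test_that("length PDFs are normalized and centred where they should be", {
  lp <- length_pdf(list(rep(2, 500)))
  h <- lp[[1]]
  # all mass in the [2.00, 2.05) bin
  expect_equal(h$counts[which(h$breaks == 2)], 500)
  expect_equal(sum(h$counts), 500)
  # histogram density integrates to one
  expect_equal(sum(h$density * 0.05), 1, tolerance = 1e-9)
  # KDE of a known normal sample recovers the mean
  set.seed(14)
  x <- rnorm(2000, 3, 0.2)
  lp2 <- length_pdf(list(x))
  kde <- lp2[[1]]$kde
  expect_equal(sum(kde$x * kde$y) / sum(kde$y), 3,
               tolerance = 3 * 0.2 / sqrt(2000) / 3 * 3)
  # KDE integrates to ~1
  expect_equal(sum(kde$y) * diff(kde$x[1:2]), 1, tolerance = 1e-2)
  # temporal pooling: middle frame pools neighbours
  series <- c(replicate(5, rnorm(50, 1, 0.05), simplify = FALSE),
              replicate(6, rnorm(50, 5, 0.05), simplify = FALSE))
  lp3 <- length_pdf(series)
  expect_equal(sum(lp3[[1]]$counts), 50 * 6)   # frames 1..6 pooled
  # empty series flagged
  lp4 <- length_pdf(list(numeric(0)))
  expect_true(isTRUE(attr(lp4[[1]], "empty")))
})

test_that("ring thickness recovers widths from Gaussian and convolved profiles", {
  # pure Gaussian sigma = 0.2, limit 0.25: FWHM 0.4710, thickness 0.2210
  prof <- gen_intensity_profile(ring_width = 0, psf_sigma = 0.2, snr = Inf)
  rt <- ring_thickness(prof, diffraction_limit = 0.25)
  expect_true(rt$converged)
  expect_equal(rt$fwhm, 2 * sqrt(2 * log(2)) * 0.2, tolerance = 1e-3)
  expect_equal(round(rt$fwhm, 4), 0.471, tolerance = 1e-2)
  expect_equal(rt$thickness, rt$fwhm - 0.25, tolerance = 1e-6)
  # sub-resolution: floored at zero and flagged
  prof2 <- gen_intensity_profile(ring_width = 0, psf_sigma = 0.05, snr = Inf)
  rt2 <- ring_thickness(prof2, diffraction_limit = 0.25)
  expect_equal(rt2$thickness, 0)
  expect_true(rt2$sub_resolution)
  # known ring width convolved with known PSF: recovered within 10%
  w <- 0.2; psf <- 0.1
  prof3 <- gen_intensity_profile(ring_width = w, psf_sigma = psf, snr = 50,
                                 seed = 4)
  rt3 <- ring_thickness(prof3, diffraction_limit = 0)
  # top-hat (x) gaussian has variance w^2/12 + psf^2; compare via that width
  w_eff <- 2 * sqrt(2 * log(2)) * sqrt(w^2 / 12 + psf^2)
  expect_equal(rt3$fwhm, w_eff, tolerance = 0.1)
})

test_that("power-law fit is exact on clean data and honors the filters", {
  d <- gen_powerlaw_dataset(a = 3, b = 1.5, noise_sd = 0, n = 120, seed = 2)
  fit <- fit_power_law(d$x, d$y, d$ar)
  expect_equal(fit$a, 3, tolerance = 1e-9)
  expect_equal(fit$b, 1.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # rows outside the aspect-ratio window are excluded
  d2 <- d
  d2$ar[d2$x == min(d2$x)] <- 1.1
  fit2 <- fit_power_law(d2$x, d2$y, d2$ar)
  expect_equal(fit2$n, sum(d2$ar >= 1.5))
  # all aspect ratios outside the window: refused
  expect_error(fit_power_law(d$x, d$y, rep(1.1, nrow(d))), "refused")
  # sparse x values (fewer than 10 rows) are dropped
  x3 <- c(rep(1, 20), rep(2, 20), rep(3, 20), rep(4, 3))
  y3 <- 2 * x3^0.8
  fit3 <- fit_power_law(x3, y3, min_per_x = 10)
  expect_equal(fit3$n, 60)
  expect_equal(fit3$filter$dropped_sparse_x, 3)
  # noisy recovery: b within its own 95% CI
  d4 <- gen_powerlaw_dataset(a = 2, b = 1.2, noise_sd = 0.1, n = 200,
                             seed = 6)
  fit4 <- fit_power_law(d4$x, d4$y, d4$ar)
  expect_gte(1.2, fit4$b_ci[1])
  expect_lte(1.2, fit4$b_ci[2])
})

test_that("state fractions sum to one in both linker modes", {
  fr <- list(linker_pos = matrix(0, 10, 3),
             actin_links = cbind(c(1, 1, 2, 3, 3, 3, 3), 1,
                                 seq(0.1, 0.7, by = 0.1)),
             partner_links = cbind(c(4, 5), c(5, 6)))
  ft <- state_fractions(fr, "tetramer")
  expect_equal(sum(ft), 1, tolerance = 1e-12)
  expect_equal(unname(ft["f2"]), 0.1)   # linker 1 has 2 links
  expect_equal(unname(ft["f4"]), 0.1)   # linker 3 has 4 links
  fm <- state_fractions(fr, "monomer")
  expect_equal(sum(fm), 1, tolerance = 1e-12)
  expect_equal(unname(fm["2F"]), 0.1)   # linker 5 has two partners, no actin
})
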