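#' Equipartition mode model for bundle fluctuations in a droplet
#'
#' A circumferential actin bundle of length `L` lying under the surface of a
#' droplet of radius `R` fluctuates thermally.  Writing the radial deviation of
#' the bundle centerline as a cosine series with mode amplitudes `u_m`, the
#' bending energy stored in mode `m` above the baseline circular state is
#' `(k_b/2) * f(m) * (L/R^4) * u_m^2` with `f(m) = 2 + m^4` and
#' `k_b = L_p * k_BT` the bundle flexural rigidity.  Equipartition assigns each
#' mode `k_BT/2`, which fixes the root-mean-square amplitude.
#'
#' @param R droplet radius (µm).
#' @param L_p bundle persistence length (µm).
#' @param m positive integer mode index.
#' @param k_BT thermal energy (pN·µm); default 0.0042 (room temperature).
#' @param L bundle length (µm); defaults to the droplet circumference `2*pi*R`.
#' @return `mode_model()` returns a validated list of class `"mode_model"`.
#' @examples
#' mm <- mode_model(R = 1, L_p = 18, m = 2)
#' mode_amplitude(mm)
#' @export
mode_model <- function(R, L_p, m = 1L, k_BT = 0.0042, L = 2 * pi * R) {
  stopifnot(R > 0, L_p > 0, k_BT > 0, L > 0, m >= 1, m == as.integer(m))
  structure(list(R = R, L_p = L_p, m = as.integer(m), k_BT = k_BT, L = L),
            class = "mode_model")
}

#' Mode-dependent stiffness factor f(m) = 2 + m^4
#' @param m positive integer mode index (vectorized).
#' @return numeric vector, always >= 3.
#' @export
mode_factor <- function(m) {
  stopifnot(all(m >= 1))
  2 + m^4
}

#' Thermal root-mean-square amplitude of bundle mode m
#'
#' Solves the equipartition identity
#' `k_BT/2 = (k_b/2) * f(m) * (L/R^4) * u_m^2` for `u_m`, with
#' `k_b = L_p * k_BT`.  For a bundle spanning the droplet circumference
#' (`L = 2*pi*R`) this reduces to `u_m = sqrt(R^3 / (2*pi*L_p*f(m)))`, i.e.
#' `u_m` grows as `R^1.5`.
#'
#' @param model a [mode_model()].
#' @return amplitude u_m in µm.
#' @export
mode_amplitude <- function(model) {
  stopifnot(inherits(model, "mode_model"))
  k_b <- model$L_p * model$k_BT
  sqrt(model$k_BT * model$R^4 / (k_b * mode_factor(model$m) * model$L))
}

#' Baseline bending energy of a circumferential bundle
#'
#' Energy of the unperturbed circular bundle, `k_b * L / (2 R^2)`, i.e. the
#' worm-like-chain energy `(k_b/2) * integral(kappa^2 ds)` at constant
#' curvature `1/R`.
#'
#' @param R droplet radius (µm).
#' @param L bundle length (µm).
#' @param k_b flexural rigidity (pN·µm²).
#' @return energy in pN·µm.
#' @export
bundle_bending_energy <- function(R, L, k_b) {
  stopifnot(R > 0, L > 0, k_b > 0)
  k_b * L / (2 * R^2)
}

#' Thickness-radius scaling exponent from the mode model
#'
#' Evaluates `u_m` on a grid of droplet radii (with the bundle length either
#' tied to the circumference, `L = 2*pi*R`, or held fixed) and returns the
#' slope of `log(u_m)` against `log(R)`.  With `L = 2*pi*R` the slope is
#' exactly 1.5 for every mode index and persistence length; with fixed `L` it
#' is exactly 2.
#'
#' @param R_grid numeric vector of at least 3 distinct radii (µm).
#' @param L_p persistence length (µm).
#' @param m mode index.
#' @param k_BT thermal energy (pN·µm).
#' @param L either `"circumference"` (default, `L = 2*pi*R`) or a fixed
#'   numeric bundle length in µm.
#' @return fitted log-log slope (dimensionless).
#' @export
scaling_exponent <- function(R_grid, L_p = 18, m = 1L, k_BT = 0.0042,
                             L = "circumference") {
  stopifnot(length(unique(R_grid)) >= 3, all(R_grid > 0))
  u <- vapply(R_grid, function(R) {
    Lb <- if (identical(L, "circumference")) 2 * pi * R else L
    mode_amplitude(mode_model(R = R, L_p = L_p, m = m, k_BT = k_BT, L = Lb))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(u) ~ log(R_grid)))[2])
}
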