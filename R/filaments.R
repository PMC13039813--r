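#' Semiflexible growing actin filament
#'
#' A filament is an ordered chain of vertices connected by inextensible
#' segments of length `L_seg` (the last segment may be partial while the plus
#' end grows).  The minus end is vertex 1; it never grows but moves freely
#' under forces.  The plus end elongates deterministically at `k_grow` while
#' uncapped, and bending about interior hinge points is penalized by the
#' flexural rigidity `k_bend`.
#'
#' @param start 3-vector, position of the minus end (µm).
#' @param direction 3-vector, initial orientation (normalized internally).
#' @param length initial contour length (µm); default one segment.
#' @param L_seg segment length (µm).
#' @param k_bend flexural rigidity (pN·µm²).  The default 0.075 corresponds
#'   to an actin persistence length of ~18 µm at k_BT = 0.0042 pN·µm.
#' @param k_grow plus-end growth rate (µm/s).
#' @param capped logical, initial plus-end capping state.
#' @return an object of class `"filament"`.
#' @examples
#' f <- filament(c(0, 0, 0), c(1, 0, 0))
#' filament_length(grow_plus_end(f, 600))   # ~ 2*pi with defaults
#' @export
filament <- function(start = c(0, 0, 0), direction = c(1, 0, 0),
                     length = 0.1, L_seg = 0.1, k_bend = 0.075,
                     k_grow = 0.0103, capped = FALSE) {
  stopifnot(length > 0, L_seg > 0, k_bend >= 0, k_grow >= 0)
  d <- direction / sqrt(sum(direction^2))
  n_full <- floor(length / L_seg + 1e-12)
  partial <- length - n_full * L_seg
  if (partial < 1e-12) { partial <- L_seg; n_full <- n_full - 1 }
  s <- c(seq(0, n_full * L_seg, by = L_seg), n_full * L_seg + partial)
  v <- outer(s, d) + matrix(start, length(s), 3, byrow = TRUE)
  structure(list(vertices = v, L_seg = L_seg, partial = partial,
                 k_bend = k_bend, k_grow = k_grow, capped = isTRUE(capped)),
            class = "filament")
}

#' Build a filament directly from a vertex chain
#'
#' Used for fixtures (e.g. circular arcs) and tests.  Full segments must all
#' have the same length; the trailing segment may be partial.
#' @param vertices n x 3 matrix of vertex positions (µm).
#' @param k_bend,k_grow,capped see [filament()].
#' @return a `"filament"`.
#' @export
filament_from_vertices <- function(vertices, k_bend = 0.075, k_grow = 0.0103,
                                   capped = FALSE) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3, nrow(vertices) >= 2)
  seg <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                       vertices[-nrow(vertices), , drop = FALSE])^2))
  L_seg <- if (length(seg) > 1) seg[1] else seg[1]
  structure(list(vertices = vertices, L_seg = L_seg,
                 partial = seg[length(seg)], k_bend = k_bend,
                 k_grow = k_grow, capped = isTRUE(capped)),
            class = "filament")
}

#' Contour length of a filament
#' @param fil a [filament()].
#' @return length (µm): full segments times `L_seg` plus the partial segment.
#' @export
filament_length <- function(fil) {
  (nrow(fil$vertices) - 2) * fil$L_seg + fil$partial
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf("filament: %d vertices, L = %.4f um, plus end %s\n",
              nrow(x$vertices), filament_length(x),
              if (x$capped) "capped" else "uncapped"))
  invisible(x)
}

#' Stochastic capping kinetics of the plus end
#' @param k_cap capping rate (1/s).
#' @param k_uncap uncapping rate (1/s).
#' @return list of class `"capping_kinetics"`.
#' @export
capping_kinetics <- function(k_cap, k_uncap) {
  if (k_cap < 0 || k_uncap < 0) stop("capping rates must be non-negative")
  structure(list(k_cap = k_cap, k_uncap = k_uncap),
            class = "capping_kinetics")
}

#' Deterministic plus-end elongation
#'
#' While uncapped the contour length increases by exactly `k_grow * dt`; new
#' vertices are appended along the terminal tangent whenever the partial
#' segment would exceed `L_seg`.  Capped filaments are returned unchanged.
#' Growth is additive: many small steps and one large step give the same
#' length.
#'
#' @param fil a [filament()].
#' @param dt time step (s).
#' @return the grown filament.
#' @export
grow_plus_end <- function(fil, dt) {
  stopifnot(dt > 0)
  if (fil$capped || fil$k_grow == 0) return(fil)
  add <- fil$k_grow * dt
  v <- fil$vertices
  n <- nrow(v)
  d <- v[n, ] - v[n - 1, ]
  nd <- sqrt(sum(d^2))
  d <- if (nd > 0) d / nd else c(1, 0, 0)
  remaining <- fil$partial + add
  base <- v[n - 1, ]
  v <- v[-n, , drop = FALSE]
  while (remaining > fil$L_seg + 1e-12) {
    base <- base + d * fil$L_seg
    v <- rbind(v, base)
    remaining <- remaining - fil$L_seg
  }
  v <- rbind(v, base + d * remaining)
  fil$vertices <- unname(v)
  fil$partial <- remaining
  fil
}

#' One stochastic capping/uncapping attempt
#'
#' Uncapped plus ends cap with probability `1 - exp(-k_cap * dt)` and capped
#' ends uncap with probability `1 - exp(-k_uncap * dt)`; exactly one
#' transition attempt is made per (sub-)step.  When `k * dt > 0.1` the step is
#' subdivided so the exponential probabilities stay in their accurate regime.
#' Uses R's global RNG stream.
#'
#' @param fil a [filament()].
#' @param kinetics a [capping_kinetics()].
#' @param dt time step (s).
#' @return the filament with a possibly toggled `capped` state.
#' @export
update_capping <- function(fil, kinetics, dt) {
  stopifnot(inherits(kinetics, "capping_kinetics"), dt > 0)
  kmax <- max(kinetics$k_cap, kinetics$k_uncap)
  nsub <- max(1L, ceiling(kmax * dt / 0.1))
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    k <- if (fil$capped) kinetics$k_uncap else kinetics$k_cap
    if (k > 0 && stats::runif(1) < 1 - exp(-k * h))
      fil$capped <- !fil$capped
  }
  fil
}

#' Discrete bending energy of a filament
#'
#' `E = (k_bend / L_seg) * sum_i (1 - cos(theta_i))` over interior hinge
#' angles; converges to the worm-like-chain energy
#' `(k_bend/2) * integral(kappa^2 ds)` as `L_seg -> 0`.  The hinge flanking
#' the partial plus-end segment is weighted by `(partial / L_seg)^2` so its
#' stiffness ramps in smoothly as the growing tip segment fills (a
#' near-empty tip segment would otherwise make the hinge force arbitrarily
#' stiff and the angle of a fresh tip segment would wander freely).
#' @param fil a [filament()].
#' @return energy (pN·µm); 0 for chains with fewer than 3 vertices.
#' @export
bending_energy <- function(fil) {
  v <- fil$vertices
  n <- nrow(v)
  if (n < 3) return(0)
  u <- v[-1, , drop = FALSE] - v[-n, , drop = FALSE]
  len <- sqrt(rowSums(u^2))
  if (any(len == 0)) stop("coincident vertices")
  ct <- rowSums(u[-1, , drop = FALSE] * u[-(n - 1), , drop = FALSE]) /
    (len[-1] * len[-(n - 1)])
  w <- rep(1, n - 2)
  w[n - 2] <- min(1, (fil$partial / fil$L_seg)^2)
  fil$k_bend / fil$L_seg * sum(w * (1 - ct))
}

#' Bending forces on each vertex
#'
#' Analytic negative gradient of [bending_energy()].  The force set has zero
#' net force and zero net torque (the energy is invariant to rigid motions).
#' @param fil a [filament()] with at least 3 vertices.
#' @return n x 3 matrix of forces (pN).
#' @export
bending_forces <- function(fil) {
  v <- fil$vertices
  n <- nrow(v)
  if (n < 3) stop("need >= 3 vertices for bending")
  u <- v[-1, , drop = FALSE] - v[-n, , drop = FALSE]   # (n-1) segments
  len <- sqrt(rowSums(u^2))
  if (any(len == 0)) stop("coincident vertices")
  F <- matrix(0, n, 3)
  kfull <- fil$k_bend / fil$L_seg
  wtip <- min(1, (fil$partial / fil$L_seg)^2)
  for (h in 2:(n - 1)) {
    k <- if (h == n - 1) kfull * wtip else kfull
    if (k == 0) next
    a <- u[h - 1, ]; bb <- u[h, ]
    la <- len[h - 1]; lb <- len[h]
    ct <- sum(a * bb) / (la * lb)
    dca <- bb / (la * lb) - ct * a / la^2    # d cos / d a
    dcb <- a / (la * lb) - ct * bb / lb^2    # d cos / d b
    # force = -dE/dr = +k * d cos / dr
    F[h - 1, ] <- F[h - 1, ] - k * dca
    F[h, ]     <- F[h, ]     + k * (dca - dcb)
    F[h + 1, ] <- F[h + 1, ] + k * dcb
  }
  F
}

#' Restore segment-length constraints
#'
#' Newton iteration on the segment-length constraints: every full segment is
#' restored to `L_seg`, and the trailing segment to its bookkept partial
#' length, displacing vertices minimally (equal weights).  For a chain the
#' constraint Gram matrix is tridiagonal, so each iteration is an O(n)
#' Thomas solve and convergence is quadratic; errors out with the maximum
#' residual after `max_sweeps` iterations.
#'
#' @param fil a [filament()].
#' @param tol maximum allowed residual per segment (µm).
#' @param max_sweeps iteration limit.
#' @return the projected filament.
#' @export
enforce_inextensibility <- function(fil, tol = 1e-6, max_sweeps = 50) {
  v <- fil$vertices
  n <- nrow(v)
  m <- n - 1
  tgt <- c(rep(fil$L_seg, n - 2), fil$partial)
  worst <- Inf
  for (s in seq_len(max_sweeps)) {
    d <- v[-1, , drop = FALSE] - v[-n, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    if (any(len == 0)) stop("coincident vertices during projection")
    u <- d / len
    r <- len - tgt
    worst <- max(abs(r))
    if (worst < tol) { fil$vertices <- v; return(fil) }
    # solve (J J^T) lam = -r: tridiagonal, diag 2, off -u_j . u_{j+1}
    diag_ <- rep(2, m)
    off <- if (m > 1) -rowSums(u[-m, , drop = FALSE] *
                               u[-1, , drop = FALSE]) else numeric(0)
    lam <- -r
    if (m > 1) {
      for (j in 2:m) {
        w <- off[j - 1] / diag_[j - 1]
        diag_[j] <- diag_[j] - w * off[j - 1]
        lam[j] <- lam[j] - w * lam[j - 1]
      }
    }
    lam[m] <- lam[m] / diag_[m]
    if (m > 1) for (j in (m - 1):1)
      lam[j] <- (lam[j] - off[j] * lam[j + 1]) / diag_[j]
    # dx = J^T lam: vertex j gets -u_j lam_j + u_{j-1} lam_{j-1}
    dx <- matrix(0, n, 3)
    dx[1:m, ] <- dx[1:m, ] - u * lam
    dx[2:n, ] <- dx[2:n, ] + u * lam
    v <- v + dx
  }
  stop(sprintf("inextensibility projection did not converge: max residual %.3g um",
               worst))
}

#' Resample a filament at fixed arc-length spacing
#'
#' Points are placed along the polyline every `spacing` µm starting at the
#' minus end; the plus end is always included, so degenerate spacings larger
#' than the filament return the two end points.
#'
#' @param fil a [filament()].
#' @param spacing arc-length interval (µm); default 0.0027 (actin monomer
#'   rise), i.e. monomer-level discretization.
#' @return m x 3 matrix of points.
#' @export
discretize <- function(fil, spacing = 0.0027) {
  stopifnot(spacing > 0)
  v <- fil$vertices
  n <- nrow(v)
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-n, , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[n]
  s <- seq(0, L, by = spacing)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx[idx >= n] <- n - 1
  w <- (s - cs[idx]) / seg[idx]
  v[idx, , drop = FALSE] +
    (v[idx + 1, , drop = FALSE] - v[idx, , drop = FALSE]) * w
}
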