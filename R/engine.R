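#' Simulation configuration
#'
#' Collects every parameter of a droplet simulation with the defaults used
#' throughout: an initially spherical droplet of radius 1 µm with surface
#' tension 7 pN/µm and effective viscosity 100 pN·s/µm, 30 filaments growing
#' at 0.0103 µm/s (so they reach the droplet circumference, 2*pi µm, in the
#' 600 s duration), and 1000 tetravalent crosslinkers (~0.40 µM).
#'
#' @param duration total simulated time (s).
#' @param dt integration time step (s).
#' @param snapshot_interval recording interval (s); must satisfy
#'   `dt < snapshot_interval <= duration`.
#' @param seed integer RNG seed; the same configuration and seed reproduce
#'   the trajectory bit for bit.
#' @param k_BT thermal energy (pN·µm).
#' @param medium_viscosity droplet medium viscosity (pN·s/µm²); sets agent
#'   mobilities via Stokes drag.  Distinct from `effective_viscosity`, which
#'   damps boundary axis motion only.
#' @param radius initial droplet radius (µm).
#' @param surface_tension sigma (pN/µm).
#' @param effective_viscosity boundary damping (pN·s/µm).
#' @param confinement_stiffness boundary repulsion stiffness (pN/µm).
#' @param rigid freeze the boundary axes (rigid-droplet mode).
#' @param n_filaments number of filaments.
#' @param k_grow,k_bend,segment_length filament parameters (see [filament()]).
#' @param k_cap,k_uncap plus-end capping kinetics (1/s).
#' @param linker_mode `"tetramer"`, `"monomer"` or `"none"`.
#' @param n_linkers crosslinker count; default 1000 tetramers or 2000
#'   monomers.
#' @param k_bind,k_unbind,F0,k_form,k_split,binding_distance,link_stiffness
#'   crosslinker kinetics (see [kinetic_params()]).
#' @param steric_stiffness soft linker-filament overlap penalty (pN/µm).
#' @param linker_radius crosslinker radius (µm).
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(duration = 600, dt = 0.005,
                              snapshot_interval = 1, seed = 1,
                              k_BT = 0.0042, medium_viscosity = 0.5,
                              radius = 1, surface_tension = 7,
                              effective_viscosity = 100,
                              confinement_stiffness = 100, rigid = FALSE,
                              n_filaments = 30, k_grow = 0.0103,
                              k_bend = 0.075, segment_length = 0.1,
                              k_cap = 0, k_uncap = 0,
                              linker_mode = c("tetramer", "monomer", "none"),
                              n_linkers = NULL,
                              k_bind = 0, k_unbind = 0, F0 = 6,
                              k_form = 0, k_split = 0,
                              binding_distance = 0.03, link_stiffness = 100,
                              steric_stiffness = 100, linker_radius = 0.03) {
  linker_mode <- match.arg(linker_mode)
  if (is.null(n_linkers))
    n_linkers <- switch(linker_mode, tetramer = 1000L, monomer = 2000L,
                        none = 0L)
  if (linker_mode == "none") n_linkers <- 0L
  stopifnot(dt > 0, dt < snapshot_interval, snapshot_interval <= duration,
            k_BT >= 0, medium_viscosity > 0, radius > 0)
  structure(list(duration = duration, dt = dt,
                 snapshot_interval = snapshot_interval, seed = as.integer(seed),
                 k_BT = k_BT, medium_viscosity = medium_viscosity,
                 radius = radius, surface_tension = surface_tension,
                 effective_viscosity = effective_viscosity,
                 confinement_stiffness = confinement_stiffness,
                 rigid = isTRUE(rigid),
                 n_filaments = as.integer(n_filaments), k_grow = k_grow,
                 k_bend = k_bend, segment_length = segment_length,
                 k_cap = k_cap, k_uncap = k_uncap,
                 linker_mode = linker_mode, n_linkers = as.integer(n_linkers),
                 k_bind = k_bind, k_unbind = k_unbind, F0 = F0,
                 k_form = k_form, k_split = k_split,
                 binding_distance = binding_distance,
                 link_stiffness = link_stiffness,
                 steric_stiffness = steric_stiffness,
                 linker_radius = linker_radius),
            class = "simulation_config")
}

#' Named configuration presets
#'
#' `"disc"` uses weak binding kinetics (k_bind = 0.1, k_unbind = 1 s⁻¹) that
#' leave crosslinkers mostly unbound, `"ring"` strong kinetic-trapping
#' kinetics (k_bind = 10, k_unbind = 1 s⁻¹), `"multimer"` ring-forming actin
#' kinetics with dynamically multimerizing monomers (k_form = 10,
#' k_split = 0.01 s⁻¹), `"no-crosslinker"` omits linkers entirely, and
#' `"rigid"` freezes the boundary under ring kinetics.
#'
#' @param name preset name.
#' @param ... overrides passed on to [simulation_config()].
#' @return a [simulation_config()].
#' @export
preset_config <- function(name = c("disc", "ring", "multimer",
                                   "no-crosslinker", "rigid"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    disc = list(k_bind = 0.1, k_unbind = 1.0),
    ring = list(k_bind = 10, k_unbind = 1.0),
    multimer = list(linker_mode = "monomer", k_bind = 10, k_unbind = 1.0,
                    k_form = 10, k_split = 0.01),
    `no-crosslinker` = list(linker_mode = "none"),
    rigid = list(k_bind = 10, k_unbind = 1.0, rigid = TRUE))
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

#' Time-compressed variant of a configuration
#'
#' Desk-scale protocol: all chemical rates (growth, capping, binding,
#' unbinding, multimerization) are multiplied by `scale` while the duration
#' and the boundary damping `effective_viscosity` are divided by it, so the
#' deterministic dynamics traverse the same sequence of states in 1/scale of
#' the simulated time.  Thermal diffusion is not rescaled, so Brownian
#' exploration per unit growth is reduced; the morphology outcomes are
#' force-dominated and survive this compression.
#'
#' @param config a [simulation_config()].
#' @param scale compression factor (default 10).
#' @param scale_viscosity also divide the boundary damping
#'   `effective_viscosity` by `scale` (default).  Set `FALSE` when the
#'   deformation timescale `mu_effective / sigma` already fits comfortably
#'   inside the compressed duration: the boundary then still tracks its
#'   quasi-static shape, and leaving the damping at full value suppresses
#'   the extra shape jitter a fast-responding boundary picks up from agent
#'   collisions.
#' @return a rescaled [simulation_config()].
#' @export
time_scaled_config <- function(config, scale = 10, scale_viscosity = TRUE) {
  stopifnot(inherits(config, "simulation_config"), scale > 0)
  upd <- list(duration = config$duration / scale,
              snapshot_interval = config$snapshot_interval / scale,
              effective_viscosity = if (scale_viscosity)
                config$effective_viscosity / scale else
                config$effective_viscosity,
              k_grow = config$k_grow * scale,
              k_cap = config$k_cap * scale, k_uncap = config$k_uncap * scale,
              k_bind = config$k_bind * scale,
              k_unbind = config$k_unbind * scale,
              k_form = config$k_form * scale,
              k_split = config$k_split * scale)
  cfg <- utils::modifyList(unclass(config), upd)
  do.call(simulation_config, cfg[names(cfg) != "n_linkers_default"])
}

# engine-facing flat parameter list
.engine_cfg <- function(config) {
  list(dt = config$dt, L_seg = config$segment_length,
       k_grow = config$k_grow, k_bend = config$k_bend,
       k_cap = config$k_cap, k_uncap = config$k_uncap,
       k_bind = config$k_bind, k_unbind = config$k_unbind, F0 = config$F0,
       k_form = config$k_form, k_split = config$k_split,
       binding_distance = config$binding_distance,
       link_stiffness = config$link_stiffness,
       steric_stiffness = config$steric_stiffness,
       linker_radius = config$linker_radius,
       k_BT = config$k_BT, medium_viscosity = config$medium_viscosity,
       surface_tension = config$surface_tension,
       effective_viscosity = config$effective_viscosity,
       reference_volume = 4 / 3 * pi * config$radius^3,
       confinement_stiffness = config$confinement_stiffness,
       rigid = config$rigid,
       mode = switch(config$linker_mode, none = 0L, tetramer = 1L,
                     monomer = 2L))
}

#' Largest stable mechanics sub-step of a configuration
#'
#' Explicit Euler-Maruyama integration of the stiffest force term is stable
#' when `mobility * stiffness * h < 2`.  The dominant stiffnesses are the
#' alternating bending mode (bounded by `16 * k_bend / L_seg^3`), engaged
#' links (`link_stiffness` plus the steric penalty) and the confinement
#' spring.  The engine applies this bound automatically: each time step
#' `dt` is internally subdivided so that `mobility * stiffness * h <= 1`,
#' re-evaluating the bound from the current per-vertex link multiplicity.
#' This function reports the base bound (single link per vertex) as a
#' diagnostic for cost estimates.
#'
#' @param config a [simulation_config()].
#' @return stable sub-step (s).
#' @export
stable_dt <- function(config) {
  mu_v <- 1 / (6 * pi * config$medium_viscosity * config$segment_length / 2)
  mu_l <- 1 / (6 * pi * config$medium_viscosity * config$linker_radius)
  cand <- c(bending = mu_v * (16 * config$k_bend / config$segment_length^3 +
                              config$confinement_stiffness +
                              config$steric_stiffness),
            linker = mu_l * config$confinement_stiffness)
  if (config$linker_mode != "none" && config$n_linkers > 0)
    cand["links"] <- max(mu_v, mu_l) *
      (config$link_stiffness + config$steric_stiffness +
       config$confinement_stiffness)
  1 / max(cand)
}

# uniform random points inside the ellipsoid (rejection from the unit ball)
.runif_ellipsoid <- function(n, semi_axes, margin = 0) {
  out <- matrix(NA_real_, n, 3)
  got <- 0
  ax <- semi_axes - margin
  while (got < n) {
    m <- max(2 * (n - got), 16)
    p <- matrix(stats::runif(3 * m, -1, 1), m, 3)
    keep <- rowSums(p^2) <= 1
    p <- p[keep, , drop = FALSE]
    take <- min(nrow(p), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <-
        p[seq_len(take), , drop = FALSE] *
        matrix(ax, take, 3, byrow = TRUE)
      got <- got + take
    }
  }
  out
}

.runif_directions <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# initial engine state for a configuration (uses the current RNG stream)
.initial_state <- function(config) {
  nf <- config$n_filaments
  starts <- if (nf > 0)
    .runif_ellipsoid(nf, rep(config$radius, 3),
                     margin = config$segment_length) else matrix(0, 0, 3)
  dirs <- if (nf > 0) .runif_directions(nf) else matrix(0, 0, 3)
  fv <- lapply(seq_len(nf), function(i)
    rbind(starts[i, ], starts[i, ] + dirs[i, ] * config$segment_length))
  lp <- if (config$n_linkers > 0)
    .runif_ellipsoid(config$n_linkers, rep(config$radius, 3)) else
    matrix(0, 0, 3)
  list(fil_vertices = fv,
       fil_partial = rep(config$segment_length, nf),
       fil_capped = rep(FALSE, nf),
       linker_pos = lp,
       actin_links = matrix(0, 0, 3),
       partner_links = matrix(0, 0, 2),
       semi_axes = rep(config$radius, 3))
}

#' Run a droplet simulation
#'
#' Seeds the RNG from `config$seed`, places filaments (uniform random
#' interior positions and orientations, initial length one segment) and
#' crosslinkers (uniform random interior), then integrates the overdamped
#' Langevin dynamics: every mobile point moves by `mobility * force * dt`
#' plus Gaussian noise of per-coordinate standard deviation
#' `sqrt(2 * D * dt)` (`D = mobility * k_BT`), followed by the
#' inextensibility projection and the boundary axis update.  The fixed event
#' order within a step is growth, capping, binding kinetics, forces, move,
#' project, boundary.
#'
#' @param config a [simulation_config()].
#' @return object of class `"droplet_trajectory"`: a list with `times`,
#'   `frames` (one state per snapshot) and `config`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(duration = 1, dt = 0.005, snapshot_interval = 0.5,
#'                          n_filaments = 2, linker_mode = "none", seed = 7)
#' traj <- simulate_droplet(cfg)
#' length(traj$frames)
#' }
#' @export
simulate_droplet <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  state <- .initial_state(config)
  nsteps <- round(config$duration / config$dt)
  snap <- max(1L, round(config$snapshot_interval / config$dt))
  res <- cpp_run_engine(state, .engine_cfg(config), nsteps, snap, 0)
  structure(list(times = res$times, frames = res$snapshots, config = config),
            class = "droplet_trajectory")
}

#' @export
print.droplet_trajectory <- function(x, ...) {
  cat(sprintf("droplet trajectory: %d frames over %.1f s, %d filaments, %d linkers (%s)\n",
              length(x$frames), max(x$times), x$config$n_filaments,
              x$config$n_linkers, x$config$linker_mode))
  invisible(x)
}

#' Advance a system state by single Langevin steps
#'
#' Low-level surface over the same integrator used by [simulate_droplet()];
#' operates on an engine state (the per-frame representation stored in
#' trajectories: `fil_vertices`, `fil_partial`, `fil_capped`, `linker_pos`,
#' `actin_links`, `partner_links`, `semi_axes`).
#'
#' @param state engine state list.
#' @param config a [simulation_config()] (its `dt` is the step size).
#' @param nsteps number of steps (default 1).
#' @return the updated state.
#' @export
langevin_step <- function(state, config, nsteps = 1) {
  res <- cpp_run_engine(state, .engine_cfg(config), as.integer(nsteps), 0L, 0)
  res$final_state
}

# ------------------------------------------------------------ trajectory IO

.frame_rows <- function(t, fr) {
  rows <- list(data.frame(t = t, record = "boundary", id = 0L, sub = 0L,
                          x = fr$semi_axes[1], y = fr$semi_axes[2],
                          z = fr$semi_axes[3], aux = 0))
  for (i in seq_along(fr$fil_vertices)) {
    v <- fr$fil_vertices[[i]]
    rows[[length(rows) + 1]] <-
      data.frame(t = t, record = "filament", id = i,
                 sub = seq_len(nrow(v)), x = v[, 1], y = v[, 2], z = v[, 3],
                 aux = as.integer(fr$fil_capped[i]))
  }
  lp <- fr$linker_pos
  if (nrow(lp) > 0)
    rows[[length(rows) + 1]] <-
      data.frame(t = t, record = "linker", id = seq_len(nrow(lp)), sub = 0L,
                 x = lp[, 1], y = lp[, 2], z = lp[, 3], aux = 0)
  al <- fr$actin_links
  if (nrow(al) > 0)
    rows[[length(rows) + 1]] <-
      data.frame(t = t, record = "link", id = al[, 1], sub = al[, 2],
                 x = al[, 3], y = 0, z = 0, aux = 1)
  pl <- fr$partner_links
  if (nrow(pl) > 0)
    rows[[length(rows) + 1]] <-
      data.frame(t = t, record = "link", id = pl[, 1], sub = pl[, 2],
                 x = 0, y = 0, z = 0, aux = 2)
  do.call(rbind, rows)
}

#' Write / read a trajectory
#'
#' The trajectory is stored as a flat CSV (gzip-compressed when the path ends
#' in `.gz`) with columns `(t, record, id, sub, x, y, z, aux)` covering
#' boundary axes, filament vertices (aux = capping state), linker centers,
#' and link topology rows (aux 1 = actin link with abscissa in `x`, aux 2 =
#' partner bond).  Metadata (full configuration, seed, package version,
#' frame count) is written alongside as `<path>.meta.json`; reading verifies
#' the frame count so truncated files fail loudly.
#'
#' @param traj a `"droplet_trajectory"`.
#' @param path output CSV path (`.gz` optional).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the reconstructed `"droplet_trajectory"`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "droplet_trajectory"))
  tab <- if (length(traj$frames) == 0)
    data.frame(t = numeric(0), record = character(0), id = integer(0),
               sub = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), aux = numeric(0))
  else do.call(rbind, Map(.frame_rows, traj$times, traj$frames))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE)
  meta <- list(config = unclass(traj$config),
               n_frames = length(traj$frames),
               package_version = as.character(utils::packageVersion("dropletActin")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- tryCatch(utils::read.csv(con),
                  error = function(e) stop("malformed trajectory file: ",
                                           conditionMessage(e)))
  req <- c("t", "record", "id", "sub", "x", "y", "z", "aux")
  if (!all(req %in% names(tab)))
    stop("malformed trajectory file: missing columns ",
         paste(setdiff(req, names(tab)), collapse = ", "))
  times <- sort(unique(tab$t))
  if (length(times) != meta$n_frames)
    stop(sprintf("truncated trajectory: expected %d frames, found %d",
                 meta$n_frames, length(times)))
  frames <- lapply(times, function(tt) {
    d <- tab[tab$t == tt, ]
    bd <- d[d$record == "boundary", ]
    if (nrow(bd) != 1) stop("malformed frame at t = ", tt)
    fd <- d[d$record == "filament", ]
    ids <- sort(unique(fd$id))
    fv <- lapply(ids, function(i) {
      di <- fd[fd$id == i, ]
      di <- di[order(di$sub), ]
      unname(as.matrix(di[, c("x", "y", "z")]))
    })
    partial <- vapply(fv, function(v) {
      n <- nrow(v)
      sqrt(sum((v[n, ] - v[n - 1, ])^2))
    }, numeric(1))
    capped <- vapply(ids, function(i) fd$aux[fd$id == i][1] == 1, logical(1))
    ld <- d[d$record == "linker", ]
    ld <- ld[order(ld$id), ]
    lk <- d[d$record == "link", ]
    list(fil_vertices = fv,
         fil_partial = partial,
         fil_capped = capped,
         linker_pos = unname(as.matrix(ld[, c("x", "y", "z")])),
         actin_links = unname(as.matrix(lk[lk$aux == 1,
                                           c("id", "sub", "x")])),
         partner_links = unname(as.matrix(lk[lk$aux == 2, c("id", "sub")])),
         semi_axes = c(bd$x, bd$y, bd$z))
  })
  cfg <- meta$config
  config <- tryCatch(do.call(simulation_config, cfg[names(cfg) %in%
                               names(formals(simulation_config))]),
                     error = function(e) NULL)
  structure(list(times = times, frames = frames, config = config),
            class = "droplet_trajectory")
}

#' Boundary aspect-ratio time series of a trajectory
#' @param traj a `"droplet_trajectory"`.
#' @return data frame with `time`, `a`, `b`, `c` (sorted), `aspect_ratio`.
#' @export
aspect_ratio_series <- function(traj) {
  ax <- t(vapply(traj$frames, function(f) sort(f$semi_axes, decreasing = TRUE),
                 numeric(3)))
  data.frame(time = traj$times, a = ax[, 1], b = ax[, 2], c = ax[, 3],
             aspect_ratio = ax[, 1] / ax[, 3])
}

#' Filament lengths in one trajectory frame
#' @param traj a `"droplet_trajectory"`.
#' @param frame frame index.
#' @param L_seg segment length (µm); defaults to the configuration value.
#' @return numeric vector of contour lengths (µm).
#' @export
frame_lengths <- function(traj, frame, L_seg = traj$config$segment_length) {
  fr <- traj$frames[[frame]]
  vapply(seq_along(fr$fil_vertices), function(i)
    (nrow(fr$fil_vertices[[i]]) - 2) * L_seg + fr$fil_partial[i], numeric(1))
}

#' Monomer-level point cloud of all filaments in a frame
#' @param traj a `"droplet_trajectory"`.
#' @param frame frame index.
#' @param spacing resampling interval (µm).
#' @return matrix of 3D points.
#' @export
frame_points <- function(traj, frame, spacing = 0.0027) {
  fr <- traj$frames[[frame]]
  do.call(rbind, lapply(fr$fil_vertices, function(v)
    discretize(filament_from_vertices(v), spacing)))
}
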