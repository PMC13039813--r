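test_that("zero temperature and zero forces give no motion", {
  cfg <- simulation_config(duration = 1, dt = 0.01, snapshot_interval = 0.5,
                           n_filaments = 1, linker_mode = "tetramer",
                           n_linkers = 5, k_BT = 1e-300, rigid = TRUE,
                           seed = 1)
  set.seed(1)
  st <- dropletActin:::.initial_state(cfg)
  ec <- dropletActin:::.engine_cfg(cfg)
  ec$k_BT <- 0; ec$k_grow <- 0; ec$steric_stiffness <- 0
  out <- langevin_step(st, structure(utils::modifyList(unclass(cfg),
    list(k_BT = 0, k_grow = 0, steric_stiffness = 0)),
    class = "simulation_config"), nsteps = 50)
  expect_equal(out$fil_vertices[[1]], st$fil_vertices[[1]], tolerance = 1e-12)
  expect_equal(out$linker_pos, st$linker_pos, tolerance = 1e-12)
})

test_that("free crosslinker diffusion satisfies the Einstein relation", {
  # D = k_BT / (6 pi eta r) = 0.01486 um^2/s; MSD over 1 s = 6 D
  cfg <- simulation_config(duration = 1, dt = 0.005, snapshot_interval = 1,
                           n_filaments = 0, linker_mode = "tetramer",
                           n_linkers = 1000, radius = 50, rigid = TRUE,
                           seed = 42)
  tr <- simulate_droplet(cfg)
  p0 <- tr$frames[[1]]$linker_pos
  p1 <- tr$frames[[2]]$linker_pos
  msd <- mean(rowSums((p1 - p0)^2))
  D <- 0.0042 / (6 * pi * 0.5 * 0.03)
  expect_equal(D, 0.01486, tolerance = 1e-3)
  expect_equal(msd, 6 * D, tolerance = 0.05)
})

test_that("per-coordinate noise variance equals 2 D dt", {
  cfg <- simulation_config(duration = 0.01, dt = 0.005,
                           snapshot_interval = 0.01, n_filaments = 0,
                           linker_mode = "tetramer", n_linkers = 2000,
                           radius = 50, rigid = TRUE, seed = 5)
  tr <- simulate_droplet(cfg)
  d <- tr$frames[[2]]$linker_pos - tr$frames[[1]]$linker_pos
  D <- 0.0042 / (6 * pi * 0.5 * 0.03)
  v_exp <- 2 * D * 0.01
  v_obs <- apply(d, 2, var)
  for (v in v_obs)
    expect_equal(v, v_exp, tolerance = 3 * sqrt(2 / (2000 - 1)))
})

test_that("engine forces equal the sum of the R module force terms", {
  f1 <- make_wiggly_chain(n = 8, seed = 31)
  f2 <- make_wiggly_chain(n = 6, seed = 32)
  f2$vertices <- sweep(f2$vertices, 2, c(0.1, 0.35, -0.1), "+")
  lks <- list(local({
    l <- linker(c(0.25, 0.1, 0), mode = "monomer")
    l$actin_links <- data.frame(filament = 1L, abscissa = 0.23)
    l$partner_links <- 2L
    l
  }), local({
    l <- linker(c(0.3, 0.12, 0.02), mode = "monomer")
    l$partner_links <- 1L
    l
  }))
  # small boundary so several vertices are outside and feel confinement
  ax <- c(0.45, 0.4, 0.35)
  b <- boundary(ax, confinement_stiffness = 100)
  par <- kinetic_params(link_stiffness = 250)
  cfg <- simulation_config(n_filaments = 2, linker_mode = "monomer",
                           n_linkers = 2, link_stiffness = 250,
                           steric_stiffness = 0, radius = 0.45)
  st <- make_state(list(f1, f2), do.call(rbind, lapply(lks, `[[`, "position")),
                   actin_links = cbind(1, 1, 0.23),
                   partner_links = cbind(1, 2), semi_axes = ax)
  ec <- dropletActin:::.engine_cfg(cfg)
  cf <- dropletActin:::cpp_system_forces(st, ec)
  lr <- link_forces(lks, list(f1, f2), par)
  want_f1 <- bending_forces(f1) + lr$filament_forces[[1]] +
    t(apply(f1$vertices, 1, function(p) as.numeric(confinement_force(p, b))))
  want_f2 <- bending_forces(f2) + lr$filament_forces[[2]] +
    t(apply(f2$vertices, 1, function(p) as.numeric(confinement_force(p, b))))
  want_l <- lr$linker_forces +
    t(apply(st$linker_pos, 1, function(p) as.numeric(confinement_force(p, b))))
  expect_equal(cf$filament_forces[[1]], want_f1, tolerance = 1e-8)
  expect_equal(cf$filament_forces[[2]], want_f2, tolerance = 1e-8)
  expect_equal(cf$linker_forces, want_l, tolerance = 1e-8)
})

test_that("internal forces sum to zero; only confinement loads the boundary", {
  f1 <- make_wiggly_chain(n = 10, seed = 33)
  lks <- list(local({
    l <- linker(c(0.3, 0.05, 0))
    l$actin_links <- data.frame(filament = 1L, abscissa = c(0.1, 0.55))
    l
  }))
  cfg <- simulation_config(n_filaments = 1, linker_mode = "tetramer",
                           n_linkers = 1, radius = 30, steric_stiffness = 100)
  st <- make_state(list(f1), matrix(lks[[1]]$position, 1, 3),
                   actin_links = rbind(c(1, 1, 0.1), c(1, 1, 0.55)),
                   semi_axes = c(30, 30, 30))
  cf <- dropletActin:::cpp_system_forces(st, dropletActin:::.engine_cfg(cfg))
  tot <- colSums(cf$filament_forces[[1]]) + colSums(cf$linker_forces)
  expect_equal(tot, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(cf$boundary_load, c(0, 0, 0))
})

test_that("identical seeds replay bit-identical trajectories", {
  cfg <- simulation_config(duration = 2, dt = 0.01, snapshot_interval = 1,
                           n_filaments = 3, linker_mode = "tetramer",
                           n_linkers = 30, k_bind = 5, k_unbind = 1,
                           k_cap = 0.5, k_uncap = 0.5, seed = 77)
  t1 <- simulate_droplet(cfg)
  t2 <- simulate_droplet(cfg)
  expect_identical(t1$frames, t2$frames)
  cfg2 <- cfg; cfg2$seed <- 78L
  t3 <- simulate_droplet(cfg2)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("trajectories round-trip through CSV with metadata", {
  cfg <- simulation_config(duration = 1, dt = 0.01, snapshot_interval = 0.5,
                           n_filaments = 2, linker_mode = "monomer",
                           n_linkers = 10, k_bind = 50, k_unbind = 0.1,
                           k_form = 50, k_split = 0.1, seed = 8)
  tr <- simulate_droplet(cfg)
  path <- file.path(tempdir(), "traj-test.csv.gz")
  write_trajectory(tr, path)
  rt <- read_trajectory(path)
  expect_equal(rt$times, tr$times)
  for (i in seq_along(tr$frames)) {
    expect_equal(rt$frames[[i]]$fil_vertices, tr$frames[[i]]$fil_vertices,
                 tolerance = 1e-9)
    expect_equal(rt$frames[[i]]$linker_pos, tr$frames[[i]]$linker_pos,
                 tolerance = 1e-9)
    expect_equal(rt$frames[[i]]$semi_axes, tr$frames[[i]]$semi_axes,
                 tolerance = 1e-9)
    expect_equal(nrow(rt$frames[[i]]$actin_links),
                 nrow(tr$frames[[i]]$actin_links))
    expect_equal(rt$frames[[i]]$fil_capped, tr$frames[[i]]$fil_capped)
  }
  # empty trajectory: valid file with metadata only
  empty <- structure(list(times = numeric(0), frames = list(), config = cfg),
                     class = "droplet_trajectory")
  p2 <- file.path(tempdir(), "empty.csv")
  write_trajectory(empty, p2)
  r2 <- read_trajectory(p2)
  expect_length(r2$frames, 0)
  # truncated file: explicit error, not a silent partial read
  p3 <- file.path(tempdir(), "trunc.csv")
  write_trajectory(tr, p3)
  lines <- readLines(p3)
  body <- lines[-1]
  writeLines(c(lines[1], body[startsWith(body, "0,")]), p3)
  expect_error(read_trajectory(p3), "truncated")
  # missing metadata is an error
  file.remove(paste0(p3, ".meta.json"))
  expect_error(read_trajectory(p3), "metadata")
})

test_that("a droplet with no filaments stays spherical", {
  cfg <- simulation_config(duration = 20, dt = 0.01, snapshot_interval = 10,
                           n_filaments = 0, linker_mode = "tetramer",
                           n_linkers = 100, surface_tension = 7,
                           effective_viscosity = 10, seed = 12)
  tr <- simulate_droplet(cfg)
  ars <- aspect_ratio_series(tr)
  expect_lt(max(abs(ars$aspect_ratio - 1)), 0.01)
})
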