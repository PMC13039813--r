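test_that("state labels enumerate 5 tetramer and 6 monomer states", {
  expect_equal(classify_state(linker(mode = "tetramer")), "0-bound")
  expect_length(linker_state_space("tetramer"), 5)
  expect_length(linker_state_space("monomer"), 6)
  lk <- linker(mode = "monomer")
  lk$partner_links <- c(2L, 3L)
  lk$actin_links <- data.frame(filament = 1L, abscissa = 0.5)
  expect_equal(classify_state(lk), "2B")
  # inconsistent counts are an integrity error
  bad <- linker(mode = "monomer")
  bad$partner_links <- c(2L, 3L, 4L)
  expect_error(classify_state(bad), "inconsistent")
})

test_that("binding probability matches 1 - exp(-k n dt)", {
  par <- kinetic_params(k_bind = 10)
  cand <- data.frame(filament = 1L, abscissa = 0.2)
  lk <- linker()
  # no candidates or zero rate: unchanged
  expect_identical(attempt_binding(lk, cand[0, ], par, 0.01), lk)
  expect_identical(
    attempt_binding(lk, cand, kinetic_params(k_bind = 0), 0.01)$actin_links,
    lk$actin_links)
  set.seed(10)
  n <- 4e4
  hits <- sum(vapply(seq_len(n), function(i)
    nrow(attempt_binding(lk, cand, par, 0.01)$actin_links) > 0, logical(1)))
  p <- 1 - exp(-0.1)
  expect_equal(hits / n, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})

test_that("Bell's law accelerates unbinding with tension", {
  par <- kinetic_params(k_unbind = 1, F0 = 6)
  expect_equal(bell_rate(1, 0, 6), 1)
  expect_equal(bell_rate(1, 6, 6), exp(1))
  expect_error(bell_rate(1, 1, 0), "F0")
  # empirical removal frequency at F = 2 F0, dt = 0.001
  set.seed(11)
  n <- 1e5
  hits <- sum(vapply(seq_len(n), function(i)
    attempt_unbinding(12, par, 0.001), logical(1)))
  p <- 1 - exp(-exp(2) * 0.001)
  expect_equal(p, 0.00736, tolerance = 1e-3)
  expect_equal(hits / n, p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})

test_that("bound fraction of an on/off site matches a Gillespie oracle", {
  # force-free single-site linker next to an immobile filament: the per-step
  # scheme must reproduce the exact two-state stationary occupancy
  k_on <- 2; k_off <- 1
  par <- kinetic_params(k_bind = k_on, k_unbind = k_off)
  cand <- data.frame(filament = 1L, abscissa = 0.1)
  lk <- linker(mode = "monomer")
  set.seed(12)
  nstep <- 3e4; dt <- 0.02
  bound <- logical(nstep)
  for (i in seq_len(nstep)) {
    if (nrow(lk$actin_links) == 0) {
      lk <- attempt_binding(lk, cand, par, dt)
    } else if (attempt_unbinding(0, par, dt)) {
      lk$actin_links <- lk$actin_links[0, ]
    }
    bound[i] <- nrow(lk$actin_links) > 0
  }
  # independent oracle: exact telegraph process with the same rates
  orc <- gen_two_state_series(k_cap = k_on, k_uncap = k_off,
                              duration = nstep * dt, dt = dt, seed = 77)
  p_sim <- mean(bound)
  p_orc <- mean(orc$capped)
  n_eff <- nstep * dt * (k_on + k_off) / 2
  expect_equal(p_sim, k_on / (k_on + k_off),
               tolerance = 4 / sqrt(n_eff) / p_sim * 0.5)
  expect_equal(p_orc, k_on / (k_on + k_off),
               tolerance = 4 / sqrt(n_eff) / p_orc * 0.5)
})

test_that("multimer events preserve chain topology (paths only)", {
  # three monomers in a row within binding distance
  mk <- function(x) {
    l <- linker(c(x, 0, 0), mode = "monomer")
    l
  }
  linkers <- list(mk(0), mk(0.02), mk(0.04))
  par <- kinetic_params(k_form = 1e4, k_split = 0)
  set.seed(5)
  out <- attempt_multimer_events(linkers, par, 0.01)
  deg <- vapply(out, function(l) length(l$partner_links), integer(1))
  expect_true(all(deg <= 2))
  # with k_form large everyone chains up, but no triangle forms
  nb <- sum(deg) / 2
  expect_equal(nb, 2)   # a 3-path, not a 3-cycle
  # k_split = 0: bonds never break
  out2 <- attempt_multimer_events(out, kinetic_params(k_form = 0, k_split = 0),
                                  0.01)
  expect_equal(vapply(out2, function(l) length(l$partner_links), integer(1)),
               deg)
  # self-bonding is impossible
  expect_true(all(vapply(seq_along(out), function(i)
    !(i %in% out[[i]]$partner_links), logical(1))))
})

test_that("mean multimer size matches a Gillespie oracle of the pair network", {
  # closed well-mixed system: bonds form at rate k_on per free ordered pair
  # and break at rate k_off per bond.  Chain topology is ignored by placing
  # all monomers in one binding neighbourhood with 2 partner sites each.
  n <- 8; k_on <- 0.5; k_off <- 2
  par <- kinetic_params(k_form = k_on, k_split = k_off, F0 = 6,
                        binding_distance = 1, link_stiffness = 0)
  linkers <- lapply(seq_len(n), function(i)
    linker(c(0.001 * i, 0, 0), mode = "monomer"))
  set.seed(21)
  dt <- 0.02; nstep <- 1.5e4
  nb <- numeric(nstep)
  for (s in seq_len(nstep)) {
    linkers <- attempt_multimer_events(linkers, par, dt)
    nb[s] <- sum(vapply(linkers, function(l) length(l$partner_links),
                        integer(1))) / 2
  }
  mean_bonds_sim <- mean(nb[-(1:2000)])

  # brute-force Gillespie on the same constrained-bond reaction network
  set.seed(22)
  gill_bonds <- local({
    partners <- lapply(seq_len(n), function(i) integer(0))
    t <- 0; t_end <- 400; acc <- 0; t_prev <- 0; burn <- 40
    repeat {
      deg <- lengths(partners)
      chain_id <- local({ # connected components for cycle rejection
        id <- seq_len(n)
        repeat {
          changed <- FALSE
          for (i in seq_len(n)) for (j in partners[[i]])
            if (id[j] != id[i]) { nid <- min(id[i], id[j]);
              id[id == id[i] | id == id[j]] <- nid; changed <- TRUE }
          if (!changed) break
        }
        id
      })
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      ok <- apply(pairs, 1, function(p)
        deg[p[1]] < 2 && deg[p[2]] < 2 &&
          !(p[2] %in% partners[[p[1]]]) &&
          chain_id[p[1]] != chain_id[p[2]])
      n_form <- sum(ok)
      n_bond <- sum(deg) / 2
      rate <- n_form * k_on + n_bond * k_off
      if (rate == 0) break
      tau <- rexp(1, rate)
      if (t > burn) acc <- acc + n_bond * min(tau, t_end - t)
      t <- t + tau
      if (t >= t_end) break
      if (runif(1) < n_form * k_on / rate) {
        pick <- which(ok)[sample.int(n_form, 1)]
        i <- pairs[pick, 1]; j <- pairs[pick, 2]
        partners[[i]] <- c(partners[[i]], j)
        partners[[j]] <- c(partners[[j]], i)
      } else {
        bonds <- do.call(rbind, lapply(seq_len(n), function(i)
          if (length(partners[[i]])) cbind(i, partners[[i]])))
        bonds <- bonds[bonds[, 1] < bonds[, 2], , drop = FALSE]
        pick <- sample.int(nrow(bonds), 1)
        i <- bonds[pick, 1]; j <- bonds[pick, 2]
        partners[[i]] <- setdiff(partners[[i]], j)
        partners[[j]] <- setdiff(partners[[j]], i)
      }
    }
    acc / (t_end - burn)
  })
  expect_equal(mean_bonds_sim, gill_bonds, tolerance = 0.07)
})

test_that("link forces obey Hooke's law and Newton's third law", {
  par <- kinetic_params(link_stiffness = 250)
  f <- filament(length = 0.5)
  lk <- linker(c(0.2, 0.01, 0))
  lk$actin_links <- data.frame(filament = 1L, abscissa = 0.2)
  res <- link_forces(list(lk), list(f), par)
  # endpoints 0.01 apart at 250 pN/um -> 2.5 pN
  expect_equal(sqrt(sum(res$linker_forces^2)), 2.5, tolerance = 1e-10)
  expect_equal(res$tensions$tension, 2.5, tolerance = 1e-10)
  # action-reaction: total force sums to zero
  tot <- res$linker_forces[1, ] + colSums(res$filament_forces[[1]])
  expect_equal(tot, c(0, 0, 0), tolerance = 1e-10)
  # coincident endpoints: no force
  lk2 <- linker(c(0.2, 0, 0))
  lk2$actin_links <- data.frame(filament = 1L, abscissa = 0.2)
  res2 <- link_forces(list(lk2), list(f), par)
  expect_equal(max(abs(res2$linker_forces)), 0)
  # dangling link beyond the filament end is dropped and reported
  lk3 <- linker(c(0.2, 0, 0))
  lk3$actin_links <- data.frame(filament = 1L, abscissa = 5)
  expect_equal(link_forces(list(lk3), list(f), par)$dropped, 1L)
})
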