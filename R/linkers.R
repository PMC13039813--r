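#' Crosslinker agent
#'
#' Crosslinkers are diffusing spheres of radius 30 nm.  In `"tetramer"` mode
#' (stable tetravalent bundlers such as VASP) a linker carries four
#' actin-binding sites and no partner sites.  In `"monomer"` mode (dynamic
#' multimerization, e.g. mini-Lpd) a linker carries a single actin-binding
#' site and two partner sites through which monomers chain into multimers.
#'
#' @param position 3-vector (µm).
#' @param mode `"tetramer"` or `"monomer"`.
#' @param radius sphere radius (µm).
#' @return object of class `"linker"` with empty link lists.
#' @export
linker <- function(position = c(0, 0, 0), mode = c("tetramer", "monomer"),
                   radius = 0.03) {
  mode <- match.arg(mode)
  structure(list(position = as.numeric(position), radius = radius,
                 mode = mode,
                 actin_links = data.frame(filament = integer(0),
                                          abscissa = numeric(0)),
                 partner_links = integer(0)),
            class = "linker")
}

#' Crosslinker kinetic and mechanical parameters
#'
#' @param k_bind actin binding rate per candidate in range (1/s).
#' @param k_unbind zero-force actin unbinding rate (1/s).
#' @param F0 characteristic unbinding force of the Bell slip bond (pN).
#' @param k_form multimer formation rate (1/s; monomer mode).
#' @param k_split zero-force multimer splitting rate (1/s; monomer mode).
#' @param binding_distance capture radius for binding candidates (µm).
#' @param link_stiffness Hookean stiffness of an engaged link (pN/µm).
#' @return list of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k_bind = 0, k_unbind = 0, F0 = 6,
                           k_form = 0, k_split = 0,
                           binding_distance = 0.03, link_stiffness = 100) {
  vals <- c(k_bind, k_unbind, F0, k_form, k_split, binding_distance,
            link_stiffness)
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  structure(list(k_bind = k_bind, k_unbind = k_unbind, F0 = F0,
                 k_form = k_form, k_split = k_split,
                 binding_distance = binding_distance,
                 link_stiffness = link_stiffness),
            class = "kinetic_params")
}

.free_actin_sites <- function(lk) {
  cap <- if (lk$mode == "tetramer") 4L else 1L
  cap - nrow(lk$actin_links)
}

#' Bell's-law slip-bond rate
#'
#' `k_off = k0 * exp(F / F0)`: tension accelerates unbinding with
#' characteristic force `F0`.
#' @param k0 zero-force rate (1/s).
#' @param F tension magnitude (pN), >= 0.
#' @param F0 characteristic force (pN), > 0.
#' @return rate (1/s).
#' @export
bell_rate <- function(k0, F, F0) {
  if (F0 <= 0) stop("F0 must be positive (Bell rate undefined at F0 = 0)")
  stopifnot(all(F >= 0))
  k0 * exp(F / F0)
}

#' One stochastic actin-binding attempt
#'
#' Given candidate attachment points already filtered to within
#' `binding_distance` of the linker center, binding occurs with probability
#' `1 - exp(-k_bind * n_candidates * dt)` (the propensity is per candidate in
#' range, so the total rate scales with the local density of filament
#' material).  On success one candidate is chosen uniformly at random and an
#' actin link `(filament, abscissa)` is created.  Steps with
#' `k_bind * n * dt > 0.1` are subdivided internally.
#'
#' @param lk a [linker()] with a free actin site.
#' @param candidates data frame with columns `filament` (id) and `abscissa`
#'   (µm along that filament); zero rows means nothing in range.
#' @param params a [kinetic_params()].
#' @param dt time step (s).
#' @return the (possibly) updated linker.
#' @export
attempt_binding <- function(lk, candidates, params, dt) {
  stopifnot(inherits(lk, "linker"), dt > 0)
  n <- nrow(candidates)
  if (n == 0 || params$k_bind == 0 || .free_actin_sites(lk) == 0) return(lk)
  rate <- params$k_bind * n
  nsub <- max(1L, ceiling(rate * dt / 0.1))
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    if (stats::runif(1) < 1 - exp(-rate * h)) {
      pick <- if (n == 1) 1L else sample.int(n, 1)
      lk$actin_links <- rbind(lk$actin_links,
                              data.frame(filament = candidates$filament[pick],
                                         abscissa = candidates$abscissa[pick]))
      break
    }
  }
  lk
}

#' One stochastic force-sensitive unbinding attempt
#'
#' The link detaches with probability `1 - exp(-k_off * dt)` where
#' `k_off = k_unbind * exp(F / F0)` ([bell_rate()]).
#' @param tension link spring-force magnitude (pN), >= 0.
#' @param params a [kinetic_params()].
#' @param dt time step (s).
#' @param rate_name which zero-force rate to use: `"k_unbind"` (actin links)
#'   or `"k_split"` (partner bonds).
#' @return logical: `TRUE` if the link is removed.
#' @export
attempt_unbinding <- function(tension, params, dt, rate_name = "k_unbind") {
  k0 <- params[[rate_name]]
  if (k0 == 0) return(FALSE)
  koff <- bell_rate(k0, tension, params$F0)
  stats::runif(1) < 1 - exp(-koff * dt)
}

# union-find style reachability over partner bonds (chains are short)
.same_chain <- function(i, j, partners) {
  frontier <- i
  seen <- i
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(partners[frontier])), seen)
    if (j %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Stochastic multimer formation and splitting events
#'
#' Monomer-mode linkers within `binding_distance` of each other and with free
#' partner sites form a bond with probability `1 - exp(-k_form * dt)`;
#' existing bonds split with Bell-law probability driven by `k_split` and the
#' bond spring tension.  Events that would create a degree-3 node, a
#' self-bond, a duplicate bond, or close a chain into a cycle are rejected,
#' so the partner graph is always a disjoint union of simple paths.
#'
#' @param linkers list of monomer-mode [linker()] objects; `partner_links`
#'   holds indices into this list.
#' @param params a [kinetic_params()].
#' @param dt time step (s).
#' @return the updated list of linkers, with a `"rejected"` attribute
#'   counting silently rejected self/degree/cycle events.
#' @export
attempt_multimer_events <- function(linkers, params, dt) {
  n <- length(linkers)
  partners <- lapply(linkers, function(l) l$partner_links)
  rejected <- 0L
  # splitting first (so a freshly formed bond is not immediately retested)
  if (params$k_split > 0) {
    for (i in seq_len(n)) for (j in partners[[i]]) if (j > i) {
      d <- linkers[[i]]$position - linkers[[j]]$position
      tension <- params$link_stiffness * sqrt(sum(d^2))
      if (attempt_unbinding(tension, params, dt, "k_split")) {
        partners[[i]] <- setdiff(partners[[i]], j)
        partners[[j]] <- setdiff(partners[[j]], i)
      }
    }
  }
  # formation
  if (params$k_form > 0) {
    pos <- do.call(rbind, lapply(linkers, `[[`, "position"))
    for (i in seq_len(n)) {
      if (length(partners[[i]]) >= 2) next
      d2 <- rowSums((pos - matrix(pos[i, ], n, 3, byrow = TRUE))^2)
      cand <- which(d2 <= params$binding_distance^2)
      for (j in cand) {
        if (j == i) { rejected <- rejected + 1L; next }
        if (j < i) next                  # each unordered pair attempted once
        if (length(partners[[i]]) >= 2) break
        if (length(partners[[j]]) >= 2 || j %in% partners[[i]]) next
        if (.same_chain(i, j, partners)) { rejected <- rejected + 1L; next }
        if (stats::runif(1) < 1 - exp(-params$k_form * dt)) {
          partners[[i]] <- c(partners[[i]], j)
          partners[[j]] <- c(partners[[j]], i)
        }
      }
    }
  }
  for (i in seq_len(n)) linkers[[i]]$partner_links <- partners[[i]]
  attr(linkers, "rejected") <- rejected
  linkers
}

# point on a filament at arc-length abscissa s
.filament_point <- function(fil, s) {
  v <- fil$vertices
  n <- nrow(v)
  seg <- c(rep(fil$L_seg, n - 2), fil$partial)
  cs <- c(0, cumsum(seg))
  s <- min(max(s, 0), cs[n])
  j <- findInterval(s, cs, rightmost.closed = TRUE)
  j <- min(j, n - 1)
  w <- (s - cs[j]) / seg[j]
  list(point = v[j, ] + (v[j + 1, ] - v[j, ]) * w, index = j, weight = w)
}

#' Hookean link forces between linkers, filaments and partner linkers
#'
#' Each actin link pulls the linker toward its attachment point with force
#' `link_stiffness * (filament_point - linker_center)`; the reaction on the
#' filament is distributed to the two flanking vertices by linear
#' interpolation of the abscissa.  Partner bonds act likewise between linker
#' centers.  Links whose abscissa lies beyond the filament end are dropped
#' and reported.
#'
#' @param linkers list of [linker()]s (`actin_links$filament` indexes into
#'   `filaments`, `partner_links` into `linkers`).
#' @param filaments list of [filament()]s.
#' @param params a [kinetic_params()].
#' @return list with `linker_forces` (m x 3), `filament_forces` (list of
#'   n x 3 matrices), `tensions` (data frame per actin link: linker, filament,
#'   abscissa, tension), and `dropped` (count of dangling links removed).
#' @export
link_forces <- function(linkers, filaments, params) {
  m <- length(linkers)
  lf <- matrix(0, m, 3)
  ff <- lapply(filaments, function(f) matrix(0, nrow(f$vertices), 3))
  tens <- list()
  dropped <- 0L
  for (i in seq_len(m)) {
    lk <- linkers[[i]]
    keep <- rep(TRUE, nrow(lk$actin_links))
    for (r in seq_len(nrow(lk$actin_links))) {
      fid <- lk$actin_links$filament[r]
      s <- lk$actin_links$abscissa[r]
      fil <- filaments[[fid]]
      if (s > filament_length(fil) + 1e-9) {
        keep[r] <- FALSE; dropped <- dropped + 1L; next
      }
      fp <- .filament_point(fil, s)
      dvec <- fp$point - lk$position
      f <- params$link_stiffness * dvec
      lf[i, ] <- lf[i, ] + f
      ff[[fid]][fp$index, ] <- ff[[fid]][fp$index, ] - f * (1 - fp$weight)
      ff[[fid]][fp$index + 1, ] <- ff[[fid]][fp$index + 1, ] - f * fp$weight
      tens[[length(tens) + 1]] <-
        data.frame(linker = i, filament = fid, abscissa = s,
                   tension = params$link_stiffness * sqrt(sum(dvec^2)))
    }
    if (!all(keep)) linkers[[i]]$actin_links <- lk$actin_links[keep, ]
    for (j in lk$partner_links) if (j > i) {
      f <- params$link_stiffness * (linkers[[j]]$position - lk$position)
      lf[i, ] <- lf[i, ] + f
      lf[j, ] <- lf[j, ] - f
    }
  }
  list(linker_forces = lf, filament_forces = ff,
       tensions = if (length(tens)) do.call(rbind, tens) else
         data.frame(linker = integer(0), filament = integer(0),
                    abscissa = numeric(0), tension = numeric(0)),
       dropped = dropped)
}

#' Kinetic state label of a crosslinker
#'
#' Tetramers occupy one of five states, `"0-bound"` ... `"4-bound"`, counting
#' bound actin filaments.  Monomers occupy one of six states combining the
#' number of bound partners (0, 1, 2) with actin occupancy (`B` bound, `F`
#' free): `"0F", "0B", "1F", "1B", "2F", "2B"`.
#'
#' @param lk a [linker()].
#' @return character state label.
#' @export
classify_state <- function(lk) {
  na <- nrow(lk$actin_links)
  if (lk$mode == "tetramer") {
    if (na < 0 || na > 4 || length(lk$partner_links) > 0)
      stop("inconsistent tetramer link counts")
    return(paste0(na, "-bound"))
  }
  np <- length(lk$partner_links)
  if (na > 1 || np > 2) stop("inconsistent monomer link counts")
  paste0(np, if (na == 1) "B" else "F")
}

#' All reachable states of a linker mode
#' @param mode `"tetramer"` or `"monomer"`.
#' @return character vector of state labels (length 5 or 6).
#' @export
linker_state_space <- function(mode = c("tetramer", "monomer")) {
  mode <- match.arg(mode)
  if (mode == "tetramer") paste0(0:4, "-bound")
  else as.vector(outer(0:2, c("F", "B"), paste0))
}
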