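# shared helpers: geometric chains and tiny engine states

# discrete circular arc in the xy plane: n_seg segments subtending
# `angle_per_seg` radians each on a circle of radius R
make_arc <- function(R = 1, angle_per_seg = 0.1, n_seg = 63, k_bend = 0.075) {
  th <- seq(0, n_seg) * angle_per_seg
  v <- cbind(R * cos(th), R * sin(th), 0)
  filament_from_vertices(v, k_bend = k_bend)
}

# random mildly-bent open chain with equal segment lengths
make_wiggly_chain <- function(n = 10, L = 0.1, sd = 0.2, seed = 1) {
  set.seed(seed)
  v <- matrix(0, n, 3)
  d <- c(1, 0, 0)
  for (i in 2:n) {
    d <- d + rnorm(3, 0, sd)
    d <- d / sqrt(sum(d^2))
    v[i, ] <- v[i - 1, ] + d * L
  }
  filament_from_vertices(v)
}

# minimal engine state around explicit geometry
make_state <- function(fils = list(), linker_pos = matrix(0, 0, 3),
                       actin_links = matrix(0, 0, 3),
                       partner_links = matrix(0, 0, 2),
                       semi_axes = c(1, 1, 1)) {
  list(fil_vertices = lapply(fils, function(f) f$vertices),
       fil_partial = vapply(fils, function(f) f$partial, numeric(1)),
       fil_capped = vapply(fils, function(f) f$capped, logical(1)),
       linker_pos = linker_pos,
       actin_links = actin_links,
       partner_links = partner_links,
       semi_axes = semi_axes)
}
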