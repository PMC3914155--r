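# Small shared fixtures, built in code.

tiny_grid <- function(counts = c(3L, 3L, 3L), d = 100, guard = c(0L, 0L, 0L)) {
  build_grid(c(0, 0, 0), counts, d, guard = guard)
}

# a small random electrode/grid system in the cortical depth range,
# suitable for both InfH and SphIh conductors
small_system <- function(n_e = 8L, counts = c(3L, 3L, 3L), d = 100,
                         seed = 11L) {
  set.seed(seed)
  grid <- build_grid(c(-100, -100, 600), counts, d, guard = c(0L, 0L, 0L))
  pos <- cbind(
    x = runif(n_e, -150, 150),
    y = runif(n_e, -150, 150),
    z = runif(n_e, 550, 950)
  )
  # keep electrodes clear of grid nodes
  repeat {
    D2 <- outer(pos[, 1], grid$x, "-")^2 + outer(pos[, 2], grid$y, "-")^2 +
      outer(pos[, 3], grid$z, "-")^2
    bad <- unique(which(D2 < (d / 8)^2, arr.ind = TRUE)[, 1])
    if (!length(bad)) break
    pos[bad, ] <- pos[bad, ] + 13
  }
  list(array = electrode_array(pos), grid = grid)
}

# an isotropic shell profile (SphIh reduces to InfH with this)
iso_shells <- function(sigma = 0.3) {
  sh <- default_sphih_shells()
  sh$sigma_radial <- sigma
  sh$sigma_tangential <- sigma
  sh
}

# registered sphere coordinates used by the default profile (pia at 4000 um)
register_pt <- function(p, R = 4000) {
  r <- R - p[3]
  c(p[1], p[2], sqrt(r^2 - p[1]^2 - p[2]^2))
}
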