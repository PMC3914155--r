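test_that("the sinusoidal phantom evaluates its defining expression", {
  g <- build_grid(c(-200, -200, 0), c(9L, 9L, 21L), d = 50,
                  guard = c(0L, 0L, 0L))
  ph <- sinusoidal_phantom(g, z0 = 500, period = 400, width = 100)
  at <- function(x, y, z) {
    as.numeric(ph$csd)[which(g$x == x & g$y == y & g$z == z)]
  }
  expect_equal(at(0, 0, 500), 0)                     # sin(0) at the center
  expect_equal(at(0, 0, 600), 1)                     # quarter period on axis
  expect_equal(at(100, 100, 600), exp(-1))           # x^2 + y^2 = 2 l^2
  expect_equal(at(0, 0, 600), -at(0, 0, 400))        # odd in depth
  expect_equal(at(-150, 50, 450), -at(-150, 50, 550))
  # support limited to one axial period
  expect_equal(at(0, 0, 800), 0)
  expect_true(all(as.numeric(ph$csd)[abs(g$z - 500) >= 200] == 0))
})

test_that("the Gaussian phantom is unit-peak, /(2 l^2) convention, unbalanced", {
  g <- build_grid(c(-200, -200, 0), c(9L, 9L, 9L), d = 50,
                  guard = c(0L, 0L, 0L))
  ph <- gaussian_phantom(g, center = c(0, 0, 200), width = 100)
  v <- as.numeric(ph$csd)
  expect_equal(v[which(g$x == 0 & g$y == 0 & g$z == 200)], 1)
  # distance sqrt(2) l from the center decays to 1/e
  i <- which(g$x == 100 & g$y == 100 & g$z == 200)
  expect_equal(v[i], exp(-1))
  # total charge is strictly positive: unbalanced by construction
  expect_gt(sum(v) * (50e-6)^3, 0)
  expect_true(all(v > 0))
})

test_that("noise is scaled to the spatial sample variance and seeded", {
  set.seed(900)
  phi <- rnorm(64) * 1e-3
  expect_identical(add_noise(phi, 0), phi)
  n1 <- add_noise(phi, 0.1, seed = 7)
  n2 <- add_noise(phi, 0.1, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(add_noise(phi, 0.1, seed = 8), n1))
  # empirical variance of the added noise over many draws
  set.seed(901)
  draws <- replicate(10000 %/% 64 + 1, add_noise(phi, 0.5) - phi)
  expect_lt(abs(stats::var(as.vector(draws)) / (0.5 * stats::var(phi)) - 1),
            0.05)
  expect_error(add_noise(rep(1, 10), 0.1), class = "vcsd_degenerate_input")
})

test_that("reconstruction error has its defining fixed points", {
  g <- tiny_grid(c(2L, 2L, 2L), d = 50)
  truth <- csd_volume(g, c(1, 0, 0, 0, 0, 0, 0, 0))
  est0 <- csd_volume(g, rep(0, 8))
  swap <- csd_volume(g, c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(reconstruction_error(truth, truth), 0)
  expect_equal(reconstruction_error(truth, est0), 1)
  expect_equal(reconstruction_error(truth, swap), 2)  # (1,0) vs (0,1)
  # invariant to joint rescaling; not symmetric in its arguments
  t2 <- csd_volume(g, 5 * as.numeric(truth$csd))
  s2 <- csd_volume(g, 5 * as.numeric(swap$csd))
  expect_equal(reconstruction_error(t2, s2), 2)
  half <- csd_volume(g, as.numeric(truth$csd) / 2)
  expect_false(isTRUE(all.equal(reconstruction_error(truth, half),
                                reconstruction_error(half, truth))))
  expect_error(reconstruction_error(est0, truth), class = "vcsd_zero_energy")
})

test_that("reconstruction error ignores guard nodes", {
  g <- build_grid(c(0, 0, 0), c(8L, 8L, 6L), d = 50, guard = c(1L, 1L, 1L))
  v <- rep(1, nrow(g))
  truth <- csd_volume(g, v)
  est <- v
  est[g$guard] <- 99  # wildly wrong on guards only
  expect_equal(reconstruction_error(truth, csd_volume(g, est)), 0)
})

test_that("phantom generators are deterministic given their spec", {
  g <- tiny_grid(c(4L, 4L, 4L), d = 50)
  a <- sinusoidal_phantom(g, z0 = 100, period = 300, width = 80)
  b <- sinusoidal_phantom(g, z0 = 100, period = 300, width = 80)
  expect_identical(a$csd, b$csd)
})

test_that("a reduced mismatch experiment shows the matched-model advantage", {
  res <- run_model_mismatch_experiment(
    trials = 1, seed = 99,
    grid_counts = c(10L, 10L, 12L), d = 50,
    array = lattice_array(c(5L, 5L, 6L), pitch = 100, origin = c(-215, -215, 475)),
    widths = c(small = 120), periods = c(small = 400))
  expect_equal(nrow(res), 4L)
  wide <- tidyr::pivot_wider(res, names_from = "inverse_model",
                             values_from = "re",
                             id_cols = c("trial", "kind"))
  expect_true(all(wide$sphih <= wide$infh))
})
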