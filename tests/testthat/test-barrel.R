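make_plane <- function(values, nx = NULL) {
  n <- length(values)
  if (is.null(nx)) nx <- round(sqrt(n))
  ny <- n / nx
  structure(tibble::tibble(
    ix = rep(seq_len(nx), times = ny),
    iy = rep(seq_len(ny), each = nx),
    x = rep(seq_len(nx), times = ny) * 50,
    y = rep(seq_len(ny), each = nx) * 50,
    value = as.numeric(values)
  ), plane_index = 5L, nx = nx, ny = ny,
  class = c("csd_plane", class(tibble::tibble())))
}

test_that("plane extraction keeps non-guard nodes and the right values", {
  g <- build_grid(c(0, 0, 0), c(30L, 30L, 28L), d = 50)  # 3/3/2 guards
  vals <- seq_len(nrow(g))
  csd <- csd_volume(g, vals)
  pl <- extract_layer4_plane(csd, 12L)
  expect_equal(nrow(pl), 24L * 24L)
  # spot-check: plane values equal the 3D entries at those nodes
  j <- node_index(g, 10L, 17L, 12L)
  expect_equal(pl$value[pl$ix == 10 & pl$iy == 17], vals[j])
  # guard planes are rejected
  expect_error(extract_layer4_plane(csd, 2L), class = "vcsd_invalid_argument")
  expect_error(extract_layer4_plane(csd, 27L), class = "vcsd_invalid_argument")
  # symmetric phantom: two planes flanking the center are equal
  ph <- gaussian_phantom(g, center = c(750, 750, 675), width = 200)
  p1 <- extract_layer4_plane(ph, 13L)  # z = 600
  p2 <- extract_layer4_plane(ph, 16L)  # z = 750, mirror about 675
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("normalization scales the maximum to one and is scale invariant", {
  pl <- make_plane(c(2, -1, 0.5, 1))
  n1 <- normalize_csd_plane(pl)
  expect_equal(n1$value, c(1, -0.5, 0.25, 0.5))
  already <- normalize_csd_plane(n1)
  expect_equal(already$value, n1$value)
  pl7 <- make_plane(7 * c(2, -1, 0.5, 1))
  expect_equal(normalize_csd_plane(pl7)$value, n1$value)
  expect_error(normalize_csd_plane(make_plane(c(-1, -2, -0.5, -3))),
               class = "vcsd_sign_convention")
})

test_that("thresholding implements f_k = 1 iff value >= alpha", {
  pl <- make_plane(c(1, 0.4, 0.6, -0.2))
  expect_equal(threshold_barrel(pl, 0.5)$mask, c(1L, 0L, 1L, 0L))
  expect_equal(threshold_barrel(pl, 0)$mask, c(1L, 1L, 1L, 0L))
  expect_error(threshold_barrel(pl, 1.0001), "\\[0, 1\\]")
})

test_that("area matching picks the exact threshold; brute force agrees", {
  # anatomical area 3 on a 3x3 plane with distinct values: top-3 selected
  set.seed(33)
  v <- sample(seq(0.1, 0.9, length.out = 9))
  pl <- normalize_csd_plane(make_plane(v, nx = 3))
  A <- barrel_mask(pl, as.integer(seq_len(9) %in% c(1, 5, 7)))
  fb <- select_alpha(pl, A)
  expect_equal(which(fb$mask == 1L), which(rank(-pl$value) <= 3))
  # plane equal to the mask itself reproduces the mask exactly
  plA <- make_plane(as.numeric(A$mask), nx = 3)
  fb2 <- select_alpha(plA, A)
  expect_equal(fb2$mask, A$mask)
  expect_equal(localization_error(A, fb2), 0)
  # brute-force enumeration over a dense alpha grid on small random planes
  for (s in 1:5) {
    set.seed(s)
    v <- round(runif(36), 2)
    pl <- normalize_csd_plane(make_plane(v, nx = 6))
    A <- barrel_mask(pl, as.integer(runif(36) < 0.3))
    if (sum(A$mask) == 0) next
    fb <- select_alpha(pl, A)
    target <- sum(A$mask)
    best_bf <- min(vapply(seq(0, 1, by = 1e-3), function(a) {
      abs(target - sum(pl$value >= a))
    }, numeric(1)))
    expect_equal(abs(target - sum(fb$mask)), best_bf)
  }
  expect_error(select_alpha(pl, barrel_mask(pl, rep(0L, 36))), "empty")
})

test_that("localization error is the printed 2-norm ratio", {
  pl <- make_plane(numeric(16))
  A <- barrel_mask(pl, as.integer(seq_len(16) %in% 1:4))
  # perfect match
  f_perfect <- barrel_mask(pl, A$mask)
  expect_equal(localization_error(A, f_perfect), 0)
  # 3 of 4 matched plus 1 false positive: two mismatches, ||A|| = 2
  f_part <- barrel_mask(pl, as.integer(seq_len(16) %in% c(1, 2, 3, 9)))
  expect_equal(localization_error(A, f_part), sqrt(2) / 2)
  # disjoint with equal area: sqrt(2), beyond the nominal [0, 1] range
  f_disj <- barrel_mask(pl, as.integer(seq_len(16) %in% 5:8))
  expect_equal(localization_error(A, f_disj), sqrt(2))
  expect_error(localization_error(barrel_mask(pl, rep(0L, 16)), f_disj),
               class = "vcsd_zero_energy")
})

test_that("barrel phantoms have area-consistent masks and distinct centers differ", {
  g <- build_grid(c(-725, -725, 225), c(30L, 30L, 28L), d = 50)
  ph <- synthesize_barrel_phantom(g, c(0, 0), 200, c(700, 900))
  plane_nodes <- dplyr::filter(g, !guard, iz == ph$plane_index)
  expect_equal(sum(ph$mask$mask),
               sum(sqrt(plane_nodes$x^2 + plane_nodes$y^2) <= 200))
  # sink is negative and confined to the cylinder and band
  v <- as.numeric(ph$csd$csd)
  expect_true(all(v <= 0))
  nz <- v != 0
  expect_true(all(sqrt(g$x[nz]^2 + g$y[nz]^2) <= 200))
  expect_true(all(g$z[nz] >= 700 & g$z[nz] <= 900))
  ph2 <- synthesize_barrel_phantom(g, c(200, -150), 200, c(700, 900))
  expect_false(identical(ph$mask$mask, ph2$mask$mask))
  expect_error(
    synthesize_barrel_phantom(g, c(500, 0), 200, c(700, 900)),
    "outside the non-guard plane")
})

test_that("a noiseless end-to-end localization beats the disjoint-barrel bound", {
  arr <- mea_layout("array128")
  g <- grid_centered_on(arr, c(20L, 20L, 20L), 70)
  m <- default_sphih()
  ph <- synthesize_barrel_phantom(g, c(0, 0), 250, c(650, 950))
  lf <- assemble_leadfield(arr, g, m)
  fit <- fit_vcsd(lf, forward_potentials(lf, ph$csd))
  loc <- localize_barrel(fit$csd, ph$mask)
  expect_lt(loc$error, sqrt(2))
  expect_gte(attr(loc$functional, "alpha_star"), 0)
})
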