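test_that("the Laplacian has the printed structure, literally on the boundary", {
  g <- tiny_grid(c(3L, 3L, 3L), d = 50)
  L <- build_laplacian(g)$matrix
  expect_true(Matrix::isSymmetric(L))
  expect_equal(unique(Matrix::diag(L)), -6 / 50^2)
  rs <- Matrix::rowSums(L)
  expect_equal(rs[node_index(g, 2, 2, 2)], 0)            # interior row
  expect_equal(rs[node_index(g, 1, 1, 1)], -3 / 50^2)    # corner row
  # full 2x2x2 grid: every node has exactly 3 face-adjacent partners
  g2 <- tiny_grid(c(2L, 2L, 2L), d = 10)
  L2 <- as.matrix(build_laplacian(g2)$matrix)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) {
    ref[i, i] <- -6 / 100
    ref[i, neighbor_indices(g2, i)] <- (6 / 100) * (1 / 6)
  }
  expect_equal(L2, ref)
})

test_that("Laplacian sparsity equals the face-adjacency graph", {
  for (counts in list(c(2L, 2L, 3L), c(4L, 3L, 2L), c(4L, 4L, 4L))) {
    g <- tiny_grid(counts, d = 20)
    L <- as.matrix(build_laplacian(g)$matrix)
    for (j in g$node) {
      expect_equal(sort(setdiff(which(L[j, ] != 0), j)),
                   sort(neighbor_indices(g, j)))
    }
  }
})

test_that("solve_vcsd matches the dense normal-equations transcription", {
  sys <- small_system(n_e = 10L, counts = c(2L, 3L, 4L), seed = 21L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  lap <- build_laplacian(sys$grid)
  set.seed(22)
  phi <- rnorm(10) * 1e-4
  d_m <- 100 * 1e-6
  G <- lf$matrix * d_m^3
  L <- as.matrix(lap$matrix)
  for (lam in c(1e-3, 1) * sum(G^2) / sum(diag(crossprod(L)))) {
    dense <- solve(crossprod(G) + lam * crossprod(L), crossprod(G, phi))
    est <- solve_vcsd(lf, phi, lap, lambda = lam)
    expect_lt(max(abs(est$csd - drop(dense))) / max(abs(dense)), 1e-8)
    expect_equal(attr(est, "lambda_used"), lam)
  }
  # zero data gives a zero estimate
  z <- solve_vcsd(lf, rep(0, 10), lap, lambda = 1e-3)
  expect_equal(unname(as.numeric(z$csd)), rep(0, 24))
  # lambda = 0 with M >> N is rejected as rank deficient
  expect_error(solve_vcsd(lf, phi, lap, lambda = 0),
               class = "vcsd_rank_deficiency")
})

test_that("solutions shrink monotonically as lambda grows large", {
  sys <- small_system(n_e = 10L, counts = c(2L, 3L, 4L), seed = 31L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  lap <- build_laplacian(sys$grid)
  op <- vcsd_operator(lf, lap)
  set.seed(32)
  phi <- rnorm(10) * 1e-4
  lams <- op$lambda_scale * 10^seq(-2, 12, by = 2)
  norms <- vapply(lams, function(l) {
    sqrt(sum(solve_vcsd(potentials = phi, lambda = l, operator = op)$csd^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)] / norms[1], 1e-6)
})

test_that("solve_vcsd is invariant under joint electrode permutation", {
  sys <- small_system(n_e = 9L, counts = c(3L, 2L, 3L), seed = 41L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  lap <- build_laplacian(sys$grid)
  set.seed(42)
  phi <- rnorm(9) * 1e-4
  est <- solve_vcsd(lf, phi, lap, lambda = 1e-2 * vcsd_operator(lf, lap)$lambda_scale)
  perm <- sample(9)
  pos <- cbind(sys$array$x, sys$array$y, sys$array$z)[perm, ]
  lf2 <- assemble_leadfield(electrode_array(pos), sys$grid, conductor_infh(0.3))
  est2 <- solve_vcsd(lf2, phi[perm], lap,
                     lambda = attr(est, "lambda_used"))
  expect_lt(max(abs(est$csd - est2$csd)) / max(abs(est$csd)), 1e-8)
})

test_that("gcv_objective matches its dense transcription and scales as c^2", {
  sys <- small_system(n_e = 8L, counts = c(3L, 3L, 3L), seed = 51L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  lap <- build_laplacian(sys$grid)
  set.seed(52)
  phi <- rnorm(8) * 1e-4
  d_m <- 100e-6
  G <- lf$matrix * d_m^3
  L <- as.matrix(lap$matrix)
  lam <- 0.37 * sum(G^2) / sum(diag(crossprod(L)))
  P <- diag(8) - G %*% solve(crossprod(G) + lam * crossprod(L), t(G))
  dense <- sum((P %*% phi)^2) / sum(diag(P))^2
  expect_equal(gcv_objective(lf, phi, lap, lam), dense, tolerance = 1e-8)
  # homogeneity of degree 2 in the data; zero data scores zero
  expect_equal(gcv_objective(lf, 3 * phi, lap, lam), 9 * dense,
               tolerance = 1e-8)
  expect_equal(gcv_objective(lf, rep(0, 8), lap, lam), 0)
})

test_that("GCV scores stay finite over a very wide lambda range", {
  sys <- small_system(n_e = 8L, seed = 61L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  op <- vcsd_operator(lf)
  set.seed(62)
  phi <- rnorm(8) * 1e-4
  lams <- op$lambda_scale * 10^seq(-12, 6, length.out = 60)
  sc <- gcv_objective(potentials = phi, lambda = lams, operator = op)
  expect_true(all(is.finite(sc)))
  expect_true(all(sc >= 0))
})

test_that("select_lambda returns the score minimizer, ties toward larger", {
  sys <- small_system(n_e = 8L, seed = 71L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  op <- vcsd_operator(lf)
  set.seed(72)
  phi <- rnorm(8) * 1e-4
  sel <- select_lambda(potentials = phi, operator = op)
  expect_equal(min(sel$scores$score),
               sel$scores$score[sel$scores$lambda == sel$lambda])
  # single-element grid returns that element
  one <- select_lambda(potentials = phi, lambda_grid = 0.5, operator = op)
  expect_equal(one$lambda, 0.5)
})

test_that("GCV picks a larger lambda under heavier noise (median over seeds)", {
  sys <- small_system(n_e = 12L, counts = c(4L, 4L, 4L), seed = 81L)
  lf <- assemble_leadfield(sys$array, sys$grid, conductor_infh(0.3))
  op <- vcsd_operator(lf)
  g <- sys$grid
  truth <- gaussian_phantom(g, c(mean(g$x), mean(g$y), mean(g$z)), width = 150)
  phi0 <- forward_potentials(lf, truth)
  pick <- function(beta, seed) {
    phi <- add_noise(phi0, beta, seed = seed)
    select_lambda(potentials = phi, operator = op)$lambda
  }
  lam_lo <- vapply(1:20, function(s) pick(0.01, s), numeric(1))
  lam_hi <- vapply(1:20, function(s) pick(0.5, 100 + s), numeric(1))
  expect_gte(median(lam_hi), median(lam_lo))
})

test_that("the iCSD3D baseline recovers a CSD supported on one basis element", {
  arr <- lattice_array(c(3L, 3L, 3L), pitch = 200, origin = c(0, 0, 400))
  # grid nodes offset by half a spacing so none sits on a cube boundary
  g <- build_grid(c(-150, -150, 350), c(7L, 7L, 7L), d = 100,
                  guard = c(0L, 0L, 0L))
  # potentials generated from the step-basis forward matrix itself
  FF <- vcsd:::icsd_forward_matrix(arr, 0.3, 200, 4L)
  target <- 14L  # center electrode cube
  phi <- FF[, target]
  est <- solve_icsd3d(arr, phi, 0.3, g, interpolation = "step")
  # nodes inside the target cube carry 1, all others 0
  inside <- abs(g$x - arr$x[target]) < 100 &
    abs(g$y - arr$y[target]) < 100 & abs(g$z - arr$z[target]) < 100
  expect_equal(unname(as.numeric(est$csd)[inside]),
               rep(1, sum(inside)), tolerance = 1e-8)
  expect_equal(max(abs(as.numeric(est$csd)[!inside])), 0, tolerance = 1e-8)
  # zero potentials give zero CSD
  z <- solve_icsd3d(arr, rep(0, 27), 0.3, g)
  expect_equal(max(abs(z$csd)), 0)
  # non-lattice arrays are rejected
  bad <- electrode_array(cbind(runif(8), runif(8), runif(8) + 300))
  expect_error(solve_icsd3d(bad, rnorm(8), 0.3, g), "lattice")
})

test_that("trilinear extension interpolates between electrode values", {
  arr <- lattice_array(c(3L, 3L, 3L), pitch = 200, origin = c(0, 0, 400))
  g <- build_grid(c(0, 0, 400), c(5L, 5L, 5L), d = 100, guard = c(0L, 0L, 0L))
  FF <- vcsd:::icsd_forward_matrix(arr, 0.3, 200, 4L)
  cc <- seq_len(27) / 27
  est <- solve_icsd3d(arr, drop(FF %*% cc), 0.3, g, interpolation = "trilinear")
  # at electrode positions the interpolant equals the solved coefficients
  at_e <- match(
    paste(arr$x, arr$y, arr$z),
    paste(g$x, g$y, g$z))
  have <- !is.na(at_e)
  expect_equal(as.numeric(est$csd)[at_e[have]], cc[have], tolerance = 1e-6)
})
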