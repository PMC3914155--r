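#' Phantom CSD distributions
#'
#' Synthetic ground-truth CSD volumes used by the validation experiments.
#'
#' `sinusoidal_phantom()` is charge-balanced: a sinusoid along depth
#' weighted by a tangential Gaussian,
#' `C = sin(2 pi (z - z0) / T) exp(-(x^2 + y^2) / (2 l^2))` for
#' `|z - z0| < T / 2` and zero outside one axial period.
#'
#' `gaussian_phantom()` is charge-unbalanced: a pure Gaussian
#' `C = exp(-||r - r0||^2 / (2 l^2))`. With `center = c(x_c, y_c, z0)` at
#' the grid's tangential center this is the separable tangential/depth
#' form; a general center gives the isotropic form used in the noise
#' sweeps. (`l` enters as a Gaussian width parameter throughout.)
#'
#' @param grid a [build_grid()] source grid.
#' @param z0 phantom center depth (micrometers).
#' @param period axial period `T` of the sinusoid (micrometers).
#' @param width Gaussian width parameter `l` (micrometers).
#' @param amplitude peak amplitude (arbitrary CSD units).
#' @param center_xy tangential center; defaults to the grid center.
#' @return A [csd_volume()] with `method = "phantom"`.
#' @export
sinusoidal_phantom <- function(grid, z0, period, width, amplitude = 1,
                               center_xy = NULL) {
  stopifnot(inherits(grid, "source_grid"), period > 0, width > 0)
  if (is.null(center_xy)) {
    center_xy <- c(mean(range(grid$x)), mean(range(grid$y)))
  }
  dz <- grid$z - z0
  vals <- ifelse(
    abs(dz) < period / 2,
    amplitude * sin(2 * pi * dz / period) *
      exp(-((grid$x - center_xy[1])^2 + (grid$y - center_xy[2])^2) /
            (2 * width^2)),
    0
  )
  csd_volume(grid, vals, method = "phantom")
}

#' @rdname sinusoidal_phantom
#' @param center 3D phantom center `(x, y, z)` in micrometers.
#' @export
gaussian_phantom <- function(grid, center, width, amplitude = 1) {
  stopifnot(inherits(grid, "source_grid"), width > 0, length(center) == 3L)
  r2 <- (grid$x - center[1])^2 + (grid$y - center[2])^2 +
    (grid$z - center[3])^2
  csd_volume(grid, amplitude * exp(-r2 / (2 * width^2)), method = "phantom")
}

#' Add channel noise scaled to the signal's spatial variance
#'
#' Adds i.i.d. zero-mean Gaussian noise to each channel with variance
#' `sigma^2 = beta * var(Phi)`, where `var(Phi)` is the sample variance of
#' the potentials across the N channels at that time instant; `beta` is the
#' noise level (0.01-0.5 in the validation sweeps). Draws are independent
#' per channel and per time instant and deterministic given `seed`.
#'
#' @param potentials numeric N-vector or N x T matrix.
#' @param beta nonnegative noise level.
#' @param seed optional integer seed for reproducible noise.
#' @return Noisy potentials, same shape as the input.
#' @export
add_noise <- function(potentials, beta, seed = NULL) {
  stopifnot(beta >= 0)
  if (beta == 0) return(potentials)
  phi <- as.matrix(potentials)
  if (nrow(phi) < 2L) stop("need at least 2 channels", call. = FALSE)
  v <- apply(phi, 2, stats::var)
  if (any(v == 0)) {
    rlang::abort("potentials have zero variance across channels; noise level undefined",
                 class = "vcsd_degenerate_input")
  }
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(stats::rnorm(length(phi)), nrow(phi)) *
    rep(sqrt(beta * v), each = nrow(phi))
  out <- phi + noise
  if (is.null(dim(potentials))) drop(out) else out
}

#' Reconstruction error between a true and an estimated CSD
#'
#' `RE = sum_j (C_j - C_hat_j)^2 / sum_j C_j^2`, summed over non-guard
#' nodes only. Zero iff the estimate equals the truth on the reported
#' volume; an all-zero estimate gives exactly 1. The measure is normalized
#' by the truth's energy and is therefore not symmetric in its arguments.
#'
#' @param truth,estimate [csd_volume()] objects on the same grid (single
#'   time instant).
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(truth, estimate) {
  stopifnot(inherits(truth, "csd_volume"), inherits(estimate, "csd_volume"))
  if (!identical(grid_counts(truth), grid_counts(estimate)) ||
      !identical(grid_spacing(truth), grid_spacing(estimate))) {
    stop("truth and estimate must share the same grid", call. = FALSE)
  }
  keep <- !truth$guard
  ct <- as.numeric(truth$csd)[keep]
  ce <- as.numeric(estimate$csd)[keep]
  den <- sum(ct^2)
  if (den == 0) {
    rlang::abort("truth has zero energy on non-guard nodes",
                 class = "vcsd_zero_energy")
  }
  sum((ct - ce)^2) / den
}

# homogeneous sigma matched to a shell profile: mean effective conductivity
infh_sigma_from <- function(conductor) {
  mean(sqrt(conductor$shells$sigma_radial * conductor$shells$sigma_tangential))
}

#' Volume-conductor mismatch experiment
#'
#' Quantifies the cost of inverting with a misspecified volume conductor.
#' Per trial, a charge-balanced (sinusoidal) and a charge-unbalanced
#' (Gaussian) phantom — each at a small and a large source size — is placed
#' at a random depth along the lamina, forward-projected through the
#' layered-sphere (SphIh) conductor onto the dense simulation array, and
#' inverted (GCV-selected lambda) twice: with the matched SphIh lead field
#' and with an infinite-homogeneous (InfH) one. Reconstruction error is
#' recorded per condition.
#'
#' Defaults reproduce the validation design: `sim_9x9x15` array at 100 um
#' pitch, 16 x 16 x 28 grid at `d = 50` um, 10 trials with phantom centers
#' uniform over the middle two-thirds of the grid's depth extent.
#'
#' @param trials number of phantom placements.
#' @param seed integer seed controlling phantom depths.
#' @param conductor a [conductor_sphih()] used for the forward projection
#'   and the matched inversion.
#' @param widths named vector: Gaussian width `l` (um) for the small and
#'   large source sizes.
#' @param periods named vector: sinusoid period `T` (um) per source size.
#' @param grid_counts,d source-grid dimensions and spacing (um).
#' @param array the observing [electrode_array()].
#' @param infh_sigma homogeneous conductivity for the mismatched inversion;
#'   `"auto"` uses the mean effective shell conductivity.
#' @param lambda_grid optional lambda search grid.
#' @param cache_dir optional directory for lead-field caches.
#' @return A tibble with columns `trial`, `kind`, `size`, `inverse_model`,
#'   `lambda`, `re`.
#' @export
run_model_mismatch_experiment <- function(
    trials = 10L, seed = 1L,
    conductor = default_sphih(),
    widths = c(small = 150, large = 300),
    periods = c(small = 500, large = 1000),
    grid_counts = c(16L, 16L, 28L), d = 50,
    array = mea_layout("sim_9x9x15"),
    infh_sigma = "auto",
    lambda_grid = NULL,
    cache_dir = NULL) {
  stopifnot(trials >= 1L)
  if (identical(infh_sigma, "auto")) infh_sigma <- infh_sigma_from(conductor)
  grid <- grid_centered_on(array, grid_counts, d)
  lf_sph <- maybe_cached_leadfield(array, grid, conductor, cache_dir, "sphih")
  lf_inf <- maybe_cached_leadfield(array, grid, conductor_infh(infh_sigma),
                                   cache_dir, "infh")
  lap <- build_laplacian(grid)
  ops <- list(sphih = vcsd_operator(lf_sph, lap),
              infh = vcsd_operator(lf_inf, lap))
  zr <- range(grid$z)
  span <- diff(zr)
  set.seed(seed)
  z0s <- stats::runif(trials, zr[1] + span / 6, zr[2] - span / 6)
  grids_xy <- c(mean(range(grid$x)), mean(range(grid$y)))
  rows <- list()
  for (tr in seq_len(trials)) {
    for (size in names(widths)) {
      phs <- list(
        sinusoidal = sinusoidal_phantom(grid, z0 = z0s[tr],
                                        period = periods[[size]],
                                        width = widths[[size]]),
        gaussian = gaussian_phantom(grid,
                                    center = c(grids_xy, z0s[tr]),
                                    width = widths[[size]])
      )
      for (kind in names(phs)) {
        phi <- forward_potentials(lf_sph, phs[[kind]])
        for (inv in names(ops)) {
          fit <- fit_vcsd(potentials = phi, operator = ops[[inv]],
                          lambda_grid = lambda_grid)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            trial = tr, kind = kind, size = size, inverse_model = inv,
            lambda = fit$lambda,
            re = reconstruction_error(phs[[kind]], fit$csd)
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

maybe_cached_leadfield <- function(array, grid, model, cache_dir, tag) {
  if (is.null(cache_dir)) return(assemble_leadfield(array, grid, model))
  assemble_leadfield_cached(array, grid, model,
                            file.path(cache_dir, paste0("leadfield_", tag, ".rds")))
}

#' Noise level by electrode pitch sweep
#'
#' Compares the regularized vCSD inverse against the unregularized iCSD3D
#' baseline across noise levels and array resolutions. Per cell, isotropic
#' Gaussian phantoms (`l = 400` um) centered uniformly in the non-guard ROI
#' of a 24 x 24 x 24, `d = 50` um grid are forward-projected through an
#' infinite homogeneous conductor onto a 4 x 4 x 8 lattice array at the
#' given pitch; channel noise at level `beta` is added, and both methods
#' (vCSD with GCV lambda, iCSD3D with step interpolation) are scored by
#' reconstruction error. Forward and inverse both use the InfH model, so
#' the comparison isolates noise sensitivity from conductor mismatch.
#'
#' @param betas noise levels.
#' @param pitches inter-electrode distances (um).
#' @param trials phantom placements per (beta, pitch) cell.
#' @param seed integer seed.
#' @param grid_counts,d grid dimensions and spacing (um).
#' @param width Gaussian width parameter `l` (um).
#' @param sigma homogeneous conductivity (S/m).
#' @param array_counts electrode lattice dimensions.
#' @param lambda_grid optional lambda search grid.
#' @return A tibble with columns `method`, `beta`, `pitch_um`, `trial`,
#'   `lambda`, `re`.
#' @export
run_noise_resolution_sweep <- function(
    betas = c(0.01, 0.05, 0.1, 0.5),
    pitches = c(200, 300, 400, 600),
    trials = 50L, seed = 1L,
    grid_counts = c(24L, 24L, 24L), d = 50,
    width = 400, sigma = 0.3,
    array_counts = c(4L, 4L, 8L),
    lambda_grid = NULL) {
  stopifnot(length(betas) > 0L, length(pitches) > 0L, trials >= 1L)
  grid <- build_grid(c(0, 0, 0), grid_counts, d)
  ctr <- c(mean(range(grid$x)), mean(range(grid$y)), mean(range(grid$z)))
  roi <- dplyr::filter(grid, !.data$guard)
  rows <- list()
  set.seed(seed)
  for (pitch in pitches) {
    array <- lattice_array(array_counts, pitch,
                           origin = ctr - (array_counts - 1L) * pitch / 2)
    lf <- assemble_leadfield(array, grid, conductor_infh(sigma))
    op <- vcsd_operator(lf)
    for (tr in seq_len(trials)) {
      center <- c(stats::runif(1, min(roi$x), max(roi$x)),
                  stats::runif(1, min(roi$y), max(roi$y)),
                  stats::runif(1, min(roi$z), max(roi$z)))
      truth <- gaussian_phantom(grid, center, width)
      phi0 <- forward_potentials(lf, truth)
      for (beta in betas) {
        phi <- add_noise(phi0, beta)
        fit <- fit_vcsd(potentials = phi, operator = op,
                        lambda_grid = lambda_grid)
        est_icsd <- suppressWarnings(
          solve_icsd3d(array, phi, sigma, grid, interpolation = "step"))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = c("vcsd", "icsd3d"),
          beta = beta, pitch_um = pitch, trial = tr,
          lambda = c(fit$lambda, NA_real_),
          re = c(reconstruction_error(truth, fit$csd),
                 reconstruction_error(truth, est_icsd))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write experiment results with a manifest
#'
#' Saves a results tibble as tidy CSV plus a JSON manifest recording the
#' run parameters.
#'
#' @param results a tibble.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @param manifest named list of run parameters (seeds, grid, conductor
#'   fingerprint, ...).
#' @return The CSV path, invisibly.
#' @export
write_results <- function(results, dir, name = "results", manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(results, csv, row.names = FALSE)
  manifest$written <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
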