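#' Assemble the lead-field matrix
#'
#' Builds the N x M generalized Green's function matrix `G` whose entry
#' `G[i, j]` is the potential at electrode `i` per unit point current at
#' grid node `j`, under the chosen volume conductor. The linear algebra of
#' the inverse (`Phi = G C`, with node currents `I_j = C_j d^3`) is carried
#' out against this matrix.
#'
#' No electrode may lie within the exclusion radius (default `d / 10`) of a
#' grid node: the kernels are singular at zero distance and the forward
#' model places sources strictly between electrodes.
#'
#' @param array an [electrode_array()].
#' @param grid a [build_grid()] source grid.
#' @param model a [conductor_infh()] or [conductor_sphih()] volume conductor.
#' @param exclusion minimum electrode-node distance in micrometers
#'   (default `d / 10`).
#' @return An object of class `lead_field`: list with elements `matrix`
#'   (N x M, V/A), `array`, `grid`, `conductor`, `reference`
#'   (`"monopolar_vs_infinity"` until [apply_average_reference()] is used).
#' @export
assemble_leadfield <- function(array, grid, model, exclusion = NULL) {
  stopifnot(inherits(array, "electrode_array"), inherits(grid, "source_grid"),
            inherits(model, "volume_conductor"))
  if (is.null(exclusion)) exclusion <- grid_spacing(grid) / 10
  E <- cbind(array$x, array$y, array$z)
  S <- cbind(grid$x, grid$y, grid$z)
  D2 <- outer(E[, 1], S[, 1], "-")^2
  D2 <- D2 + outer(E[, 2], S[, 2], "-")^2
  D2 <- D2 + outer(E[, 3], S[, 3], "-")^2
  viol <- which(D2 < exclusion^2, arr.ind = TRUE)
  if (nrow(viol) > 0L) {
    show <- utils::head(viol, 5L)
    stop(sprintf(
      "%d electrode-node pair(s) closer than the exclusion radius %.3g um; e.g. %s",
      nrow(viol), exclusion,
      paste(sprintf("(site %d, node %d)", show[, 1], show[, 2]), collapse = ", ")
    ), call. = FALSE)
  }
  G <- if (model$kind == "InfH") {
    1 / (4 * pi * model$sigma * sqrt(D2) * 1e-6)
  } else {
    sphih_leadfield_matrix(E, S, model)
  }
  dimnames(G) <- NULL
  structure(list(
    matrix = G, array = array, grid = grid, conductor = model,
    reference = "monopolar_vs_infinity"
  ), class = "lead_field")
}

# Dense SphIh kernel over all electrode x node pairs. Radial series
# coefficients are shared across the (few) unique radius pairs; the angular
# Legendre sum runs in C++.
sphih_leadfield_matrix <- function(E, S, model) {
  sa <- sphere_coords(E, model)
  sb <- sphere_coords(S, model)
  U <- (sa$pos %*% t(sb$pos)) / outer(sa$radius, sb$radius)
  U <- pmin(pmax(U, -1), 1)
  n_e <- nrow(E)
  n_s <- nrow(S)
  ra <- rep(sa$radius * 1e-6, times = n_s)
  rb <- rep(sb$radius * 1e-6, each = n_e)
  vals <- sphih_series_eval(ra, rb, as.vector(U), model)
  matrix(vals, n_e, n_s)
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d electrodes x %d nodes, %s conductor, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$conductor$kind, x$reference))
  invisible(x)
}

#' @export
tidy.lead_field <- function(x, ...) {
  tibble::tibble(
    site = rep(x$array$site, times = ncol(x$matrix)),
    node = rep(x$grid$node, each = nrow(x$matrix)),
    gain = as.vector(x$matrix)
  )
}

#' Re-reference a lead field and potentials to the common average
#'
#' Applies the average-reference operator `H = I - (1/N) 11'` to the rows of
#' the lead field and to the potential vector(s), removing the signal at the
#' (unmodeled) reference electrode. `H` annihilates constants and is a
#' projector, so re-referenced potentials sum to zero across channels and a
#' second application changes nothing (and is rejected as an invalid state).
#'
#' @param lead_field a [assemble_leadfield()] result with monopolar
#'   reference.
#' @param potentials numeric N-vector, or N x T matrix (columns are time
#'   instants).
#' @return A list with re-referenced `lead_field` and `potentials`.
#' @export
apply_average_reference <- function(lead_field, potentials) {
  stopifnot(inherits(lead_field, "lead_field"))
  if (identical(lead_field$reference, "average_reference")) {
    rlang::abort("lead field is already average-referenced",
                 class = "vcsd_invalid_state")
  }
  phi <- as.matrix(potentials)
  if (nrow(phi) != nrow(lead_field$matrix)) {
    stop("`potentials` must have one row per electrode", call. = FALSE)
  }
  lead_field$matrix <- sweep(lead_field$matrix, 2, colMeans(lead_field$matrix))
  lead_field$reference <- "average_reference"
  phi <- sweep(phi, 2, colMeans(phi))
  if (is.null(dim(potentials))) phi <- drop(phi)
  list(lead_field = lead_field, potentials = phi)
}

#' Forward-project a CSD volume to electrode potentials
#'
#' Computes `Phi = G (C d^3)`: each node's CSD value (current per volume)
#' times its cubic cell volume gives the node's point current; the lead
#' field maps point currents to potentials.
#'
#' @param lead_field a [assemble_leadfield()] result.
#' @param csd a `csd_volume` (see [solve_vcsd()]) on the lead field's grid,
#'   or a numeric M-vector / M x T matrix of CSD values.
#' @return Numeric N-vector (or N x T matrix) of potentials (V).
#' @export
forward_potentials <- function(lead_field, csd) {
  stopifnot(inherits(lead_field, "lead_field"))
  vals <- csd_values(csd)
  d_m <- grid_spacing(lead_field$grid) * 1e-6
  out <- lead_field$matrix %*% (vals * d_m^3)
  if (ncol(out) == 1L) drop(out) else out
}

#' Cache a lead field on disk
#'
#' Assembling the SphIh lead field is the expensive step of the pipeline, so
#' it can be cached. The cache stores a fingerprint of the array, grid and
#' conductor; any change in geometry or profile invalidates it and triggers
#' reassembly.
#'
#' @inheritParams assemble_leadfield
#' @param cache_file path to an `.rds` cache file.
#' @return A `lead_field`, from cache when the fingerprint matches.
#' @export
assemble_leadfield_cached <- function(array, grid, model, cache_file,
                                      exclusion = NULL) {
  fp <- leadfield_fingerprint(array, grid, model)
  if (file.exists(cache_file)) {
    cached <- readRDS(cache_file)
    if (identical(cached$fingerprint, fp)) return(cached$lead_field)
  }
  lf <- assemble_leadfield(array, grid, model, exclusion = exclusion)
  dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(fingerprint = fp, lead_field = lf), cache_file)
  lf
}

leadfield_fingerprint <- function(array, grid, model) {
  prof <- if (model$kind == "InfH") c(sigma = model$sigma) else c(
    unlist(model$shells), outer = model$outer_sigma, axis = model$axis_xy,
    tol = model$series_tolerance, terms = model$max_terms
  )
  paste(
    model$kind,
    paste(signif(c(array$x, array$y, array$z), 10), collapse = ","),
    paste(signif(c(grid$x, grid$y, grid$z), 10), collapse = ","),
    paste(signif(prof, 10), collapse = ","),
    sep = "|"
  )
}
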