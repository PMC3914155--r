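#' Volume conductor models
#'
#' Two conductor models map point current sources to extracellular
#' potentials:
#'
#' * **InfH** — an infinite, homogeneous, isotropic medium with scalar
#'   conductivity `sigma`; the kernel is the closed form
#'   `1 / (4 pi sigma r)`.
#' * **SphIh** — a spherically layered, inhomogeneous, anisotropic medium:
#'   concentric shells (cortical layers) each with its own radial and
#'   tangential conductivity, embedded in an unbounded homogeneous outer
#'   medium so that monopolar sources admit a steady state with the
#'   potential vanishing at infinity. The kernel is computed by
#'   Legendre-series expansion in the angle between source and electrode
#'   radii, with per-shell radial transfer propagation and a closed-form
#'   geometric tail acceleration.
#'
#' All geometry is in micrometers; conversion to SI happens inside the
#' kernels.
#'
#' @param sigma scalar conductivity in S/m.
#' @return An object of class `volume_conductor`.
#' @export
conductor_infh <- function(sigma = 0.3) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar conductivity (S/m)", call. = FALSE)
  }
  structure(list(kind = "InfH", sigma = sigma), class = "volume_conductor")
}

#' @rdname conductor_infh
#' @param shells data frame with columns `radius_um` (outer radius of each
#'   shell, strictly increasing; the innermost shell spans from the sphere
#'   center to its radius), `sigma_radial` and `sigma_tangential` (S/m).
#' @param outer_sigma isotropic conductivity of the unbounded medium beyond
#'   the outermost shell (S/m). A low value emulates a poorly conducting
#'   medium above the pia.
#' @param axis_xy tangential coordinates of the radial axis through the ROI
#'   center; the Cartesian grid is registered to the sphere about this axis.
#' @param series_tolerance relative term-magnitude cutoff for the Legendre
#'   series.
#' @param max_terms cap on the number of series terms.
#' @export
conductor_sphih <- function(shells, outer_sigma = 0.1, axis_xy = c(0, 0),
                            series_tolerance = 1e-8, max_terms = 512L) {
  shells <- as.data.frame(shells)
  need <- c("radius_um", "sigma_radial", "sigma_tangential")
  if (!all(need %in% names(shells))) {
    stop("`shells` needs columns radius_um, sigma_radial, sigma_tangential",
         call. = FALSE)
  }
  r <- as.numeric(shells$radius_um)
  if (any(diff(r) <= 0) || any(r <= 0)) {
    stop("shell radii must be positive and strictly increasing", call. = FALSE)
  }
  if (any(shells$sigma_radial <= 0) || any(shells$sigma_tangential <= 0) ||
      outer_sigma <= 0) {
    stop("all conductivities must be positive", call. = FALSE)
  }
  structure(list(
    kind = "SphIh",
    shells = tibble::tibble(
      radius_um = r,
      sigma_radial = as.numeric(shells$sigma_radial),
      sigma_tangential = as.numeric(shells$sigma_tangential)
    ),
    outer_sigma = as.numeric(outer_sigma),
    axis_xy = as.numeric(axis_xy),
    series_tolerance = series_tolerance,
    max_terms = as.integer(max_terms)
  ), class = "volume_conductor")
}

#' Default six-shell cortical conductor profile
#'
#' A synthetic but physiologically plausible six-shell profile for rat
#' somatosensory cortex: pia at radius 4000 um, cortical layers as thin
#' anisotropic shells (radial conductivity larger than tangential), an
#' isotropic subcortical core, and a low-conductivity medium above the pia.
#' These are placeholder values chosen to be realistic in magnitude
#' (0.25-0.45 S/m); they are not a published measured profile. All
#' validation experiments are profile-agnostic: the same model is used for
#' the forward projection and the inversion.
#'
#' @return `default_sphih_shells()`: a tibble of shells;
#'   `default_sphih()`: a ready [conductor_sphih()] model.
#' @export
default_sphih_shells <- function() {
  tibble::tibble(
    radius_um        = c(2100, 2500, 3100, 3350, 3850, 4000),
    sigma_radial     = c(0.25, 0.35, 0.40, 0.45, 0.35, 0.30),
    sigma_tangential = c(0.25, 0.25, 0.28, 0.30, 0.26, 0.30)
  )
}

#' @rdname default_sphih_shells
#' @param ... passed to [conductor_sphih()].
#' @export
default_sphih <- function(...) {
  conductor_sphih(default_sphih_shells(), ...)
}

#' Read a conductor profile from YAML or JSON
#'
#' Schema: a mapping with `outer_sigma` (S/m) and `shells`, a list of
#' mappings each with `radius_um`, `sigma_radial`, `sigma_tangential`.
#' Optional keys `axis_xy`, `series_tolerance`, `max_terms`.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return A [conductor_sphih()] model.
#' @export
read_conductor_profile <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  shells <- cfg$shells
  if (is.list(shells) && !is.data.frame(shells)) {
    shells <- do.call(rbind, lapply(shells, function(s) as.data.frame(s)))
  }
  args <- list(shells = shells, outer_sigma = cfg$outer_sigma)
  for (k in c("axis_xy", "series_tolerance", "max_terms")) {
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  }
  do.call(conductor_sphih, args)
}

#' @export
print.volume_conductor <- function(x, ...) {
  if (x$kind == "InfH") {
    cat("<volume_conductor: InfH>  sigma =", x$sigma, "S/m\n")
  } else {
    cat("<volume_conductor: SphIh> ", nrow(x$shells),
        "shells, outer radius", max(x$shells$radius_um), "um,",
        "outer sigma", x$outer_sigma, "S/m\n")
  }
  invisible(x)
}

# --- geometric registration -------------------------------------------------

# Map ROI Cartesian coordinates (x, y tangential; z depth below pia, um) onto
# the sphere: the ROI center axis passes through the sphere center; a point
# at depth z lies at radius R - z, with (x, y) as chordal offsets
# perpendicular to the axis at that depth. Returns unit-consistent Cartesian
# coordinates relative to the sphere center (um) plus radii.
sphere_coords <- function(xyz, model) {
  R <- max(model$shells$radius_um)
  dx <- xyz[, 1] - model$axis_xy[1]
  dy <- xyz[, 2] - model$axis_xy[2]
  r <- R - xyz[, 3]
  if (any(r <= 0)) {
    stop("points must lie above the sphere center (depth < outer radius)",
         call. = FALSE)
  }
  h2 <- r^2 - dx^2 - dy^2
  if (any(h2 <= 0)) {
    stop("tangential offset exceeds the radius at this depth; ",
         "point cannot be registered to the sphere", call. = FALSE)
  }
  list(pos = cbind(dx, dy, sqrt(h2)), radius = r)
}

# --- radial two-point boundary-value solution -------------------------------

# For each Legendre order n, the radial factor R_n(r) of the potential obeys
#   sigma_r (r^2 R')' / r^2 - sigma_t n(n+1) R / r^2 = 0
# piecewise in each shell, with continuity of R and of the radial current
# sigma_r R' at interfaces. Within a shell the fundamental solutions are
# r^p and r^-(p+1) with p(p+1) = (sigma_t/sigma_r) n(n+1).
#
# This propagates the solution regular at the center ("u", outward) and the
# solution decaying at infinity ("w", inward) through all interfaces,
# evaluating (value, radial-current) at each requested radius, with
# per-interface rescaling against overflow (log scale tracked).
#
# radii_m: sorted unique radii (meters), all strictly inside the outer shell.
# The state is renormalized at every breakpoint (interfaces and evaluation
# radii) so that thick shells and high orders cannot overflow; the running
# log-scale is returned alongside.
# Returns matrices (length(radii) x (nmax+1)): VU, FU, LU, VW, FW, LW.
sphih_radial_states <- function(model, radii_m, nmax) {
  rb <- model$shells$radius_um * 1e-6        # interface radii, meters
  sr <- model$shells$sigma_radial
  st <- model$shells$sigma_tangential
  K <- length(rb)
  s_out <- model$outer_sigma
  nn <- 0:nmax
  nn1 <- nn * (nn + 1)
  # p exponent per shell (rows: shells, cols: orders)
  P <- t(vapply(seq_len(K), function(k) {
    (-1 + sqrt(1 + 4 * (st[k] / sr[k]) * nn1)) / 2
  }, numeric(nmax + 1)))
  nr <- length(radii_m)
  region_of <- function(r) findInterval(r, rb, left.open = TRUE) + 1L  # 1..K
  if (any(radii_m >= rb[K]) || any(radii_m <= 0)) {
    stop("all points must lie strictly inside the outer shell", call. = FALSE)
  }
  VU <- FU <- LU <- VW <- FW <- LW <- matrix(0, nr, nmax + 1L)

  # value and radial current at xi = r/r0 of the local combination
  # a (r/r0)^p + b (r/r0)^-(p+1), given state (v, f) at r0 in shell k
  step_once <- function(v, f, r0, r1, k) {
    p <- P[k, ]
    a <- ((p + 1) * v + r0 * f / sr[k]) / (2 * p + 1)
    b <- (p * v - r0 * f / sr[k]) / (2 * p + 1)
    lx <- log(r1 / r0)
    list(
      v = a * exp(p * lx) + b * exp(-(p + 1) * lx),
      f = sr[k] * (a * p * exp((p - 1) * lx) -
                   b * (p + 1) * exp(-(p + 2) * lx)) / r0
    )
  }
  rescale <- function(st_vf, r) {
    s <- pmax(abs(st_vf$v), abs(st_vf$f) * r)
    s[s == 0 | !is.finite(s)] <- 1
    list(v = st_vf$v / s, f = st_vf$f / s, dL = log(s))
  }
  # step with intermediate rescaled substeps so that high orders cannot
  # overflow (the per-substep exponent p * |log ratio| stays below ~500);
  # returns the unrescaled state at r1 plus the scale accumulated en route
  step_to <- function(v, f, r0, r1, k) {
    pmx <- max(P[k, ])
    nsub <- max(1L, ceiling(pmx * abs(log(r1 / r0)) / 500))
    dL <- 0
    if (nsub > 1L) {
      rs <- exp(seq(log(r0), log(r1), length.out = nsub + 1L))
      for (s in seq_len(nsub - 1L)) {
        st <- step_once(v, f, rs[s], rs[s + 1L], k)
        sc <- rescale(st, rs[s + 1L])
        v <- sc$v; f <- sc$f; dL <- dL + sc$dL
      }
      r0 <- rs[nsub]
    }
    st <- step_once(v, f, r0, r1, k)
    list(v = st$v, f = st$f, dL = dL)
  }

  # --- outward solution u, regular at the center ---
  # start at the first interface; targets below it get the closed form
  below <- which(radii_m <= rb[1])
  for (i in below) {
    lx <- log(radii_m[i] / rb[1])
    VU[i, ] <- exp(P[1, ] * lx)
    p1 <- P[1, ]
    FU[i, ] <- ifelse(p1 == 0, 0, sr[1] * p1 * exp((p1 - 1) * lx) / rb[1])
    LU[i, ] <- 0
  }
  bps <- sort(unique(c(radii_m[radii_m > rb[1]], rb[rb > rb[1]])))
  v <- rep(1, nmax + 1L); f <- sr[1] * P[1, ] / rb[1]; L <- rep(0, nmax + 1L)
  r_cur <- rb[1]
  for (r_next in bps) {
    k <- region_of(r_next)
    stv <- step_to(v, f, r_cur, r_next, k)
    L <- L + stv$dL
    hit <- which(radii_m == r_next)
    for (i in hit) { VU[i, ] <- stv$v; FU[i, ] <- stv$f; LU[i, ] <- L }
    sc <- rescale(stv, r_next)
    v <- sc$v; f <- sc$f; L <- L + sc$dL
    r_cur <- r_next
  }
  # --- inward solution w, decaying at infinity ---
  bps <- sort(unique(c(radii_m, rb[-K])), decreasing = TRUE)
  v <- rep(1, nmax + 1L); f <- -s_out * (nn + 1) / rb[K]; L <- rep(0, nmax + 1L)
  r_cur <- rb[K]
  for (r_next in bps) {
    k <- region_of(r_cur)
    stv <- step_to(v, f, r_cur, r_next, k)
    L <- L + stv$dL
    hit <- which(radii_m == r_next)
    for (i in hit) { VW[i, ] <- stv$v; FW[i, ] <- stv$f; LW[i, ] <- L }
    sc <- rescale(stv, r_next)
    v <- sc$v; f <- sc$f; L <- L + sc$dL
    r_cur <- r_next
  }
  list(VU = VU, FU = FU, LU = LU, VW = VW, FW = FW, LW = LW,
       radii_m = radii_m)
}

# Radial series coefficients c_n for unique (r_min, r_max) radius pairs.
# ia, ib: indices into the state radii, with radii[ia] <= radii[ib].
# For a unit point current at one radius observed at the other,
#   phi(r_e, gamma) = sum_n c_n P_n(cos gamma),
#   c_n = -(2n+1)/(4 pi) u(r_min) w(r_max) / Omega,
# where Omega = r^2 (u sigma_r w' - sigma_r u' w) is the (constant)
# generalized Wronskian evaluated at r_max.
sphih_pair_coeffs <- function(states, ia, ib) {
  nmax1 <- ncol(states$VU)
  nn <- 0:(nmax1 - 1L)
  rb2 <- states$radii_m[ib]^2
  omega <- rb2 * (states$VU[ib, , drop = FALSE] * states$FW[ib, , drop = FALSE] -
                  states$FU[ib, , drop = FALSE] * states$VW[ib, , drop = FALSE])
  scal <- exp(states$LU[ia, , drop = FALSE] - states$LU[ib, , drop = FALSE])
  num <- states$VU[ia, , drop = FALSE] * states$VW[ib, , drop = FALSE] * scal
  cn <- -sweep(num / omega, 2, (2 * nn + 1) / (4 * pi), "*")
  t(cn)  # (nmax+1) x npairs
}

# Fit the geometric tail c_n ~ A t^n at the truncation order.
# Returns list(A, t) per pair; flags pairs whose terms are still growing.
sphih_tail_fit <- function(coef, tol) {
  N <- nrow(coef)
  P <- ncol(coef)
  A <- numeric(P)
  tt <- numeric(P)
  win <- min(8L, N - 1L)
  grow <- logical(P)
  for (p in seq_len(P)) {
    cN <- abs(coef[N, p])
    c0 <- abs(coef[N - win, p])
    cmax <- max(abs(coef[, p]))
    if (!is.finite(cN) || cN == 0 || c0 == 0 || cN <= tol * cmax) {
      A[p] <- 0; tt[p] <- 0
      next
    }
    r <- (cN / c0)^(1 / win)
    if (!is.finite(r)) { A[p] <- 0; tt[p] <- 0; next }
    if (r > 1 + 1e-6) grow[p] <- TRUE
    r <- min(r, 1)
    # skip the correction when the tail is negligible anyway: applying it
    # would multiply closed-form cancellation error by a large A = c_N t^-N
    if (cN * r / (1 - r + 1e-12) < 10 * tol * cmax) {
      A[p] <- 0; tt[p] <- 0
      next
    }
    tt[p] <- r
    # match the last computed term exactly: A t^(N-1) = c_(N-1)
    A[p] <- coef[N, p] * exp(-(N - 1) * log(max(r, 1e-300)))
  }
  list(A = A, t = tt, growing = grow)
}

# --- kernels ----------------------------------------------------------------

#' Green's function of the infinite homogeneous medium
#'
#' Potential (V) at `r_e` produced by a unit point current (1 A) at `r_s` in
#' an infinite, homogeneous, isotropic conductor:
#' `phi = 1 / (4 pi sigma ||r_e - r_s||)`. Coordinates in micrometers,
#' conductivity in S/m; the return value is in V/A.
#'
#' @param r_e,r_s electrode and source coordinates: length-3 vectors or
#'   matrices with 3 columns (paired rowwise, recycled if one is a single
#'   point).
#' @param sigma conductivity (S/m).
#' @return Numeric vector of potentials per unit current (V/A).
#' @export
greens_infh <- function(r_e, r_s, sigma = 0.3) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  re <- to_xyz_matrix(r_e)
  rs <- to_xyz_matrix(r_s)
  n <- max(nrow(re), nrow(rs))
  if (nrow(re) == 1L) re <- re[rep(1L, n), , drop = FALSE]
  if (nrow(rs) == 1L) rs <- rs[rep(1L, n), , drop = FALSE]
  d_um <- sqrt(rowSums((re - rs)^2))
  if (any(d_um == 0)) {
    stop("singularity: source and electrode coincide", call. = FALSE)
  }
  1 / (4 * pi * sigma * d_um * 1e-6)
}

to_xyz_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("coordinates must be length-3 or an n x 3 matrix",
                              call. = FALSE)
    matrix(as.numeric(x), 1L, 3L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("coordinate matrices need 3 columns", call. = FALSE)
    storage.mode(x) <- "double"
    x
  }
}

#' Green's function of the layered anisotropic sphere
#'
#' Potential per unit point current in the SphIh conductor. Both points must
#' lie strictly inside the outermost shell (after registration of the ROI
#' coordinates to the sphere) and must not coincide. The Legendre series is
#' truncated when the relative magnitude of the terms falls below
#' `model$series_tolerance` or at `model$max_terms`; the remaining tail is
#' summed in closed form from a geometric fit, which makes the kernel exact
#' in the homogeneous-isotropic limit. If the series terms are still growing
#' at the cap, a convergence error carrying the partial sum and the term
#' count is raised.
#'
#' @inheritParams greens_infh
#' @param model a [conductor_sphih()] model.
#' @return Numeric vector of potentials per unit current (V/A).
#' @export
greens_sphih <- function(r_e, r_s, model) {
  stopifnot(inherits(model, "volume_conductor"))
  if (model$kind != "SphIh") stop("`model` must be a SphIh conductor", call. = FALSE)
  re <- to_xyz_matrix(r_e)
  rs <- to_xyz_matrix(r_s)
  n <- max(nrow(re), nrow(rs))
  if (nrow(re) == 1L) re <- re[rep(1L, n), , drop = FALSE]
  if (nrow(rs) == 1L) rs <- rs[rep(1L, n), , drop = FALSE]
  if (any(rowSums((re - rs)^2) == 0)) {
    stop("singularity: source and electrode coincide", call. = FALSE)
  }
  sa <- sphere_coords(re, model)
  sb <- sphere_coords(rs, model)
  u <- rowSums(sa$pos * sb$pos) / (sa$radius * sb$radius)
  u <- pmin(pmax(u, -1), 1)
  sphih_series_eval(sa$radius * 1e-6, sb$radius * 1e-6, u, model)
}

# Shared evaluation path: paired radii (meters) + cos(angle).
sphih_series_eval <- function(ra_m, rb_m, u, model) {
  amin <- pmin(ra_m, rb_m)
  bmax <- pmax(ra_m, rb_m)
  radii <- sort(unique(signif(c(amin, bmax), 12)))
  ia_all <- match(signif(amin, 12), radii)
  ib_all <- match(signif(bmax, 12), radii)
  code <- (ia_all - 1L) * length(radii) + ib_all
  ucode <- sort(unique(code))
  pair_of <- match(code, ucode) - 1L           # 0-based for C++
  ia <- (ucode - 1L) %/% length(radii) + 1L
  ib <- (ucode - 1L) %% length(radii) + 1L
  nmax <- model$max_terms
  states <- sphih_radial_states(model, radii, nmax)
  coef <- sphih_pair_coeffs(states, ia, ib)
  tol <- model$series_tolerance
  # truncate where every pair's terms are below tolerance
  cmax <- apply(abs(coef), 2, max)
  keep <- abs(coef) > rep(tol * cmax, each = nrow(coef))
  neff <- max(c(which(rowSums(keep) > 0), 2L))
  coef <- coef[seq_len(neff), , drop = FALSE]
  fit <- sphih_tail_fit(coef, tol)
  if (any(fit$growing)) {
    bad <- which(fit$growing)[1]
    rlang::abort(
      message = sprintf(
        "Legendre series not converging within %d terms (radius pair %.4g / %.4g m)",
        nmax, radii[ia[bad]], radii[ib[bad]]),
      class = "vcsd_convergence_error",
      partial_terms = nrow(coef), n_pairs_growing = sum(fit$growing)
    )
  }
  .legendre_series_sum(coef, fit$A, fit$t, pair_of, u)
}
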