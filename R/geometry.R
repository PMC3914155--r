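#' Electrode arrays and current-source grids
#'
#' The reconstruction operates on two geometric objects: an electrode array
#' (the N recording sites of a 3D silicon probe) and a current-source grid (a
#' regular lattice of M candidate source nodes). Both are represented as
#' tibbles with one row per site/node so they compose with dplyr verbs;
#' layout metadata travels in attributes.
#'
#' Coordinates are Cartesian micrometers. `z` is cortical depth, positive
#' downward from the pia; `x` and `y` are tangential. Unit conversions to SI
#' happen only inside the volume-conductor kernels.
#'
#' @param positions numeric matrix or data frame with columns `x`, `y`, `z`
#'   (micrometers), one row per recording site.
#' @param n_x,n_y number of shanks along each tangential axis.
#' @param n_z number of recording sites per shank.
#' @param labels optional character vector of per-site identifiers.
#' @return A tibble of class `electrode_array` with columns `site`, `label`,
#'   `x`, `y`, `z` and attributes `n_x`, `n_y`, `n_z`.
#' @examples
#' arr <- mea_layout("array64_equidistant")
#' nrow(arr)
#' @export
electrode_array <- function(positions, n_x = NA_integer_, n_y = NA_integer_,
                            n_z = NA_integer_, labels = NULL) {
  pos <- as.data.frame(positions)
  if (!all(c("x", "y", "z") %in% names(pos))) {
    if (ncol(pos) == 3L) names(pos) <- c("x", "y", "z")
    else stop("`positions` must have columns x, y, z", call. = FALSE)
  }
  n <- nrow(pos)
  if (n < 1L) stop("electrode array must contain at least one site", call. = FALSE)
  if (anyDuplicated(pos[, c("x", "y", "z")]) > 0L) {
    stop("electrode positions must be pairwise distinct", call. = FALSE)
  }
  if (!anyNA(c(n_x, n_y, n_z)) && n_x * n_y * n_z != n) {
    stop("n_x * n_y * n_z does not match the number of positions", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("e%03d", seq_len(n))
  out <- tibble::tibble(
    site = seq_len(n), label = as.character(labels),
    x = as.numeric(pos$x), y = as.numeric(pos$y), z = as.numeric(pos$z)
  )
  structure(out,
    n_x = as.integer(n_x), n_y = as.integer(n_y), n_z = as.integer(n_z),
    class = c("electrode_array", class(out))
  )
}

#' Build a full-lattice electrode array
#'
#' Sites are laid out on a regular lattice, x fastest, then y, then z (the
#' same linear-index convention used for source grids and all matrices).
#'
#' @param counts integer triple `(n_x, n_y, n_z)`.
#' @param pitch lattice spacing in micrometers; a scalar or a triple
#'   `(px, py, pz)`.
#' @param origin coordinate of the first site (micrometers).
#' @return An [electrode_array()].
#' @export
lattice_array <- function(counts, pitch, origin = c(0, 0, 0)) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 1L)) {
    stop("`counts` must be three positive integers", call. = FALSE)
  }
  pitch <- rep_len(as.numeric(pitch), 3L)
  if (any(pitch <= 0)) stop("`pitch` must be positive", call. = FALSE)
  idx <- lattice_subscripts(counts)
  pos <- cbind(
    x = origin[1] + (idx[, 1] - 1L) * pitch[1],
    y = origin[2] + (idx[, 2] - 1L) * pitch[2],
    z = origin[3] + (idx[, 3] - 1L) * pitch[3]
  )
  electrode_array(pos, n_x = counts[1], n_y = counts[2], n_z = counts[3])
}

# (a,b,c) subscripts of a counts-lattice in x-fastest linear order
lattice_subscripts <- function(counts) {
  cbind(
    rep_len(seq_len(counts[1]), prod(counts)),
    rep_len(rep(seq_len(counts[2]), each = counts[1]), prod(counts)),
    rep(seq_len(counts[3]), each = counts[1] * counts[2])
  )
}

#' Standard 3D microelectrode-array layouts
#'
#' Ships the probe layouts used throughout the validation experiments:
#'
#' * `"array128"`: 4 x 4 shanks at 400 um inter-shank pitch, 8 sites per
#'   shank at 200 um pitch (N = 128); shank tips at 1600 um depth.
#' * `"array64_equidistant"`: the equidistant 400 um subset of `array128`
#'   (4 x 4 x 4, N = 64) used by the iCSD3D baseline, which requires equal
#'   pitch on all axes.
#' * `"sim_9x9x15"`: a dense simulation array, 100 um pitch on all axes
#'   (N = 1215), used in the volume-conductor mismatch experiment.
#'
#' Arrays are centered at `x = y = 0`; depths span 200-1600 um
#' (`array128`) or 100-1500 um (`sim_9x9x15`).
#'
#' @param name one of `"array128"`, `"array64_equidistant"`, `"sim_9x9x15"`.
#' @return An [electrode_array()].
#' @export
mea_layout <- function(name = c("array128", "array64_equidistant", "sim_9x9x15")) {
  name <- match.arg(name)
  switch(name,
    array128 = lattice_array(c(4L, 4L, 8L), pitch = c(400, 400, 200),
                             origin = c(-600, -600, 200)),
    array64_equidistant = lattice_array(c(4L, 4L, 4L), pitch = 400,
                                        origin = c(-600, -600, 200)),
    sim_9x9x15 = lattice_array(c(9L, 9L, 15L), pitch = 100,
                               origin = c(-400, -400, 100))
  )
}

#' Build a current-source grid
#'
#' Creates the regular `m_x x m_y x m_z` lattice of candidate source nodes
#' with spacing `d` on every axis. Node `(a, b, c)` sits at
#' `origin + ((a-1) d, (b-1) d, (c-1) d)`; the linear node index runs x
#' fastest, then y, then z, and this single convention is shared by the
#' lead-field and Laplacian matrices.
#'
#' Guard planes are the outermost `guard` planes per axis (default 3 in x
#' and y, 2 in z). Guard nodes stay in the inverse problem — they implement
#' a free boundary that absorbs sources from outside the recorded volume —
#' but are excluded from all reported metrics. An axis too small to hold its
#' guard planes plus at least one interior plane gets no guard on that axis.
#'
#' @param origin 3D coordinate of the first node (micrometers).
#' @param counts integer triple `(m_x, m_y, m_z)`.
#' @param d inter-node spacing in micrometers (`> 0`).
#' @param guard integer triple: number of guard planes on each side per axis.
#' @return A tibble of class `source_grid` with columns `node`, `ix`, `iy`,
#'   `iz`, `x`, `y`, `z`, `guard` and attributes `counts`, `d`, `origin`,
#'   `guard_planes`.
#' @examples
#' g <- build_grid(c(0, 0, 0), c(4, 4, 4), d = 50)
#' sum(!g$guard)  # interior nodes
#' @export
build_grid <- function(origin, counts, d, guard = c(3L, 3L, 2L)) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 1L)) {
    stop("`counts` must be three positive integers", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("`d` must be a positive spacing", call. = FALSE)
  }
  guard <- pmax(rep_len(as.integer(guard), 3L), 0L)
  # drop the guard on axes it would swallow whole
  guard <- ifelse(counts > 2L * guard, guard, 0L)
  idx <- lattice_subscripts(counts)
  is_guard <- (idx[, 1] <= guard[1]) | (idx[, 1] > counts[1] - guard[1]) |
    (idx[, 2] <= guard[2]) | (idx[, 2] > counts[2] - guard[2]) |
    (idx[, 3] <= guard[3]) | (idx[, 3] > counts[3] - guard[3])
  out <- tibble::tibble(
    node = seq_len(prod(counts)),
    ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
    x = origin[1] + (idx[, 1] - 1L) * d,
    y = origin[2] + (idx[, 2] - 1L) * d,
    z = origin[3] + (idx[, 3] - 1L) * d,
    guard = is_guard
  )
  structure(out,
    counts = counts, d = as.numeric(d), origin = as.numeric(origin),
    guard_planes = guard,
    class = c("source_grid", class(out))
  )
}

#' Center a source grid on an electrode array
#'
#' Convenience placement: the grid's bounding box is centered on the
#' array's bounding box, so guard planes extend symmetrically beyond the
#' recorded volume.
#'
#' @param array an [electrode_array()].
#' @inheritParams build_grid
#' @return A [build_grid()] result.
#' @export
grid_centered_on <- function(array, counts, d, guard = c(3L, 3L, 2L)) {
  stopifnot(inherits(array, "electrode_array"))
  counts <- as.integer(counts)
  ctr <- c(mean(range(array$x)), mean(range(array$y)), mean(range(array$z)))
  origin <- ctr - (counts - 1L) * d / 2
  build_grid(origin, counts, d, guard = guard)
}

grid_counts <- function(grid) attr(grid, "counts")
grid_spacing <- function(grid) attr(grid, "d")

#' Linear node index from lattice subscripts (and back)
#'
#' The convention is x fastest, then y, then z. These conversions round-trip
#' for every node.
#'
#' @param grid a [build_grid()] result.
#' @param a,b,c 1-based lattice subscripts.
#' @param j 1-based linear node index.
#' @return `node_index()`: linear indices; `node_subscripts()`: an
#'   integer matrix with columns `ix`, `iy`, `iz`.
#' @export
node_index <- function(grid, a, b, c) {
  m <- grid_counts(grid)
  stopifnot(all(a >= 1L & a <= m[1]), all(b >= 1L & b <= m[2]),
            all(c >= 1L & c <= m[3]))
  (c - 1L) * m[1] * m[2] + (b - 1L) * m[1] + a
}

#' @rdname node_index
#' @export
node_subscripts <- function(grid, j) {
  m <- grid_counts(grid)
  if (any(j < 1L | j > prod(m))) stop("node index out of range", call. = FALSE)
  j0 <- j - 1L
  cbind(
    ix = j0 %% m[1] + 1L,
    iy = (j0 %/% m[1]) %% m[2] + 1L,
    iz = j0 %/% (m[1] * m[2]) + 1L
  )
}

#' Face-adjacent neighbors of a grid node
#'
#' Returns the linear indices of nodes at lattice distance exactly `d`
#' (6-connectivity); interior nodes have 6 neighbors, faces 5, edges 4,
#' corners 3.
#'
#' @param grid a [build_grid()] result.
#' @param j a single 1-based node index.
#' @return Integer vector of neighbor node indices.
#' @export
neighbor_indices <- function(grid, j) {
  m <- grid_counts(grid)
  if (length(j) != 1L || j < 1L || j > prod(m)) {
    stop("node index out of range", call. = FALSE)
  }
  s <- node_subscripts(grid, j)
  out <- integer(0)
  for (axis in 1:3) {
    for (step in c(-1L, 1L)) {
      t <- s
      t[axis] <- t[axis] + step
      if (t[axis] >= 1L && t[axis] <= m[axis]) {
        out <- c(out, node_index(grid, t[1], t[2], t[3]))
      }
    }
  }
  sort(out)
}

#' Serialize / read array and grid layouts
#'
#' Layouts are stored as YAML or JSON (chosen by file extension) config
#' blocks. Lattice-parameterized grids store `origin`, `counts`, `d`,
#' `guard`; arrays store explicit positions plus shank counts.
#'
#' @param x an `electrode_array` or `source_grid`.
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `write_layout()` returns `path` invisibly; `read_layout()`
#'   returns the reconstructed object.
#' @export
write_layout <- function(x, path) {
  cfg <- if (inherits(x, "source_grid")) {
    list(type = "source_grid",
         origin = attr(x, "origin"), counts = grid_counts(x),
         d = grid_spacing(x), guard = attr(x, "guard_planes"))
  } else if (inherits(x, "electrode_array")) {
    list(type = "electrode_array",
         n_x = attr(x, "n_x"), n_y = attr(x, "n_y"), n_z = attr(x, "n_z"),
         labels = x$label,
         positions = lapply(seq_len(nrow(x)), function(i) {
           c(x$x[i], x$y[i], x$z[i])
         }))
  } else stop("unsupported layout object", call. = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (identical(cfg$type, "source_grid")) {
    build_grid(unlist(cfg$origin), unlist(cfg$counts), cfg$d,
               guard = unlist(cfg$guard))
  } else if (identical(cfg$type, "electrode_array")) {
    pos <- cfg$positions
    if (is.list(pos) && !is.data.frame(pos)) {
      pos <- do.call(rbind, lapply(pos, unlist))
    }
    pos <- as.matrix(pos)
    electrode_array(pos, n_x = cfg$n_x, n_y = cfg$n_y, n_z = cfg$n_z,
                    labels = unlist(cfg$labels))
  } else stop("unrecognized layout config", call. = FALSE)
}
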