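# Regular 3D dose grids: construction, rasterization from the kernel,
# and trilinear sampling.  The grid is the package's stand-in for a
# planning-system dose export: a regular lattice with explicit origin,
# spacing and x-fastest value ordering.

#' Construct a dose grid
#'
#' @param values 3D numeric array of doses, dimensions `(nx, ny, nz)`.
#' @param origin length-3 position (mm) of the first voxel center.
#' @param spacing length-3 positive voxel spacing (mm).
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    vstop("values must be a 3D array")
  }
  if (any(dim(values) < 2L)) {
    vstop("grid must have at least 2 voxels along every axis")
  }
  origin <- as_point3(origin, "origin")
  spacing <- as_point3(spacing, "spacing")
  if (any(spacing <= 0)) vstop("all grid spacings must be > 0")
  structure(list(values = values, origin = origin, spacing = spacing,
                 dim = dim(values)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

grid_bounds <- function(grid) {
  rbind(lo = grid$origin, hi = grid$origin + (grid$dim - 1) * grid$spacing)
}

#' Rasterize the kernel dose of a plan onto a regular grid
#'
#' Evaluates the summed beam dose at every voxel center.  Intended for
#' local grids around diodes of interest; a full-phantom millimetre
#' grid is large and rarely needed.
#'
#' @param plan a `qa_plan`.
#' @param kernel a [cone_kernel()].
#' @param origin first voxel center (mm).
#' @param spacing voxel spacing (mm).
#' @param dim integer length-3 voxel counts.
#' @return a `dose_grid`.
#' @export
rasterize_dose_grid <- function(plan, kernel, origin, spacing, dim) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 2L))
  origin <- as_point3(origin, "origin")
  spacing <- as_point3(spacing, "spacing")
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                               KEEP.OUT.ATTRS = FALSE))
  dose <- colSums(beam_dose_matrix(plan, pts, kernel))
  dose_grid(array(dose, dim = dim), origin, spacing)
}

#' Trilinearly sample a dose grid at arbitrary points
#'
#' Exact at lattice nodes and for affine fields; refuses points outside
#' the grid bounds.
#'
#' @param grid a `dose_grid`.
#' @param points `n x 3` matrix or length-3 vector of points (mm).
#' @return numeric vector of interpolated doses, length `n`.
#' @export
sample_dose_grid <- function(grid, points) {
  stopifnot(inherits(grid, "dose_grid"))
  pts <- matrix(as.numeric(points), ncol = 3)
  b <- grid_bounds(grid)
  tol <- 1e-9
  for (j in 1:3) {
    bad <- pts[, j] < b["lo", j] - tol | pts[, j] > b["hi", j] + tol
    if (any(bad)) {
      i <- which(bad)[1]
      vstop(
        "point (%g, %g, %g) outside grid bounds [%g, %g] x [%g, %g] x [%g, %g]",
        pts[i, 1], pts[i, 2], pts[i, 3],
        b["lo", 1], b["hi", 1], b["lo", 2], b["hi", 2], b["lo", 3], b["hi", 3]
      )
    }
  }
  # fractional voxel coordinates, clamped so boundary points index the
  # last cell with weight 1
  fr <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, `/`)
  i0 <- pmin(pmax(floor(fr), 0), matrix(grid$dim - 2, nrow(pts), 3,
                                        byrow = TRUE))
  w <- fr - i0
  w <- pmin(pmax(w, 0), 1)
  v <- grid$values
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) * idx(0, 0, 0) +
    w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) * idx(1, 0, 0) +
    (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) * idx(0, 1, 0) +
    (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] * idx(0, 0, 1) +
    w[, 1] * w[, 2] * (1 - w[, 3]) * idx(1, 1, 0) +
    w[, 1] * (1 - w[, 2]) * w[, 3] * idx(1, 0, 1) +
    (1 - w[, 1]) * w[, 2] * w[, 3] * idx(0, 1, 1) +
    w[, 1] * w[, 2] * w[, 3] * idx(1, 1, 1)
}
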