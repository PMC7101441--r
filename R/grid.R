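#' Define a regular acquisition grid
#'
#' Describes the voxel lattice of an MRE acquisition: the number of voxels per
#' axis, the (isotropic, mm) voxel spacing and the world position of the
#' centre of voxel `(1,1,1)`. All world coordinates in the package are in mm;
#' the world position of voxel `(i,j,k)` (1-based) is
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 8).
#' @param spacing voxel spacing in mm; scalar or length-3 vector, all > 0.
#'   Isotropic spacing is expected by the ROI logic downstream.
#' @param origin world coordinate (mm) of the centre of the first voxel.
#' @return An object of class `"acquisition_grid"`.
#' @export
acquisition_grid <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stop("'shape' must be three integers, all >= 8")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "acquisition_grid")
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat(sprintf("<acquisition_grid> %d x %d x %d voxels, spacing %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

# Per-axis world coordinates (mm) of voxel centres.
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

grid_nvox <- function(grid) prod(grid$shape)

# N x 3 matrix of voxel-centre world coordinates (mm), voxel-major
# (first axis fastest), matching R's array linearisation.
grid_centers <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$shape
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

# Distance (mm) of every voxel centre from a world point, as an array.
grid_radius <- function(grid, center) {
  ax <- grid_axes(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(sqrt(r2), dim = grid$shape)
}

# Centered grid helper: grid whose world origin puts the domain centre at 0.
centered_grid <- function(shape, spacing = 1) {
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  acquisition_grid(shape, spacing, origin = -(shape - 1) / 2 * spacing)
}

# Extract an axis-aligned subgrid; returns list(grid=, index=) where index
# is the linear-index vector of the subgrid voxels inside the parent grid.
subgrid_box <- function(grid, lo, hi) {
  lo <- pmax(as.integer(lo), 1L)
  hi <- pmin(as.integer(hi), grid$shape)
  if (any(hi < lo)) stop("empty subgrid")
  sub <- acquisition_grid(pmax(hi - lo + 1L, 1L), grid$spacing,
                          grid$origin + (lo - 1L) * grid$spacing)
  n <- grid$shape
  i <- lo[1]:hi[1]; j <- lo[2]:hi[2]; k <- lo[3]:hi[3]
  idx <- outer(outer(i, (j - 1L) * n[1], "+"), (k - 1L) * n[1] * n[2], "+")
  list(grid = sub, index = as.integer(idx))
}
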