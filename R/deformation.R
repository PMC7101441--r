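#' Spherical inclusion geometry
#'
#' A pressurized, roughly spherical inclusion (tumour, balloon, void) is
#' described by its centre `c0` (world mm), its *current* (as-imaged, i.e.
#' inflated) radius `r0` (mm) and the dimensionless inflation scaling
#' `alpha`. The uninflated reference radius is `R0 = (1 - alpha) * r0`:
#' `alpha = 0` means no inflation (zero pressure), `alpha -> 1` means
#' inflation from a point, and `alpha < 0` means the inclusion pulls on the
#' surrounding tissue (negative pressure).
#'
#' @param center world position of the inclusion centre, mm.
#' @param r0 current (inflated) radius, mm; > 0.
#' @param alpha inflation scaling, strictly < 1.
#' @return An object of class `"sphere_inclusion"` with fields `center`,
#'   `r0`, `alpha` and the derived reference radius `R0`.
#' @export
sphere_inclusion <- function(center, r0, alpha = 0) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be a finite world position (mm)")
  if (!is.finite(r0) || r0 <= 0) stop("'r0' must be > 0")
  if (!is.finite(alpha) || alpha >= 1)
    stop("'alpha' must be < 1 (alpha = 1 would inflate from a point, R0 = 0)")
  structure(list(center = center, r0 = as.numeric(r0),
                 alpha = as.numeric(alpha), R0 = (1 - alpha) * r0),
            class = "sphere_inclusion")
}

#' @export
print.sphere_inclusion <- function(x, ...) {
  cat(sprintf("<sphere_inclusion> c0 = (%s) mm, r0 = %.3g mm, alpha = %.3g (R0 = %.3g mm)\n",
              paste(format(x$center), collapse = ", "), x$r0, x$alpha, x$R0))
  invisible(x)
}

#' Inflation scaling from current and reference radii
#'
#' Inverts the defining relation `R0 = (1 - alpha) * r0`.
#'
#' @param r0 current (inflated) radius, mm; > 0.
#' @param R0 reference (uninflated) radius, mm; >= 0.
#' @return `alpha = 1 - R0 / r0`.
#' @export
alpha_from_radii <- function(r0, R0) {
  if (any(r0 <= 0)) stop("'r0' must be > 0")
  if (any(R0 < 0)) stop("'R0' must be >= 0")
  1 - R0 / r0
}

# Reference radius R (mm) corresponding to current radius r (mm):
# R^3 = r^3 + (1 - alpha)^3 r0^3 - r0^3 (incompressible shell kinematics).
reference_radius <- function(r, r0, alpha) {
  (r^3 + ((1 - alpha)^3 - 1) * r0^3)^(1 / 3)
}

#' Radial displacement of the incompressible shell inflation
#'
#' Magnitude of the radial displacement `dr = r - R` at current radius `r`
#' around an inclusion of current radius `r0` inflated with scaling `alpha`.
#' Incompressibility of the shell gives `r^3 - R^3 = r0^3 - R0^3`, so
#' `dr = r - (r^3 - r0^3 + (1 - alpha)^3 r0^3)^(1/3)`.
#'
#' @param r distance from the inclusion centre in the current configuration,
#'   mm; must be at least `r0` (the field is undefined inside the inclusion).
#' @param r0 current inclusion radius, mm.
#' @param alpha inflation scaling, < 1.
#' @return Radial displacement in mm; non-negative for `alpha >= 0` and
#'   tending to 0 as r grows.
#' @export
radial_displacement <- function(r, r0, alpha) {
  if (!is.finite(r0) || r0 <= 0) stop("'r0' must be > 0")
  if (alpha >= 1) stop("'alpha' must be < 1")
  if (any(r < r0)) stop("'r' < r0: displacement undefined inside the inclusion")
  r - reference_radius(r, r0, alpha)
}

#' Deformation gradient of the spherical inflation map
#'
#' Closed-form deformation gradient `F` of the incompressible spherical
#' inflation, evaluated at a current-configuration world position `x`. In the
#' local orthonormal frame (radial, tangential, tangential) the map has
#' principal stretches `(R^2/r^2, r/R, r/R)` with
#' `R^3 = r^3 + (1 - alpha)^3 r0^3 - r0^3`; the result is rotated to
#' Cartesian axes through the radial unit vector. `det F = 1` to machine
#' precision (exact incompressibility).
#'
#' @param x world position (mm), outside the inclusion (`|x - c0| >= r0`).
#' @param inclusion a [sphere_inclusion()].
#' @return 3 x 3 deformation gradient.
#' @export
deformation_gradient_sphere <- function(x, inclusion) {
  d <- as.numeric(x) - inclusion$center
  r <- sqrt(sum(d^2))
  if (r == 0) stop("degenerate radial direction: x equals the inclusion centre")
  if (r < inclusion$r0) stop("x lies inside the inclusion: deformation undefined")
  R <- reference_radius(r, inclusion$r0, inclusion$alpha)
  e <- d / r
  P <- tcrossprod(e)
  (R^2 / r^2) * P + (r / R) * (diag(3) - P)
}

#' Build the deformation-tensor volume for an inflated spherical inclusion
#'
#' Evaluates the analytic deformation gradient at every voxel centre outside
#' the inclusion and composes the per-voxel fourth-order wave-modification
#' tensor H' (see [hprime_tensor()]). Voxels strictly inside `r0` are masked
#' out, never extrapolated: the inclusion interior is modelled as a void.
#'
#' @param grid an [acquisition_grid()].
#' @param inclusion a [sphere_inclusion()]; its centre must lie inside the
#'   grid bounds.
#' @param hprime logical; also compute the per-voxel H' tensor volume
#'   (default `TRUE`).
#' @return An object of class `"deformation_tensors"`: list with `F` (N x 9
#'   matrix of per-voxel deformation gradients, column-major 3 x 3), `J`
#'   (determinants), `Hprime` (N x 81 matrix or `NULL`), `mask` (logical
#'   array, `FALSE` inside the inclusion), `grid`, `inclusion`.
#' @export
build_deformation_volume <- function(grid, inclusion, hprime = TRUE) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  if (any(inclusion$center < lo) || any(inclusion$center > hi))
    stop("inclusion centre lies outside the grid")
  xyz <- grid_centers(grid)
  d <- sweep(xyz, 2, inclusion$center)
  r <- sqrt(rowSums(d^2))
  mask <- r >= inclusion$r0
  n <- nrow(xyz)
  Fm <- matrix(rep(as.numeric(diag(3)), each = n), n, 9)
  idx <- which(mask & r > 0)
  if (length(idx)) {
    ri <- r[idx]
    R <- reference_radius(ri, inclusion$r0, inclusion$alpha)
    lam_r <- R^2 / ri^2           # radial principal stretch of F
    lam_t <- ri / R               # tangential principal stretch
    e <- d[idx, , drop = FALSE] / ri
    # F = lam_t I + (lam_r - lam_t) e e^T, column-major 3x3 per row
    dl <- lam_r - lam_t
    col <- 0L
    for (b in 1:3) for (a in 1:3) {
      col <- col + 1L
      Fm[idx, col] <- (if (a == b) lam_t else 0) + dl * e[, a] * e[, b]
    }
  }
  J <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 8] * Fm[, 6]) -
       Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 8] * Fm[, 3]) +
       Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 5] * Fm[, 3])
  H <- if (hprime) hprime_volume(Fm) else NULL
  structure(list(F = Fm, J = J, Hprime = H,
                 mask = array(mask, dim = grid$shape),
                 grid = grid, inclusion = inclusion),
            class = "deformation_tensors")
}

#' @export
print.deformation_tensors <- function(x, ...) {
  cat(sprintf("<deformation_tensors> %d voxels (%d masked out), alpha = %.3g\n",
              length(x$J), sum(!x$mask), x$inclusion$alpha))
  invisible(x)
}

#' Deformation gradient volume from a sampled displacement field
#'
#' Numerical-gradient path for user-supplied displacement volumes of
#' arbitrary shape: `F = I + grad(u)` by central finite differences on the
#' grid (one-sided at the mask boundary). The analytic spherical path
#' ([build_deformation_volume()]) is preferred whenever the inclusion is a
#' sphere, because it is exactly incompressible and free of
#' grid-differentiation error.
#'
#' @param u N x 3 matrix of displacements (mm) on the grid, current config.
#' @param grid an [acquisition_grid()].
#' @param mask logical array; `FALSE` where the field is undefined.
#' @param hprime logical; also compute H'.
#' @return A `"deformation_tensors"` object (with `inclusion = NULL`).
#' @export
deformation_gradient_numeric <- function(u, grid, mask = NULL, hprime = FALSE) {
  n <- grid_nvox(grid)
  if (!is.matrix(u) || nrow(u) != n || ncol(u) != 3L)
    stop("'u' must be an N x 3 displacement matrix matching the grid")
  if (is.null(mask)) mask <- array(TRUE, dim = grid$shape)
  g <- cpp_field_gradient(u, matrix(0, n, 3), as.logical(mask), grid$shape,
                          grid$spacing)  # d u_i / d x_j, per mm
  Fm <- g$re
  Fm[, c(1, 5, 9)] <- Fm[, c(1, 5, 9)] + 1  # F = I + grad u
  Fm[!g$valid, ] <- rep(as.numeric(diag(3)), each = sum(!g$valid))
  J <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 8] * Fm[, 6]) -
       Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 8] * Fm[, 3]) +
       Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 5] * Fm[, 3])
  m <- array(as.logical(mask) & g$valid, dim = grid$shape)
  H <- if (hprime) hprime_volume(Fm) else NULL
  structure(list(F = Fm, J = J, Hprime = H, mask = m,
                 grid = grid, inclusion = NULL),
            class = "deformation_tensors")
}

#' Inclusion geometry from a binary mask volume
#'
#' Derives the inclusion centre (intensity centroid) and the
#' equivalent-sphere radius (from the voxel count) of a segmented inclusion.
#'
#' @param mask logical (or 0/1) array on `grid`; `TRUE` inside the inclusion.
#' @param grid an [acquisition_grid()].
#' @param alpha inflation scaling to attach (default 0).
#' @return A [sphere_inclusion()].
#' @export
inclusion_from_mask <- function(mask, grid, alpha = 0) {
  w <- as.numeric(mask) != 0
  if (!any(w)) stop("empty inclusion mask")
  xyz <- grid_centers(grid)
  c0 <- colMeans(xyz[w, , drop = FALSE])
  vol <- sum(w) * prod(grid$spacing)
  r0 <- (3 * vol / (4 * pi))^(1 / 3)
  sphere_inclusion(c0, r0, alpha)
}
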