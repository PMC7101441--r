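#' Peritumoural shell region of interest
#'
#' The spherical-shell ROI over which stiffness heterogeneity is measured:
#' inner radius `r0 + 3 * spacing` (standing off the inclusion edge by the
#' reconstruction-window radius), width `4 * spacing`. Membership is decided
#' by the voxel-centre distance from the inclusion centre in world mm. If
#' the shell is clipped by the volume edge the surviving voxels are kept and
#' a warning is emitted.
#'
#' @param grid an [acquisition_grid()] (isotropic spacing expected).
#' @param inclusion a [sphere_inclusion()].
#' @return An object of class `"shell_roi"`: list with `index` (linear voxel
#'   indices), `inner_radius`, `outer_radius` (mm), `center`, `grid`.
#' @export
build_roi <- function(grid, inclusion) {
  if (diff(range(grid$spacing)) > 1e-9)
    warning("anisotropic spacing: ROI pixel offsets use the first-axis spacing")
  delta <- grid$spacing[1]
  inner <- inclusion$r0 + 3 * delta
  outer <- inner + 4 * delta
  r <- grid_radius(grid, inclusion$center)
  idx <- which(r >= inner & r < outer)
  # expected count for an unclipped shell, from the bounding sphere extents
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  if (any(inclusion$center - outer < lo) || any(inclusion$center + outer > hi))
    warning("shell ROI clipped by the volume edge; using the surviving voxels")
  if (length(idx) == 0)
    stop("empty shell ROI: inclusion geometry incompatible with the grid")
  structure(list(index = idx, inner_radius = inner, outer_radius = outer,
                 center = inclusion$center, grid = grid),
            class = "shell_roi")
}

#' @export
print.shell_roi <- function(x, ...) {
  cat(sprintf("<shell_roi> [%.3g, %.3g) mm, %d voxels\n",
              x$inner_radius, x$outer_radius, length(x$index)))
  invisible(x)
}

#' Stiffness heterogeneity over the shell ROI
#'
#' Population standard deviation of the storage modulus `G'` (real part
#' only) over the valid ROI voxels.
#'
#' @param elastogram an elastogram from [reconstruct()].
#' @param roi a [build_roi()] result on the same grid.
#' @return Standard deviation in Pa.
#' @export
roi_std <- function(elastogram, roi) {
  g <- elastogram$G_star[roi$index]
  ok <- elastogram$valid[roi$index] & !is.na(g)
  g <- Re(g[ok])
  if (length(g) < 2) stop("degenerate ROI: fewer than 2 valid voxels")
  sqrt(mean((g - mean(g))^2))
}

#' Closed-form inclusion pressure of the inflating-sphere model
#'
#' Total inclusion pressure implied by an incompressible neo-Hookean medium
#' inflated with scaling `alpha`, obtained by integrating the radial
#' equilibrium stress from the inclusion surface to infinity:
#' \deqn{p_{inc}(\alpha) = 2\mu_e\Big(\frac{5}{4}
#'   - \frac{(1-\alpha)^4 + 4(1-\alpha)}{4}\Big).}
#' Zero at `alpha = 0`, negative for `alpha < 0` (pulling), increasing to
#' `2.5 mu_e` as `alpha -> 1`.
#'
#' @param alpha inflation scaling(s), < 1.
#' @param mu_e intrinsic (not frequency-dependent) shear modulus, Pa.
#' @return Pressure in Pa.
#' @export
pressure_from_alpha <- function(alpha, mu_e) {
  if (any(alpha >= 1)) stop("'alpha' must be < 1")
  if (mu_e <= 0) stop("'mu_e' must be > 0")
  b <- 1 - alpha
  2 * mu_e * (5 / 4 - (b^4 + 4 * b) / 4)
}

#' Radial-stress integrand of the inflating-sphere model
#'
#' The derivative `d sigma_rr / d r = 2 mu_e (r^6 - R^6) / (r^5 R^2)` with
#' `R^3 = r^3 + (1-alpha)^3 r0^3 - r0^3`, exposed so the closed form
#' [pressure_from_alpha()] can be checked against direct quadrature.
#'
#' @param r current radius (mm), vectorised.
#' @param r0 inclusion radius (mm).
#' @param alpha inflation scaling, < 1.
#' @param mu_e shear modulus, Pa.
#' @return Integrand values (Pa per mm).
#' @export
radial_stress_derivative <- function(r, r0, alpha, mu_e) {
  R <- reference_radius(r, r0, alpha)
  2 * mu_e * (r^6 - R^6) / (r^5 * R^2)
}

# default sweep grid; the alpha = 1 endpoint is clamped just below 1 to
# avoid the R -> 0 singularity at the inclusion surface
default_alpha_grid <- function(from = -0.2, to = 1, by = 0.01) {
  g <- seq(from, to, by = by)
  g[g >= 1] <- 1 - 1e-6
  g
}

#' Deformation-scaling sweep and pressure estimate
#'
#' The core estimation loop: for every candidate inflation scaling `alpha`,
#' build the analytic spherical deformation field, reconstruct the
#' deformation-corrected stiffness in the peritumoural shell, and record the
#' heterogeneity std(G'). The selected `alpha` minimizes the heterogeneity
#' (ties broken toward the smaller, i.e. more conservative, pressure) and is
#' converted to an inclusion pressure by the closed-form inflating-sphere
#' model. Reconstruction is restricted to the shell ROI voxels; deformation
#' and wave-gradient fields are built on a bounding box around the ROI
#' dilated by the reconstruction window.
#'
#' @param wave a [wave_field()].
#' @param inclusion a [sphere_inclusion()] (its `alpha` slot is ignored).
#' @param mu_e intrinsic shear modulus (Pa) used for the pressure conversion.
#'   If `NULL`, the median reconstructed background `G'` in a far-field
#'   shell beyond the ROI is used as a stand-in, with a warning (an explicit
#'   `mu_e` is preferred: the pressure model is frequency-independent).
#' @param alpha_grid strictly increasing candidate scalings, all < 1
#'   (default -0.2 to 1 in steps of 0.01, endpoint clamped below 1).
#' @param smooth_sigma Gaussian smoothing (voxels) applied to each
#'   reconstruction before the heterogeneity measure; default 0 (none).
#' @param window_radius reconstruction window half-width in voxels.
#' @param verbose print one progress line per alpha.
#' @return An object of class `"mre_pressure"` with fields `alpha_min`,
#'   `p_inc` (Pa), `mu_e`, `curve` (data.frame: alpha, sd_gprime, n_valid),
#'   `roi`, `elastogram` (at `alpha_min`), `mu_e_source`.
#' @export
alpha_sweep <- function(wave, inclusion, mu_e = NULL,
                        alpha_grid = default_alpha_grid(),
                        smooth_sigma = 0, window_radius = 3L,
                        verbose = FALSE) {
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("'alpha_grid' must be strictly increasing")
  if (any(alpha_grid >= 1)) stop("all alpha values must be < 1")
  grid <- wave$grid
  roi <- build_roi(grid, inclusion)
  # bounding box: ROI outer radius + window + smoothing + gradient stencil
  margin <- (window_radius + 3L + ceiling(3 * smooth_sigma)) * grid$spacing
  lo <- floor((inclusion$center - roi$outer_radius - margin - grid$origin) /
                grid$spacing) + 1
  hi <- ceiling((inclusion$center + roi$outer_radius + margin - grid$origin) /
                  grid$spacing) + 1
  box <- subgrid_box(grid, lo, hi)
  bwave <- wave_field(wave$v[box$index, , drop = FALSE], box$grid,
                      wave$frequency, wave$rho,
                      array(wave$support[box$index], dim = box$grid$shape))
  # ROI targets in box-local linear indices
  loc <- match(roi$index, box$index)
  if (anyNA(loc)) stop("ROI extends outside the reconstruction bounding box")
  # targets for reconstruction: the ROI itself, dilated when smoothing needs
  # a neighbourhood of valid values around each ROI voxel
  if (smooth_sigma > 0) {
    rbox <- grid_radius(box$grid, inclusion$center)
    pad <- ceiling(3 * smooth_sigma) * box$grid$spacing[1]
    targ <- which(rbox >= roi$inner_radius - pad & rbox < roi$outer_radius + pad)
  } else targ <- loc
  # alpha-independent pieces, computed once: the wave gradient and the set
  # of voxels any target window can reach (tensor algebra is restricted to
  # those)
  grad <- wave_gradient(bwave)
  rbox2 <- grid_radius(box$grid, inclusion$center)
  reach <- max(rbox2[targ]) + (window_radius + 0.5) * sqrt(3) * box$grid$spacing[1]
  subset <- which(as.numeric(rbox2) <= reach & as.numeric(rbox2) >= inclusion$r0)
  sd_curve <- rep(NA_real_, length(alpha_grid))
  n_valid <- integer(length(alpha_grid))
  best <- NULL
  for (ia in seq_along(alpha_grid)) {
    a <- alpha_grid[ia]
    t0 <- proc.time()[3]
    dv <- build_deformation_volume(box$grid,
                                   sphere_inclusion(inclusion$center,
                                                    inclusion$r0, a),
                                   hprime = FALSE)
    el <- reconstruct(bwave, dv, window_radius = window_radius, targets = targ,
                      gradient = grad, tensor_subset = subset)
    if (smooth_sigma > 0) el <- smooth_elastogram(el, smooth_sigma)
    nv <- sum(el$valid[loc])
    n_valid[ia] <- nv
    if (nv < 0.5 * length(loc)) {
      warning(sprintf("alpha = %.3g: reconstruction failed on > 50%% of ROI voxels; dropped",
                      a))
      next
    }
    roi_loc <- structure(list(index = loc, inner_radius = roi$inner_radius,
                              outer_radius = roi$outer_radius,
                              center = roi$center, grid = box$grid),
                         class = "shell_roi")
    sd_curve[ia] <- roi_std(el, roi_loc)
    if (verbose)
      message(sprintf("alpha = %+.2f  roi voxels = %4d  std(G') = %9.3f Pa  (%.2fs)",
                      a, nv, sd_curve[ia], proc.time()[3] - t0))
    if (is.null(best) || sd_curve[ia] < best$sd)
      best <- list(alpha = a, sd = sd_curve[ia], el = el)
  }
  if (is.null(best)) stop("reconstruction failed at every alpha")
  mu_src <- "user"
  if (is.null(mu_e)) {
    mu_e <- background_mu_e(wave, inclusion, roi, window_radius)
    mu_src <- "background G' (far-field median); prefer an explicit mu_e"
    warning("mu_e not supplied: using median far-field background G' as a stand-in")
  }
  structure(list(alpha_min = best$alpha,
                 p_inc = pressure_from_alpha(best$alpha, mu_e),
                 mu_e = mu_e, mu_e_source = mu_src,
                 curve = data.frame(alpha = alpha_grid, sd_gprime = sd_curve,
                                    n_valid = n_valid),
                 roi = roi, elastogram = best$el,
                 frequency = wave$frequency),
            class = "mre_pressure")
}

# median background G' in a far-field shell beyond the ROI (standard
# reconstruction, no deformation correction)
background_mu_e <- function(wave, inclusion, roi, window_radius = 3L) {
  grid <- wave$grid
  delta <- grid$spacing[1]
  r <- grid_radius(grid, inclusion$center)
  idx <- which(r >= roi$outer_radius + 2 * delta &
                 r < roi$outer_radius + 6 * delta)
  el <- reconstruct(wave, NULL, window_radius = window_radius, targets = idx)
  g <- Re(el$G_star[idx][el$valid[idx]])
  if (length(g) < 2) stop("cannot estimate background stiffness: no valid far-field voxels")
  stats::median(g)
}
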