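#' Material model for wave propagation
#'
#' @param G_star complex shear modulus `G' + i G''` (Pa) governing wave
#'   propagation at the vibration frequency; `G' > 0`, `G'' >= 0`.
#' @param mu_e intrinsic (static) shear modulus (Pa), used by the pressure
#'   model; defaults to `Re(G_star)`.
#' @param rho density (kg/m^3); default 1000 (water).
#' @return An object of class `"material_model"`.
#' @export
material_model <- function(G_star = 1500 + 200i, mu_e = Re(G_star), rho = 1000) {
  if (Re(G_star) <= 0 || Im(G_star) < 0)
    stop("need G' > 0 and G'' >= 0")
  if (mu_e <= 0 || rho <= 0) stop("'mu_e' and 'rho' must be > 0")
  structure(list(G_star = G_star, mu_e = mu_e, rho = rho),
            class = "material_model")
}

#' Configuration of a synthetic MRE experiment
#'
#' Desk-scale stand-in for a cluster FEM wave simulation: a time-harmonic
#' viscoelastic wave solve on a uniform grid, where a pressurized spherical
#' inclusion deforms the medium (analytic incompressible inflation with
#' scaling `alpha_true`), the deformation enters the wave operator through
#' the same fourth-order tensor `H'` used by the inversion, and the
#' inclusion interior is a non-wave-supporting void. Defaults follow the
#' reference configuration: 100 Hz, `G* = 1.5 + 0.2i kPa`, 50 mm cube at
#' 1 mm isotropic resolution, 4 mm inclusion.
#'
#' @param shape voxels per axis (scalar or length 3); the grid is centred on
#'   the world origin.
#' @param spacing voxel spacing, mm.
#' @param material a [material_model()].
#' @param inclusion a [sphere_inclusion()] or `NULL` for a homogeneous
#'   medium; its `alpha` slot is the true inflation scaling.
#' @param alpha_true convenience override for the inclusion's scaling.
#' @param frequency vibration frequency, Hz.
#' @param source_face face at which the polarized body-force source slab
#'   sits: one of `"x-"`, `"x+"`, `"y-"`, `"y+"`, `"z-"`, `"z+"`.
#' @param amplitude approximate radiated displacement amplitude, m.
#' @param polarization source polarization (3-vector, normalised internally).
#' @param penalty_ratio incompressibility penalty relative to `|G*|`
#'   (>= 1e3; the pressure unknown is never materialized).
#' @param void logical: model the inclusion interior as a void (shear
#'   stiffness scaled to ~0, excluded from the wave support).
#' @param tol,maxit relative-residual tolerance and iteration cap of the
#'   preconditioned GMRES solve.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(shape = 50, spacing = 1,
                              material = material_model(),
                              inclusion = sphere_inclusion(c(0, 0, 0), 4),
                              alpha_true = NULL,
                              frequency = 100,
                              source_face = "x-",
                              amplitude = 1e-5,
                              polarization = c(0, 0, 1),
                              penalty_ratio = 1e4,
                              void = TRUE,
                              tol = 1e-6, maxit = 400) {
  grid <- centered_grid(shape, spacing)
  if (!is.null(alpha_true) && !is.null(inclusion))
    inclusion <- sphere_inclusion(inclusion$center, inclusion$r0, alpha_true)
  if (penalty_ratio < 1e3) stop("'penalty_ratio' must be >= 1e3")
  lambda_m <- sqrt(Re(material$G_star) / material$rho) / frequency
  vox_per_wl <- lambda_m / (mean(grid$spacing) * 1e-3)
  if (vox_per_wl < 6)
    stop(sprintf("under-resolved shear wavelength: %.1f voxels per wavelength (need >= 6)",
                 vox_per_wl))
  if (!source_face %in% c("x-", "x+", "y-", "y+", "z-", "z+"))
    stop("invalid 'source_face'")
  pol <- polarization / sqrt(sum(polarization^2))
  structure(list(grid = grid, material = material, inclusion = inclusion,
                 frequency = frequency, source_face = source_face,
                 amplitude = amplitude, polarization = pol,
                 penalty_ratio = penalty_ratio, void = void,
                 tol = tol, maxit = maxit),
            class = "simulation_config")
}

# periodic symbol of the 4th-order central first-derivative stencil
stencil_symbol <- function(n, h) {
  th <- 2 * pi * (0:(n - 1)) / n
  (8 * sin(th) - sin(2 * th)) / (6 * h)
}

#' Simulate steady-state MRE wave data
#'
#' Solves the time-harmonic viscoelastic equation
#' `rho w^2 v + div(G* (H'(F(x)) : grad v)) + grad(lambda div v) = -f`
#' on the uniform grid with fourth-order finite differences and periodic
#' boundaries, driven by a polarized, Gaussian-tapered body-force slab at
#' the chosen face. Near-incompressibility is enforced by the penalty term
#' (`lambda = penalty_ratio * |G*|`; the pressure unknown is never
#' materialized), and void voxels carry (near-)zero shear stiffness,
#' penalty and inertia, making the inclusion interior a traction-free
#' non-wave-supporting region. The complex system is solved matrix-free by
#' restarted GMRES, preconditioned with the
#' FFT-diagonalized constant-coefficient operator, which is exact for the
#' homogeneous background so the iteration only has to resolve the compact
#' inclusion/deformation perturbation. Wrapped (periodic) wave arrivals play
#' the role of the reflections present in any finite experiment; they
#' satisfy the same local wave equation and do not bias the inversion.
#'
#' @param config a [simulation_config()].
#' @param verbose print solver progress.
#' @return A [wave_field()] with `support` `FALSE` inside the void, and
#'   attributes `alpha_true`, `iterations`, `residual`.
#' @export
simulate_waves <- function(config, verbose = FALSE) {
  grid <- config$grid
  n <- grid$shape
  N <- prod(n)
  mat <- config$material
  om <- 2 * pi * config$frequency
  hm <- grid$spacing * 1e-3
  # deformation-modified stiffness tensor volume
  if (!is.null(config$inclusion)) {
    dv <- build_deformation_volume(grid, config$inclusion, hprime = TRUE)
    H <- dv$Hprime
    void <- !dv$mask & config$void
  } else {
    H <- hprime_volume(matrix(rep(as.numeric(diag(3)), each = 1), 1, 9))
    H <- H[rep(1L, N), , drop = FALSE]
    void <- array(FALSE, dim = n)
  }
  # void shear stiffness: smoothly ramped to ~0 over ~1.5 voxels so the
  # coefficient jump does not scatter energy into the parasitic high-k band
  # of the wide difference stencil (whose symbol re-crosses the shear
  # wavenumber near the grid Nyquist)
  eps_void <- 0.01
  scale <- rep(1, N)
  if (any(void)) {
    r <- as.numeric(grid_radius(grid, config$inclusion$center))
    w <- 1.5 * mean(grid$spacing)
    # transition strictly inside r0: every voxel the inversion can read
    # (r >= r0) carries the exact modelled coefficients
    s01 <- pmin(pmax((r - (config$inclusion$r0 - w)) / w, 0), 1)
    s01 <- s01^2 * (3 - 2 * s01)  # smoothstep
    scale <- eps_void + (1 - eps_void) * s01
  }
  gre <- Re(mat$G_star) * scale
  gim <- Im(mat$G_star) * scale
  # the penalty is scaled down inside the void as well: the interior
  # transmits neither shear nor pressure, so the inclusion surface is
  # (near-)traction-free -- the boundary condition the windowed inversion
  # is exactly consistent with when its windows clip at the surface
  lam <- config$penalty_ratio * Mod(mat$G_star) * scale
  # body-force source: a spectrally tapered (Gaussian, sigma = 1.5 voxels)
  # slab near the requested face; the taper leaves the parasitic band of the
  # discrete symbol unexcited. Scaled so the radiated wave has roughly the
  # requested displacement amplitude.
  ax <- match(substr(config$source_face, 1, 1), c("x", "y", "z"))
  side <- substr(config$source_face, 2, 2)
  sig_src <- 1.5
  # centre the slab on the periodic seam at the requested face: this is the
  # point of maximum wrap distance from the domain centre, so the force
  # support (where the homogeneous wave equation does not hold) stays as far
  # from the inclusion and shell ROI as the box allows
  i0 <- if (side == "-") 1 else n[ax]
  d <- seq_len(n[ax]) - i0
  d <- pmin(abs(d), n[ax] - abs(d))
  prof <- exp(-d^2 / (2 * sig_src^2))
  prof <- prof / sum(prof) * 2
  profN <- switch(ax,
                  rep(prof, times = n[2] * n[3]),
                  rep(rep(prof, each = n[1]), times = n[3]),
                  rep(prof, each = n[1] * n[2]))
  k0 <- om * sqrt(mat$rho / mat$G_star)
  f0 <- config$amplitude * 2 * Mod(k0) * Mod(mat$G_star) / (2 * hm[ax])
  b <- matrix(0 + 0i, N, 3)
  for (c in 1:3) b[, c] <- -f0 * config$polarization[c] * profN
  rho_om2 <- mat$rho * om^2
  # the void carries no material at all: its inertia is ramped down with
  # the same profile as its stiffness and penalty, so the inclusion surface
  # is loaded by neither elastic stress nor the reaction of an interior mass
  rho_vox <- rho_om2 * scale
  Afun <- function(v) {
    y <- cpp_sim_matvec(Re(v), Im(v), H, gre, gim, lam, n, hm, rho_vox)
    y$re + 1i * y$im
  }
  # FFT preconditioner: exact inverse of the periodic constant-coefficient
  # background operator
  s1 <- stencil_symbol(n[1], hm[1]); s2 <- stencil_symbol(n[2], hm[2])
  s3 <- stencil_symbol(n[3], hm[3])
  S1 <- array(rep(s1, times = n[2] * n[3]), dim = n)
  S2 <- array(rep(rep(s2, each = n[1]), times = n[3]), dim = n)
  S3 <- array(rep(s3, each = n[1] * n[2]), dim = n)
  ss <- S1^2 + S2^2 + S3^2
  a_sym <- rho_om2 - mat$G_star * ss
  c_sym <- -(mat$G_star / 3 + config$penalty_ratio * Mod(mat$G_star))
  denom <- a_sym + c_sym * ss
  Pfun <- function(r) {
    Rh <- lapply(1:3, function(c) stats::fft(array(r[, c], dim = n)))
    sr <- S1 * Rh[[1]] + S2 * Rh[[2]] + S3 * Rh[[3]]
    fac <- (c_sym / denom) * sr
    out <- matrix(0 + 0i, N, 3)
    Sl <- list(S1, S2, S3)
    for (c in 1:3) {
      u <- (Rh[[c]] - fac * Sl[[c]]) / a_sym
      out[, c] <- as.vector(stats::fft(u, inverse = TRUE)) / N
    }
    out
  }
  # forward application of the background symbol (used to map a warm-start
  # displacement into the right-preconditioned variable)
  Mfun <- function(v) {
    Vh <- lapply(1:3, function(c) stats::fft(array(v[, c], dim = n)))
    sv <- S1 * Vh[[1]] + S2 * Vh[[2]] + S3 * Vh[[3]]
    out <- matrix(0 + 0i, N, 3)
    Sl <- list(S1, S2, S3)
    for (c in 1:3) {
      u <- a_sym * Vh[[c]] + c_sym * Sl[[c]] * sv
      out[, c] <- as.vector(stats::fft(u, inverse = TRUE)) / N
    }
    out
  }
  # two-grid warm start: large refinable inclusion runs are first solved on
  # the stride-2 coarser grid (cheap) and prolonged by Fourier zero-padding
  z0 <- NULL
  coarse_ok <- !is.null(config$inclusion) && all(n %% 2L == 0L) &&
    prod(n) > 150000 &&
    sqrt(Re(mat$G_star) / mat$rho) / config$frequency /
      (mean(grid$spacing) * 2e-3) >= 6
  if (coarse_ok) {
    ccfg <- config
    ccfg$grid <- centered_grid(n %/% 2L, grid$spacing * 2)  # same world centre
    ccfg$tol <- 1e-3
    cwv <- simulate_waves(ccfg, verbose = verbose)
    Lmm <- n * grid$spacing
    shift <- (grid$origin - cwv$grid$origin) / Lmm
    v0 <- prolong_field(cwv$v, n %/% 2L, n, shift = shift)
    z0 <- Mfun(v0)
  }
  sol <- gmres_complex(function(z) Afun(Pfun(z)), b,
                       tol = config$tol, maxit = config$maxit,
                       restart = 30L, x0 = z0, verbose = verbose)
  v <- Pfun(sol$x)
  if (!sol$converged)
    warning(sprintf("wave solve did not reach tol: relative residual %.3g after %d iterations",
                    sol$relres, sol$iter))
  wv <- wave_field(v, grid, config$frequency, mat$rho,
                   support = array(!as.logical(void), dim = n))
  attr(wv, "alpha_true") <- if (is.null(config$inclusion)) 0 else config$inclusion$alpha
  attr(wv, "iterations") <- sol$iter
  attr(wv, "residual") <- sol$relres
  wv
}

# restarted GMRES for complex operators acting on N x 3 matrices; op
# includes any preconditioning. Basis vectors are stored as columns of one
# complex matrix so the Gram-Schmidt projections run through BLAS (classical
# Gram-Schmidt with one reorthogonalization).
gmres_complex <- function(op, b, tol = 1e-6, maxit = 400, restart = 60L,
                          x0 = NULL, verbose = FALSE) {
  dims <- dim(b)
  n <- length(b)
  nrm <- function(x) sqrt(sum(Re(Conj(x) * x)))
  bn <- nrm(b)
  x <- if (is.null(x0)) complex(n) else as.vector(x0)
  opv <- function(z) as.vector(op(matrix(z, dims[1], dims[2])))
  bv <- as.vector(b)
  it <- 0
  relres <- 1
  repeat {
    r <- bv - if (it == 0 && is.null(x0)) 0 else opv(x)
    beta <- nrm(r)
    relres <- beta / bn
    if (relres < tol || it >= maxit) break
    m <- min(restart, maxit - it)
    V <- matrix(0 + 0i, n, m + 1)
    H <- matrix(0 + 0i, m + 1, m)
    V[, 1] <- r / beta
    j <- 0
    while (j < m) {
      j <- j + 1
      it <- it + 1
      w <- opv(V[, j])
      # classical Gram-Schmidt with one reorthogonalization; unused columns
      # of V are zero, so full-width BLAS products avoid per-iteration copies
      h <- Conj(crossprod(V, Conj(w))[, 1])
      w <- w - (V %*% h)[, 1]
      h2 <- Conj(crossprod(V, Conj(w))[, 1])
      w <- w - (V %*% h2)[, 1]
      h <- h + h2
      H[seq_len(j), j] <- h[seq_len(j)]
      H[j + 1, j] <- nrm(w)
      if (Mod(H[j + 1, j]) < 1e-300) break
      V[, j + 1] <- w / H[j + 1, j]
      e1 <- c(beta, rep(0 + 0i, j))
      y <- qr.solve(H[seq_len(j + 1), seq_len(j), drop = FALSE], e1)
      res_j <- sqrt(sum(Mod(e1 - H[seq_len(j + 1), seq_len(j), drop = FALSE] %*% y)^2))
      if (verbose && it %% 10 == 0)
        message(sprintf("  gmres iter %3d: relres %.3e", it, res_j / bn))
      if (res_j / bn < tol) break
    }
    e1 <- c(beta, rep(0 + 0i, j))
    y <- qr.solve(H[seq_len(j + 1), seq_len(j), drop = FALSE], e1)
    x <- x + V[, seq_len(j), drop = FALSE] %*% y
    x <- as.vector(x)
  }
  list(x = matrix(x, dims[1], dims[2]), iter = it, relres = relres,
       converged = relres < tol)
}

# Fourier zero-padding prolongation of a periodic field from a coarse grid
# (shape nc) to a fine grid (shape nf = 2*nc over the same world domain):
# exact for band-limited fields. shift (in fractions of the domain per axis)
# realigns the first-sample offset between the two grids. Used to warm-start
# fine wave solves from a coarse one.
prolong_field <- function(v, nc, nf, shift = c(0, 0, 0)) {
  half <- nc %/% 2
  freq <- function(n) { f <- 0:(n - 1); f[f > n / 2] <- f[f > n / 2] - n; f }
  out <- matrix(0 + 0i, prod(nf), ncol(v))
  ph <- lapply(1:3, function(a) exp(2i * pi * freq(nc[a]) * shift[a]))
  phase <- outer(outer(ph[[1]], ph[[2]]), ph[[3]])
  lo <- lapply(1:3, function(a) 1:half[a])
  hi_f <- lapply(1:3, function(a) (nf[a] - half[a] + 1):nf[a])
  hi_c <- lapply(1:3, function(a) (nc[a] - half[a] + 1):nc[a])
  for (c in seq_len(ncol(v))) {
    vh <- stats::fft(array(v[, c], dim = nc)) * phase
    fh <- array(0 + 0i, dim = nf)
    for (s1 in 1:2) for (s2 in 1:2) for (s3 in 1:2) {
      src <- list(if (s1 == 1) lo[[1]] else hi_c[[1]],
                  if (s2 == 1) lo[[2]] else hi_c[[2]],
                  if (s3 == 1) lo[[3]] else hi_c[[3]])
      dst <- list(if (s1 == 1) lo[[1]] else hi_f[[1]],
                  if (s2 == 1) lo[[2]] else hi_f[[2]],
                  if (s3 == 1) lo[[3]] else hi_f[[3]])
      fh[dst[[1]], dst[[2]], dst[[3]]] <- vh[src[[1]], src[[2]], src[[3]]]
    }
    out[, c] <- as.vector(stats::fft(fh, inverse = TRUE)) / prod(nc)
  }
  out
}

#' Add uniform measurement noise to wave data
#'
#' Adds independent uniform noise on each of the six real scalar components
#' (real and imaginary parts of the three displacement components) at every
#' voxel. The noise bound is `n0 = level * max(|component|)` where the
#' maximum is taken over the ROI voxels (or the whole support when no ROI
#' is given), matching how acquisition noise is referenced to the peak wave
#' amplitude near the inclusion.
#'
#' @param wave a [wave_field()].
#' @param level noise level as a fraction of the maximum ROI amplitude
#'   (e.g. 0.05, 0.10, 0.15).
#' @param roi optional [build_roi()] result defining the reference region.
#' @param seed integer seed; the same seed reproduces the noise exactly.
#' @return A noisy [wave_field()].
#' @export
add_noise <- function(wave, level, roi = NULL, seed = 1L) {
  if (level < 0) stop("'level' must be >= 0")
  if (level == 0) return(wave)
  idx <- if (is.null(roi)) which(as.logical(wave$support)) else roi$index
  comp6 <- cbind(Re(wave$v[idx, , drop = FALSE]), Im(wave$v[idx, , drop = FALSE]))
  n0 <- level * max(abs(comp6))
  n <- nrow(wave$v)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  eta <- matrix(stats::runif(6 * n, -n0, n0), n, 6)
  v <- wave$v + (eta[, 1:3] + 1i * eta[, 4:6])
  out <- wave_field(v, wave$grid, wave$frequency, wave$rho, wave$support)
  attr(out, "n0") <- n0
  for (a in c("alpha_true", "iterations", "residual"))
    attr(out, a) <- attr(wave, a)
  out
}

#' Gaussian smoothing of wave data
#'
#' Truncated sampled-Gaussian smoothing (default 3-voxel support, sigma = 1
#' voxel) applied independently to each of the six real scalar wave
#' components, mask-aware at the void boundary (void voxels neither receive
#' nor contribute).
#'
#' @param wave a [wave_field()].
#' @param support odd kernel side length in voxels (default 3).
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @return A smoothed [wave_field()].
#' @export
smooth_waves <- function(wave, support = 3L, sigma = 1) {
  if (support %% 2 != 1) stop("'support' must be odd")
  if (sigma <= 0) stop("'sigma' must be > 0")
  half <- support %/% 2
  axk <- exp(-(-half:half)^2 / (2 * sigma^2))
  kern <- outer(outer(axk, axk), axk)
  kern <- kern / sum(kern)
  dims <- wave$grid$shape
  m <- as.logical(wave$support)
  v <- wave$v
  for (c in 1:3) {
    sr <- cpp_masked_smooth(Re(v[, c]), m, dims, as.numeric(kern),
                            rep(as.integer(support), 3))
    si <- cpp_masked_smooth(Im(v[, c]), m, dims, as.numeric(kern),
                            rep(as.integer(support), 3))
    v[, c] <- complex(real = sr, imaginary = si)
  }
  out <- wave_field(v, wave$grid, wave$frequency, wave$rho, wave$support)
  for (a in c("alpha_true", "iterations", "residual", "n0"))
    attr(out, a) <- attr(wave, a)
  out
}

#' Downsample a wave field to acquisition resolution
#'
#' Reads a finely simulated volume out at the coarser acquisition
#' resolution -- the usual relation between a well-resolved forward
#' simulation and the image an MRE scan produces. `method = "stride"` (the
#' default) takes point samples at every `factor`-th fine voxel centre,
#' which matches the point-sample semantics the local inversion assumes;
#' `"average"` averages each `factor^3` block (closer to the volume
#' integration an imaging voxel performs, but it filters the steep
#' peritumoural stiffness gradients and measurably biases the recovered
#' inflation upward, so it is not the default). A coarse voxel is
#' part of the wave support only if its entire fine block is (partial-volume
#' voxels at the void edge are excluded rather than returned contaminated).
#'
#' @param wave a [wave_field()].
#' @param factor integer downsampling factor per axis (e.g. 2: 0.5 mm to 1 mm).
#' @param method `"average"` (voxel-volume averaging) or `"stride"` (point
#'   samples).
#' @return A [wave_field()] on the coarser grid.
#' @export
downsample_wave <- function(wave, factor = 2L, method = c("stride", "average")) {
  method <- match.arg(method)
  n <- wave$grid$shape
  factor <- as.integer(factor)
  if (method == "stride") {
    idx <- lapply(1:3, function(a) seq.int(1L, n[a], by = factor))
    ns <- vapply(idx, length, 0L)
    grid <- acquisition_grid(ns, wave$grid$spacing * factor, wave$grid$origin)
    lin <- outer(outer(idx[[1]], (idx[[2]] - 1L) * n[1], "+"),
                 (idx[[3]] - 1L) * n[1] * n[2], "+")
    lin <- as.integer(lin)
    v <- wave$v[lin, , drop = FALSE]
    sup <- array(wave$support[lin], dim = ns)
  } else {
    if (any(n %% factor != 0L))
      stop("'average' downsampling needs shape divisible by 'factor'")
    ns <- n %/% factor
    # coarse voxel centre = mean of its fine block's centres
    grid <- acquisition_grid(ns, wave$grid$spacing * factor,
                             wave$grid$origin + (factor - 1) / 2 * wave$grid$spacing)
    blk <- function(x) {
      a <- array(x, dim = c(factor, ns[1], factor, ns[2], factor, ns[3]))
      apply(a, c(2, 4, 6), sum)
    }
    nb <- factor^3
    v <- vapply(1:3, function(c) as.vector(blk(Re(wave$v[, c]))) / nb,
                numeric(prod(ns))) +
      1i * vapply(1:3, function(c) as.vector(blk(Im(wave$v[, c]))) / nb,
                  numeric(prod(ns)))
    sup <- array(as.vector(blk(as.numeric(wave$support))) == nb, dim = ns)
  }
  out <- wave_field(v, grid, wave$frequency, wave$rho, sup)
  for (a in c("alpha_true", "iterations", "residual"))
    attr(out, a) <- attr(wave, a)
  out
}
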