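#' Complex wave-displacement field on a grid
#'
#' Container for the steady-state MRE displacement field: a complex 3-vector
#' per voxel (metres), the acquisition grid, the vibration frequency and the
#' tissue density. The physical field is `Re(v(x) e^{i w t})`.
#'
#' @param v N x 3 complex matrix of displacement amplitudes (m), voxel-major.
#' @param grid an [acquisition_grid()].
#' @param frequency vibration frequency in Hz (> 0).
#' @param rho density in kg/m^3 (default 1000, water).
#' @param support logical array; `FALSE` in void/fluid voxels that carry no
#'   shear wave (default all `TRUE`).
#' @return An object of class `"wave_field"`.
#' @export
wave_field <- function(v, grid, frequency, rho = 1000, support = NULL) {
  n <- grid_nvox(grid)
  if (!is.matrix(v) || nrow(v) != n || ncol(v) != 3L)
    stop("'v' must be an N x 3 matrix matching the grid")
  if (!is.complex(v)) v <- v + 0i
  if (!is.finite(frequency) || frequency <= 0) stop("'frequency' must be > 0")
  if (!is.finite(rho) || rho <= 0) stop("'rho' must be > 0")
  if (is.null(support)) support <- array(TRUE, dim = grid$shape)
  vs <- v[as.logical(support), , drop = FALSE]
  if (any(!is.finite(Re(vs)) | !is.finite(Im(vs))))
    stop("wave displacements must be finite on the support")
  structure(list(v = v, grid = grid, frequency = frequency, rho = rho,
                 support = array(as.logical(support), dim = grid$shape)),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("<wave_field> %s voxels @ %g Hz, max |v| = %.3g m, %d void voxels\n",
              paste(x$grid$shape, collapse = "x"), x$frequency,
              max(Mod(x$v)), sum(!x$support)))
  invisible(x)
}

#' Per-voxel gradient of the wave field
#'
#' Finite-difference gradient `(grad v)_ij = d v_i / d x_j` in SI units
#' (per metre), fourth-order central in the interior, degrading to
#' second-order central and one-sided stencils at the support boundary.
#'
#' @param wave a [wave_field()].
#' @return List with `grad` (N x 9 complex, column index `i + 3(j-1)`) and
#'   `valid` (logical, `FALSE` where no stencil could be formed).
#' @export
wave_gradient <- function(wave) {
  g <- cpp_field_gradient(Re(wave$v), Im(wave$v), as.logical(wave$support),
                          wave$grid$shape, wave$grid$spacing * 1e-3)
  if (!any(g$valid)) stop("insufficient support: no voxel has a valid stencil")
  list(grad = g$re + 1i * g$im, valid = g$valid)
}

# ---- divergence-free test-function kernels -------------------------------

# Coefficient vectors (powers of xi) of the univariate window polynomials
# and their first two derivatives. "b2" = (1-xi^2)^2 vanishes with its first
# derivative at xi = +-1; "b2x" = xi (1-xi^2)^2.
window_poly_coef <- function(kind, order) {
  tab <- list(
    b2  = list(c(1, 0, -2, 0, 1, 0), c(0, -4, 0, 4, 0, 0), c(-4, 0, 12, 0, 0, 0)),
    b2x = list(c(0, 1, 0, -2, 0, 1), c(1, 0, -6, 0, 5, 0), c(0, -12, 0, 20, 0, 0)))
  tab[[kind]][[order + 1]]
}

# Exact-moment quadrature weights on the window nodes xi_j = (-W:W)/W for
# the weighted integral int_{-1}^{1} f(xi) u(xi) dxi: W_j are chosen so the
# rule is exact whenever u is the degree-(2W) interpolant of the data, i.e.
# the analytic test-function factor f is integrated exactly against the
# interpolated field. This removes the quadrature bias that a sampled-value
# product rule would introduce at finite voxels-per-wavelength.
moment_weights <- function(coef, W) {
  xi <- (-W:W) / W
  np <- 2L * W + 1L
  p <- 0:(np - 1)
  # m_p = int xi^p f(xi) dxi
  m <- vapply(p, function(pp) {
    q <- seq_along(coef) - 1
    sum(coef * ifelse((pp + q) %% 2 == 0, 2 / (pp + q + 1), 0))
  }, 0)
  V <- outer(p, xi, function(pp, x) x^pp)
  as.numeric(solve(V, m))
}

# Build the window kernels for the local weak-form inversion: test functions
# w_t = curl(g_t e_i) with separable g_t = P1(xi1) P2(xi2) P3(xi3) built
# from bump polynomials vanishing (with first derivatives) on the window
# boundary, so each w_t is exactly divergence-free and vanishes on the
# boundary -- eliminating the pressure gradient from the weak form. Returns
# per-offset kernels (exact-moment quadrature already folded in) for the
# displacement term (Ka) and the flux term (Kb).
window_kernels <- function(radius = 3L, spacing_m = 1e-3) {
  W <- as.integer(radius)
  offs <- as.matrix(expand.grid(di = -W:W, dj = -W:W, dk = -W:W))
  nq <- nrow(offs)
  sc <- 1 / (W * spacing_m)   # d xi / d x
  # coverage weights (window-quality metric only): product Simpson rule
  np <- 2L * W + 1L
  sw <- rep(c(2, 4), length.out = np); sw[1] <- 1; sw[np] <- 1; sw <- sw / 3
  qw <- sw[offs[, 1] + W + 1] * sw[offs[, 2] + W + 1] * sw[offs[, 3] + W + 1]
  # test-function catalogue: curl direction i, modifier axis (0 = none,
  # else g gains a factor xi_mod)
  cat_i <- rep(1:3, times = 3)
  cat_mod <- c(0, 0, 0, 2, 3, 1, 3, 1, 2)
  Tn <- length(cat_i)
  # per-axis moment-weight vectors, cached by (kind, order)
  wcache <- list()
  axw <- function(kind, order) {
    key <- paste0(kind, order)
    if (is.null(wcache[[key]]))
      wcache[[key]] <<- moment_weights(window_poly_coef(kind, order), W)
    wcache[[key]]
  }
  KaT <- matrix(0, 3 * Tn, nq)
  KbT <- matrix(0, 9 * Tn, nq)
  for (t in seq_len(Tn)) {
    i <- cat_i[t]
    kinds <- ifelse(1:3 == cat_mod[t], "b2x", "b2")
    # kernel of int f u with f = (d^{o1} P1)(d^{o2} P2)(d^{o3} P3)
    kern <- function(ord) {
      v <- axw(kinds[1], ord[1])[offs[, 1] + W + 1] *
           axw(kinds[2], ord[2])[offs[, 2] + W + 1] *
           axw(kinds[3], ord[3])[offs[, 3] + W + 1]
      v * sc^sum(ord)
    }
    dg <- function(a) { d <- c(0, 0, 0); d[a] <- 1; kern(d) }
    d2g <- function(a, b) { d <- c(0, 0, 0); d[a] <- d[a] + 1; d[b] <- d[b] + 1; kern(d) }
    j <- i %% 3 + 1; k <- j %% 3 + 1     # (i, j, k) right-handed cycle
    w <- vector("list", 3)
    w[[j]] <- -dg(k); w[[k]] <- dg(j)    # w = curl(g e_i)
    w[[i]] <- numeric(nq)
    gw <- vector("list", 9)              # (grad w)_{ca} = d w_c / d x_a
    for (c in 1:3) for (a in 1:3) {
      gw[[c + 3 * (a - 1)]] <-
        if (c == j) -d2g(k, a) else if (c == k) d2g(j, a) else numeric(nq)
    }
    for (c in 1:3) KaT[c + 3 * (t - 1), ] <- w[[c]]
    for (cc in 1:9) KbT[cc + 9 * (t - 1), ] <- gw[[cc]]
    # scale both kernels so the flux rows have unit norm (conditioning only;
    # cancels in the per-t ratio, balances the least squares across t)
    s <- sqrt(sum(KbT[(9 * (t - 1) + 1):(9 * t), ]^2))
    KaT[(3 * (t - 1) + 1):(3 * t), ] <- KaT[(3 * (t - 1) + 1):(3 * t), ] / s
    KbT[(9 * (t - 1) + 1):(9 * t), ] <- KbT[(9 * (t - 1) + 1):(9 * t), ] / s
  }
  list(offs = offs, qw = qw, KaT = KaT, KbT = KbT, T = Tn, radius = W)
}

# ---- elastogram ----------------------------------------------------------

new_elastogram <- function(G, valid, grid) {
  structure(list(G_star = array(G, dim = grid$shape),
                 valid = array(valid, dim = grid$shape), grid = grid),
            class = "elastogram")
}

#' @export
print.elastogram <- function(x, ...) {
  v <- x$valid & !is.na(x$G_star)
  cat(sprintf("<elastogram> %s voxels, %d valid; median G* = %.4g + %.4gi Pa\n",
              paste(x$grid$shape, collapse = "x"), sum(v),
              stats::median(Re(x$G_star[v])), stats::median(Im(x$G_star[v]))))
  invisible(x)
}

#' Local inversion of the time-harmonic viscoelastic wave equation
#'
#' Reconstructs a scalar complex shear modulus `G* = G' + i G''` at every
#' requested voxel by a moving-window weak-form least squares. In each
#' window the wave equation `rho w^2 v + div(G* Phi) + grad p = 0` is tested
#' against compactly supported, exactly divergence-free polynomial test
#' functions `w_t` (which eliminates the pressure), integrated by parts once
#' (no second differences of data), and solved for a single `G*` under a
#' local-homogeneity assumption:
#' `G* = rho w^2 (sum_t conj(b_t) a_t) / (sum_t |b_t|^2)` with
#' `a_t = int v . w_t`, `b_t = int Phi : grad w_t`.
#'
#' `Phi` is the flux argument: the plain symmetrised gradient
#' `grad v + (grad v)^T` for the standard isotropic reconstruction
#' (`deform = NULL`), or the deformation-modified gradient `H' : grad v`
#' when a [build_deformation_volume()] result is supplied. At `alpha = 0`
#' the two coincide voxel-for-voxel.
#'
#' @param wave a [wave_field()].
#' @param deform optional `"deformation_tensors"` on the same grid.
#' @param window_radius window half-width in voxels (default 3: a 7^3 window).
#' @param targets optional integer vector of linear voxel indices to
#'   reconstruct (default: every voxel).
#' @param max_void_frac windows whose (quadrature-weighted) overlap with
#'   invalid/void voxels exceeds this fraction are flagged invalid
#'   (default 0.2).
#' @param gradient optional precomputed [wave_gradient()] result (the
#'   gradient is deformation-independent, so sweeps reuse it across alpha).
#' @param tensor_subset optional integer vector of voxel indices on which
#'   the modification tensors are materialized; voxels outside it are
#'   flagged invalid. Used by [alpha_sweep()] to restrict the per-alpha
#'   tensor algebra to the voxels the ROI windows can reach.
#' @return An object of class `"elastogram"`: list with `G_star` (complex
#'   array, `NA` outside `targets` and at invalid voxels), `valid` (logical
#'   array) and `grid`.
#' @export
reconstruct <- function(wave, deform = NULL, window_radius = 3L,
                        targets = NULL, max_void_frac = 0.2,
                        gradient = NULL, tensor_subset = NULL) {
  grid <- wave$grid
  n <- grid_nvox(grid)
  g <- if (is.null(gradient)) wave_gradient(wave) else gradient
  valid <- g$valid
  if (is.null(deform)) {
    A <- g$grad
    # symmetrised gradient: Phi_ik = A_ik + A_ki
    Phi <- A + A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9)]
  } else {
    if (!identical(deform$grid$shape, grid$shape))
      stop("'deform' must live on the wave grid")
    if (is.null(tensor_subset)) {
      H <- deform$Hprime
      if (is.null(H)) H <- hprime_volume(deform$F)
      ph <- cpp_contract_hprime(H, Re(g$grad), Im(g$grad))
      Phi <- ph$re + 1i * ph$im
    } else {
      H <- hprime_volume(deform$F[tensor_subset, , drop = FALSE])
      ph <- cpp_contract_hprime(H,
                                Re(g$grad[tensor_subset, , drop = FALSE]),
                                Im(g$grad[tensor_subset, , drop = FALSE]))
      Phi <- matrix(0 + 0i, n, 9)
      Phi[tensor_subset, ] <- ph$re + 1i * ph$im
      inset <- rep(FALSE, n)
      inset[tensor_subset] <- TRUE
      valid <- valid & inset
    }
    valid <- valid & as.logical(deform$mask)
  }
  if (is.null(targets)) targets <- seq_len(n)
  ker <- window_kernels(window_radius, mean(grid$spacing) * 1e-3)
  acc <- cpp_recon_accumulate(Re(wave$v), Im(wave$v), Re(Phi), Im(Phi),
                              valid, grid$shape, as.integer(targets) - 1L,
                              ker$offs, ker$KaT, ker$KbT, ker$qw, ker$T)
  a <- acc$are + 1i * acc$aim
  b <- acc$bre + 1i * acc$bim
  bn <- rowSums(Re(b)^2 + Im(b)^2)
  num <- rowSums(Conj(b) * a)
  om <- 2 * pi * wave$frequency
  G <- wave$rho * om^2 * num / bn
  ok <- acc$frac >= (1 - max_void_frac) & bn > 0 &
    bn >= 1e-12 * stats::median(bn[bn > 0]) & Re(G) > 0
  ok[is.na(ok)] <- FALSE
  Gv <- rep(NA_complex_, n)
  Vv <- rep(FALSE, n)
  Gv[targets] <- ifelse(ok, G, NA_complex_)
  Vv[targets] <- ok
  new_elastogram(Gv, Vv, grid)
}

#' Gaussian smoothing of an elastogram
#'
#' Mask-weighted Gaussian smoothing of the storage and loss modulus volumes:
#' invalid voxels never bleed into valid ones (the kernel is renormalized
#' over the valid voxels under it). `sigma = 0` is the identity.
#'
#' @param elastogram an elastogram from [reconstruct()].
#' @param sigma Gaussian standard deviation in voxels (>= 0).
#' @return A smoothed elastogram with the same validity mask.
#' @export
smooth_elastogram <- function(elastogram, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(elastogram)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  ax <- -half:half
  k1 <- exp(-ax^2 / (2 * sigma^2))
  kern <- outer(outer(k1, k1), k1)
  kern <- kern / sum(kern)
  dims <- elastogram$grid$shape
  m <- as.logical(elastogram$valid) & !is.na(elastogram$G_star)
  gr <- Re(elastogram$G_star); gi <- Im(elastogram$G_star)
  gr[!m] <- 0; gi[!m] <- 0
  sr <- cpp_masked_smooth(as.numeric(gr), m, dims, as.numeric(kern),
                          rep(2L * half + 1L, 3))
  si <- cpp_masked_smooth(as.numeric(gi), m, dims, as.numeric(kern),
                          rep(2L * half + 1L, 3))
  G <- complex(real = sr, imaginary = si)
  G[!m] <- NA_complex_
  new_elastogram(G, elastogram$valid, elastogram$grid)
}
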