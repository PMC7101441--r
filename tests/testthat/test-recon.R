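test_that("wave gradient is exact for linear fields and accurate for waves", {
  grid <- elastopress:::centered_grid(12, 1)
  xyz <- elastopress:::grid_centers(grid) * 1e-3
  n <- nrow(xyz)
  # constant field -> zero gradient
  wv <- wave_field(matrix(1e-5 + 2e-6i, n, 3), grid, 100)
  g <- wave_gradient(wv)
  expect_lt(max(Mod(g$grad)), 1e-18)
  # linear field v = B x reproduced exactly at every interior voxel
  B <- matrix(rnorm(9), 3, 3) * 1e-3
  wv2 <- wave_field(xyz %*% t(B) + 0i, grid, 100)
  g2 <- wave_gradient(wv2)
  interior <- g2$valid
  for (cc in 1:9) {
    ij <- c((cc - 1) %% 3 + 1, (cc - 1) %/% 3 + 1)
    expect_equal(Re(g2$grad[interior, cc]), rep(B[ij[1], ij[2]], sum(interior)),
                 tolerance = 1e-9)
  }
  # oscillatory field: fourth-order interior accuracy
  k <- 2 * pi * 100 * sqrt(1000 / (1500 + 200i))
  v3 <- cbind(0i * xyz[, 1], 0i * xyz[, 1], 1e-5 * exp(-1i * k * xyz[, 1]))
  wv3 <- wave_field(v3, grid, 100)
  g3 <- wave_gradient(wv3)
  full <- which(array(TRUE, grid$shape) &
                  elastopress:::grid_radius(grid, c(0, 0, 0)) < 3)
  dtrue <- -1i * k * v3[full, 3]   # d v_z / d x lives in column i=3, j=1
  expect_lt(max(Mod(g3$grad[full, 3] - dtrue) / Mod(dtrue)), 5e-3)
})

test_that("isolated voxels are flagged as having insufficient support", {
  grid <- elastopress:::centered_grid(10, 1)
  n <- elastopress:::grid_nvox(grid)
  sup <- array(FALSE, grid$shape)
  sup[5, 5, 5] <- TRUE
  wv <- wave_field(matrix(1e-5 + 0i, n, 3), grid, 100, support = sup)
  expect_error(wave_gradient(wv), "insufficient support")
})

test_that("window test functions are divergence-free with boundary-vanishing bumps", {
  ker <- elastopress:::window_kernels(3L, 1e-3)
  # trace of the flux kernel vanishes identically: the pressure term is
  # eliminated exactly, and the isotropic part of any flux is invisible
  for (t in seq_len(ker$T)) {
    tr <- ker$KbT[1 + 9 * (t - 1), ] + ker$KbT[5 + 9 * (t - 1), ] +
      ker$KbT[9 + 9 * (t - 1), ]
    expect_equal(max(abs(tr)), 0)
  }
  # moment weights integrate f * u exactly for polynomial data u
  w <- elastopress:::moment_weights(elastopress:::window_poly_coef("b2", 0), 3L)
  xi <- (-3:3) / 3
  u <- 1 - 0.3 * xi + 0.7 * xi^2          # arbitrary low-order data
  exact <- integrate(function(x) (1 - x^2)^2 * (1 - 0.3 * x + 0.7 * x^2),
                     -1, 1, rel.tol = 1e-12)$value
  expect_equal(sum(w * u), exact, tolerance = 1e-12)
})

test_that("plane-wave inversion recovers the complex shear modulus", {
  G <- 1500 + 200i
  wv <- plane_wave_field(shape = 40, G_star = G)
  el <- reconstruct(wv)
  r <- elastopress:::grid_radius(wv$grid, c(0, 0, 0))
  interior <- el$valid & r < 12
  expect_gt(sum(interior), 5000)
  expect_lt(abs(median(Re(el$G_star[interior])) / Re(G) - 1), 0.02)
  expect_lt(abs(median(Im(el$G_star[interior])) / Im(G) - 1), 0.05)
  # scaling covariance: a complex amplitude factor leaves G* unchanged
  wv2 <- wave_field(wv$v * (3 - 2i), wv$grid, wv$frequency, wv$rho)
  el2 <- reconstruct(wv2)
  expect_lt(max(Mod(el2$G_star[interior] - el$G_star[interior])), 1e-8)
})

test_that("plane-wave inversion holds in the 210 Hz phantom regime", {
  # 210 Hz, stiffer phantom-like medium, 2 mm voxels: similar voxels per
  # wavelength as the 100 Hz simulation regime
  G <- 11200 + 1500i
  wv <- plane_wave_field(shape = 30, spacing = 2, G_star = G, frequency = 210)
  el <- reconstruct(wv)
  r <- elastopress:::grid_radius(wv$grid, c(0, 0, 0))
  interior <- el$valid & r < 18
  expect_lt(abs(median(Re(el$G_star[interior])) / Re(G) - 1), 0.02)
  expect_lt(abs(median(Im(el$G_star[interior])) / Im(G) - 1), 0.05)
})

test_that("the F = I deformation reduces exactly to the standard inversion", {
  # identical wave data (void in the support for both paths): the only
  # difference is the H'(I) pre-scaling, whose extra isotropic term is
  # invisible to the divergence-free test functions
  grid <- elastopress:::centered_grid(24, 1)
  sup <- array(elastopress:::grid_radius(grid, c(0, 0, 0)) >= 4, grid$shape)
  wv <- plane_wave_field(shape = 24, support = sup)
  el_std <- reconstruct(wv)
  dv0 <- build_deformation_volume(wv$grid, sphere_inclusion(c(0, 0, 0), 4, 0))
  el_mod <- reconstruct(wv, dv0)
  expect_identical(el_std$valid, el_mod$valid)
  both <- el_std$valid & el_mod$valid
  expect_gt(sum(both), 1000)
  expect_lt(max(Mod(el_mod$G_star[both] - el_std$G_star[both]) /
                  Mod(el_std$G_star[both])), 1e-10)
})

test_that("masked voxels never influence valid-voxel estimates", {
  sup <- array(TRUE, c(24, 24, 24))
  sup[10:14, 10:14, 10:14] <- FALSE
  wv <- plane_wave_field(shape = 24, support = sup)
  el1 <- reconstruct(wv)
  v2 <- wv$v
  set.seed(33)
  garbage <- complex(real = rnorm(sum(!sup), 0, 1), imaginary = rnorm(sum(!sup)))
  v2[!sup, ] <- garbage  # recycled across components; values are irrelevant
  wv2 <- wave_field(v2, wv$grid, wv$frequency, wv$rho, sup)
  el2 <- reconstruct(wv2)
  expect_identical(el1$valid, el2$valid)
  ok <- el1$valid
  expect_identical(el1$G_star[ok], el2$G_star[ok])
})

test_that("elastogram smoothing is mask-aware and matches direct convolution", {
  grid <- elastopress:::centered_grid(16, 1)
  n <- elastopress:::grid_nvox(grid)
  set.seed(41)
  G <- complex(real = rnorm(n, 1500, 100), imaginary = rnorm(n, 200, 20))
  el <- elastopress:::new_elastogram(G, rep(TRUE, n), grid)
  # sigma = 0 is the identity
  expect_identical(smooth_elastogram(el, 0), el)
  # constants are preserved under the mask-weighted normalization
  elc <- elastopress:::new_elastogram(rep(1500 + 200i, n), rep(TRUE, n), grid)
  els <- smooth_elastogram(elc, 1)
  expect_equal(els$G_star, elc$G_star, tolerance = 1e-12)
  # single spike: peak matches the truncated, normalized Gaussian kernel
  spike <- rep(0 + 0i, n)
  centre <- which(as.numeric(elastopress:::grid_radius(grid, c(0, 0, 0))) == 0)[1]
  centre <- 8 + 16 * 7 + 256 * 7  # voxel (8,8,8)
  spike[centre] <- 1000 + 0i
  el2 <- elastopress:::new_elastogram(spike, rep(TRUE, n), grid)
  sm <- smooth_elastogram(el2, 1)
  half <- 3L
  axk <- exp(-(-half:half)^2 / 2)
  kern <- outer(outer(axk, axk), axk)
  kern <- kern / sum(kern)
  expect_equal(Re(sm$G_star[8, 8, 8]), 1000 * kern[4, 4, 4], tolerance = 1e-10)
  expect_equal(Re(sm$G_star[9, 8, 8]), 1000 * kern[5, 4, 4], tolerance = 1e-10)
  # invalid voxels do not bleed into valid ones
  vmask <- rep(TRUE, n); vmask[centre] <- FALSE
  el3 <- elastopress:::new_elastogram(ifelse(vmask, 1500 + 0i, 9e9 + 0i),
                                      vmask, grid)
  sm3 <- smooth_elastogram(el3, 1)
  expect_equal(Re(sm3$G_star[9, 8, 8]), 1500, tolerance = 1e-9)
})
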