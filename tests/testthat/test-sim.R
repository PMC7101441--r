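test_that("homogeneous simulation matches the damped plane-wave dispersion", {
  cfg <- simulation_config(shape = 40, inclusion = NULL)
  wv <- simulate_waves(cfg)
  expect_lt(attr(wv, "residual"), 1e-6)
  G <- cfg$material$G_star
  k <- 2 * pi * cfg$frequency * sqrt(cfg$material$rho / G)
  if (Im(k) > 0) k <- -k
  n <- wv$grid$shape
  ax <- elastopress:::grid_axes(wv$grid)
  lin <- function(i, j, kk) i + n[1] * (j - 1) + n[1] * n[2] * (kk - 1)
  vz <- wv$v[lin(1:n[1], n[2] %/% 2, n[3] %/% 2), 3]
  x <- (ax[[1]] - ax[[1]][1]) * 1e-3
  central <- which(seq_len(n[1]) > n[1] / 3 & seq_len(n[1]) <= 2 * n[1] / 3)
  # the periodic steady state is a superposition of the two counter-running
  # damped plane waves with the analytic complex wavenumber
  B <- cbind(exp(-1i * k * x[central]), exp(1i * k * x[central]))
  cf <- qr.solve(B, vz[central])
  relerr <- sqrt(mean(Mod(vz[central] - B %*% cf)^2)) /
    sqrt(mean(Mod(vz[central])^2))
  expect_lt(relerr, 0.05)
  # linearity in the source amplitude
  cfg2 <- simulation_config(shape = 40, inclusion = NULL, amplitude = 3e-5)
  wv2 <- simulate_waves(cfg2)
  expect_equal(wv2$v, wv$v * 3, tolerance = 1e-8)
})

test_that("doubling the stiffness scales the wavelength by sqrt(2)", {
  # wavelength from the measured complex wavenumber: the interior field is
  # a superposition of the two counter-running damped waves, so fit
  # c_f exp(-ikx) + c_b exp(ikx) with k free (amplitudes profiled out)
  wl <- function(gp) {
    cfg <- simulation_config(shape = 48, inclusion = NULL,
                             material = material_model(gp + 0.2e3 * 1i * gp / 1500))
    wv <- simulate_waves(cfg)
    n <- wv$grid$shape
    lin <- function(i, j, kk) i + n[1] * (j - 1) + n[1] * n[2] * (kk - 1)
    vz <- wv$v[lin(1:n[1], n[2] %/% 2, n[3] %/% 2), 3]
    x <- (seq_len(n[1]) - 1) * wv$grid$spacing[1] * 1e-3
    central <- which(seq_len(n[1]) > n[1] / 3 & seq_len(n[1]) <= 2 * n[1] / 3)
    rss <- function(p) {
      k <- complex(real = p[1], imaginary = p[2])
      B <- cbind(exp(-1i * k * x[central]), exp(1i * k * x[central]))
      cf <- qr.solve(B, vz[central])
      sum(Mod(vz[central] - B %*% cf)^2)
    }
    k0 <- 2 * pi * 100 * sqrt(1000 / gp)
    fit <- optim(c(k0 * 1.05, -k0 * 0.1), rss)   # deliberately offset start
    2 * pi / abs(fit$par[1]) * 1000              # wavelength in mm
  }
  ratio <- wl(3000) / wl(1500)
  expect_lt(abs(ratio / sqrt(2) - 1), 0.05)
})

test_that("grid refinement tightens the damped plane-wave dispersion fit", {
  # same physics at 1 mm and 0.5 mm; the interior of each solve is compared
  # with the analytic two-wave (counter-running damped exponential) model.
  # Refinement must not worsen the fit, and the coarse fit is already at
  # the sub-percent level expected of the 4th-order discretization.
  fiterr <- function(shape, spacing) {
    wv <- simulate_waves(simulation_config(shape = shape, spacing = spacing,
                                           inclusion = NULL))
    G <- 1500 + 200i
    k <- 2 * pi * 100 * sqrt(1000 / G)
    if (Im(k) > 0) k <- -k
    n <- wv$grid$shape
    ax <- elastopress:::grid_axes(wv$grid)
    lin <- function(i, j, kk) i + n[1] * (j - 1) + n[1] * n[2] * (kk - 1)
    vz <- wv$v[lin(1:n[1], n[2] %/% 2, n[3] %/% 2), 3]
    x <- (ax[[1]] - ax[[1]][1]) * 1e-3
    central <- which(seq_len(n[1]) > n[1] / 3 & seq_len(n[1]) <= 2 * n[1] / 3)
    B <- cbind(exp(-1i * k * x[central]), exp(1i * k * x[central]))
    cf <- qr.solve(B, vz[central])
    sqrt(mean(Mod(vz[central] - B %*% cf)^2)) / sqrt(mean(Mod(vz[central])^2))
  }
  e_coarse <- fiterr(24, 1)
  e_fine <- fiterr(48, 0.5)
  expect_lt(e_coarse, 0.01)
  expect_lte(e_fine, e_coarse + 1e-4)
})

test_that("uniform noise respects its bound and its seed", {
  wv <- plane_wave_field(shape = 24)
  inc <- sphere_inclusion(c(0, 0, 0), 4)
  roi <- build_roi(wv$grid, inc)
  # level 0 is the identity
  expect_identical(add_noise(wv, 0, roi, seed = 5)$v, wv$v)
  ns <- add_noise(wv, 0.15, roi, seed = 5)
  comp6 <- cbind(Re(wv$v[roi$index, ]), Im(wv$v[roi$index, ]))
  n0 <- 0.15 * max(abs(comp6))
  expect_equal(attr(ns, "n0"), n0)
  eta <- cbind(Re(ns$v - wv$v), Im(ns$v - wv$v))
  expect_lte(max(abs(eta)), n0)
  expect_gt(max(abs(eta)), 0.9 * n0)   # the bound is actually approached
  # determinism: same seed bitwise identical, different seed different
  expect_identical(add_noise(wv, 0.15, roi, seed = 5)$v, ns$v)
  expect_false(identical(add_noise(wv, 0.15, roi, seed = 6)$v, ns$v))
  # the ambient RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(add_noise(wv, 0.1, roi, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("wave smoothing uses the normalized truncated Gaussian", {
  wv <- plane_wave_field(shape = 16)
  n <- elastopress:::grid_nvox(wv$grid)
  # constant field unchanged (unit-sum kernel)
  wc <- wave_field(matrix(2e-5 + 1e-5i, n, 3), wv$grid, 100)
  sm <- smooth_waves(wc, 3, 1)
  expect_equal(sm$v, wc$v, tolerance = 1e-12)
  # kernel weights: centre weight of the 3^3 support, sigma 1 kernel
  spike <- matrix(0 + 0i, n, 3)
  centre <- 8 + 16 * 7 + 256 * 7
  spike[centre, 3] <- 1
  ws <- smooth_waves(wave_field(spike, wv$grid, 100), 3, 1)
  axk <- exp(-c(1, 0, 1) / 2)
  kern <- outer(outer(axk, axk), axk)
  kern <- kern / sum(kern)
  expect_equal(Re(ws$v[centre, 3]), kern[2, 2, 2], tolerance = 1e-12)
  # approximate semigroup: twice sigma 1 vs once sigma sqrt(2) on a smooth
  # field (truncation makes this approximate)
  s2 <- smooth_waves(smooth_waves(wv, 3, 1), 3, 1)
  s12 <- smooth_waves(wv, 5, sqrt(2))
  r <- as.numeric(elastopress:::grid_radius(wv$grid, c(0, 0, 0)))
  mid <- r < 5
  expect_lt(max(Mod(s2$v[mid, 3] - s12$v[mid, 3])) / max(Mod(wv$v[mid, 3])),
            0.05)
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(shape = 40, frequency = 400), "under-resolved")
  expect_error(simulation_config(penalty_ratio = 10), "penalty_ratio")
  expect_error(simulation_config(source_face = "w-"), "source_face")
})
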