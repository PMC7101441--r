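test_that("radial displacement matches the incompressible shell kinematics", {
  # no inflation: R = r everywhere
  expect_equal(radial_displacement(8, 4, 0), 0, tolerance = 1e-12)
  # at the inclusion surface the displacement is alpha * r0
  expect_equal(radial_displacement(4, 4, 0.5), 2)
  # interior point: direct evaluation, frozen after cross-checking with a
  # root solve of r^3 - R^3 = r0^3 - R0^3
  expect_equal(radial_displacement(8, 4, 0.34), 0.2449232, tolerance = 1e-6)
  Rroot <- uniroot(function(R) 8^3 - R^3 - (4^3 - (0.66 * 4)^3),
                   c(6, 8), tol = 1e-12)$root
  expect_equal(radial_displacement(8, 4, 0.34), 8 - Rroot, tolerance = 1e-9)
})

test_that("radial displacement is monotone in alpha and in r, and decays", {
  alphas <- seq(-0.2, 0.9, by = 0.05)
  dr <- vapply(alphas, radial_displacement, 0, r = 6, r0 = 4)
  expect_true(all(diff(dr) > 0))
  rs <- seq(4, 40, by = 2)
  dr_r <- vapply(rs, radial_displacement, 0, r0 = 4, alpha = 0.5)
  expect_true(all(diff(dr_r) < 0))
  expect_lt(radial_displacement(400, 4, 0.5), 1e-3)
})

test_that("radial displacement rejects invalid inputs", {
  expect_error(radial_displacement(3.9, 4, 0.2), "inside the inclusion")
  expect_error(radial_displacement(5, 4, 1), "alpha")
  expect_error(sphere_inclusion(c(0, 0, 0), 4, 1), "alpha")
})

test_that("analytic deformation gradient has the exact spherical structure", {
  inc0 <- sphere_inclusion(c(1, -2, 3), 5, 0)
  expect_equal(deformation_gradient_sphere(c(9, 0, 0), inc0), diag(3),
               tolerance = 1e-12)
  # on the surface: radial eigenvalue (1-a)^2, tangential 1/(1-a)
  a <- 0.3
  inc <- sphere_inclusion(c(0, 0, 0), 4, a)
  F <- deformation_gradient_sphere(c(0, 4, 0), inc)
  ev <- sort(eigen(F, only.values = TRUE)$values)
  expect_equal(ev, sort(c((1 - a)^2, 1 / (1 - a), 1 / (1 - a))),
               tolerance = 1e-10)
  # F^{-1} equals the finite-difference gradient of the current-to-reference
  # map x -> R(r) x / r (independent oracle for the closed form)
  inc <- sphere_inclusion(c(0, 0, 0), 4, 0.4)
  x <- c(5, 2, 1)
  phi <- function(X) {
    r <- sqrt(sum(X^2))
    X / r * elastopress:::reference_radius(r, 4, 0.4)
  }
  eps <- 1e-6
  Gi <- vapply(1:3, function(j) {
    e <- replace(numeric(3), j, eps)
    (phi(x + e) - phi(x - e)) / (2 * eps)
  }, numeric(3))
  expect_equal(solve(deformation_gradient_sphere(x, inc)), Gi,
               tolerance = 1e-7)
  expect_error(deformation_gradient_sphere(c(0, 0, 0), inc), "degenerate")
  expect_error(deformation_gradient_sphere(c(1, 0, 0), inc), "inside")
})

test_that("det F = 1 across the whole alpha sweep grid", {
  grid <- elastopress:::centered_grid(16, 2)
  for (a in c(-0.2, -0.1, 0, 0.34, 0.7, 0.99)) {
    dv <- build_deformation_volume(grid, sphere_inclusion(c(0, 0, 0), 4, a),
                                   hprime = FALSE)
    expect_lt(max(abs(dv$J[as.logical(dv$mask)] - 1)), 1e-9)
  }
})

test_that("F -> I in the far field", {
  inc <- sphere_inclusion(c(0, 0, 0), 4, 0.72)
  F <- deformation_gradient_sphere(c(40, 0, 0), inc)  # r = 10 r0
  expect_lt(norm(F - diag(3), "F"), 0.01)
})

test_that("deformation volume masks the inclusion and is resolution invariant", {
  inc <- sphere_inclusion(c(0, 0, 0), 4, 0.34)
  g1 <- elastopress:::centered_grid(21, 1)
  g2 <- elastopress:::centered_grid(41, 0.5)   # same world extent
  d1 <- build_deformation_volume(g1, inc, hprime = FALSE)
  d2 <- build_deformation_volume(g2, inc, hprime = FALSE)
  r1 <- elastopress:::grid_radius(g1, c(0, 0, 0))
  expect_equal(as.logical(d1$mask), as.numeric(r1) >= 4)
  # voxel centres of the coarse grid that coincide with fine-grid centres
  c1 <- elastopress:::grid_centers(g1)
  c2 <- elastopress:::grid_centers(g2)
  ix <- match(asplit(c1, 1), asplit(c2, 1))
  common <- which(!is.na(ix) & as.logical(d1$mask))
  expect_gt(length(common), 100)
  expect_lt(max(abs(d1$F[common, ] - d2$F[ix[common], ])), 1e-12)
})

test_that("numeric-gradient path reproduces the analytic F for the sphere map", {
  # sample the forward displacement on the REFERENCE grid: u(X) = x(X) - X
  # with r^3 = R^3 + r0^3 - R0^3; then F = I + grad_X u should match the
  # closed form evaluated at the corresponding current position
  grid <- elastopress:::centered_grid(24, 1)
  a <- 0.3; r0 <- 4; R0 <- (1 - a) * r0
  XYZ <- elastopress:::grid_centers(grid)
  R <- sqrt(rowSums(XYZ^2))
  out <- R >= R0
  u <- matrix(0, nrow(XYZ), 3)
  r <- (R[out]^3 + r0^3 - R0^3)^(1 / 3)
  u[out, ] <- XYZ[out, ] / R[out] * (r - R[out])
  dv <- deformation_gradient_numeric(u, grid, mask = array(out, grid$shape))
  inc <- sphere_inclusion(c(0, 0, 0), r0, a)
  mid <- which(R > 6 & R < 9)
  err <- vapply(mid, function(i) {
    xcur <- XYZ[i, ] / R[i] * (R[i]^3 + r0^3 - R0^3)^(1 / 3)
    max(abs(matrix(dv$F[i, ], 3, 3) - deformation_gradient_sphere(xcur, inc)))
  }, 0)
  expect_lt(median(err), 5e-3)
})

test_that("alpha round-trips through the radius parametrization", {
  for (a in c(-0.2, 0, 0.34, 0.9)) {
    inc <- sphere_inclusion(c(0, 0, 0), 4, a)
    expect_equal(alpha_from_radii(inc$r0, inc$R0), a, tolerance = 1e-12)
  }
  expect_equal(alpha_from_radii(4, 4), 0)
  expect_equal(alpha_from_radii(4, 2.64), 0.34)
  expect_equal(alpha_from_radii(4, 0), 1)
})

test_that("inclusion geometry is recovered from a binary mask", {
  grid <- elastopress:::centered_grid(24, 1)
  r <- elastopress:::grid_radius(grid, c(1, 0, -2))
  mask <- r < 4
  inc <- inclusion_from_mask(mask, grid)
  expect_equal(inc$center, c(1, 0, -2), tolerance = 0.15)
  expect_equal(inc$r0, 4, tolerance = 0.15)
})
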