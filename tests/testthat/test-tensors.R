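test_that("PK2 stress matches the neo-Hookean closed form", {
  expect_equal(pk2_elastic(diag(3), 1500), matrix(0, 3, 3))
  # isochoric uniaxial stretch: term-by-term evaluation
  lam <- 1.2
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  C <- diag(c(lam^2, 1 / lam, 1 / lam))
  IC <- sum(diag(C))
  S_ref <- 1500 * (diag(3) - IC / 3 * solve(C))  # J = 1
  S <- pk2_elastic(F, 1500)
  expect_equal(S, S_ref, tolerance = 1e-12)
  expect_equal(S, t(S))
  # isochoric projection: S_e : C = 0
  expect_lt(abs(sum(S * C)), 1e-9)
  for (F in random_unimodular(5, seed = 7)) {
    S <- pk2_elastic(F, 1500)
    expect_lt(abs(sum(S * crossprod(F))), 1e-8 * max(abs(S)))
  }
  expect_error(pk2_elastic(matrix(0, 3, 3), 1), "determinant")
})

test_that("grad_F_Se is the exact derivative of pk2_elastic", {
  # central finite differences as the independent oracle, 100 random
  # unimodular deformation gradients
  eps <- 1e-6
  worst <- 0
  for (F in random_unimodular(100, seed = 11)) {
    D <- grad_F_Se(F, 1500)
    Dfd <- array(0, c(3, 3, 3, 3))
    for (m in 1:3) for (n in 1:3) {
      E <- matrix(0, 3, 3); E[m, n] <- eps
      Dfd[, , m, n] <- (pk2_elastic(F + E, 1500) - pk2_elastic(F - E, 1500)) /
        (2 * eps)
    }
    worst <- max(worst, max(abs(D - Dfd)) / max(abs(Dfd)))
  }
  expect_lt(worst, 1e-4)
  expect_equal(grad_F_Se(diag(3), 0), array(0, c(3, 3, 3, 3)))
})

test_that("H' is independent of the shear modulus and frame indifferent", {
  F <- random_unimodular(1, seed = 3)[[1]]
  H <- hprime_tensor(F)
  for (mu in c(1, 1.5e3, 11.2e3)) {
    # rebuild G'(F, mu)/mu from the pieces and compare
    J <- det(F)
    D <- grad_F_Se(F, mu)
    S <- pk2_elastic(F, mu)
    G <- array(0, c(3, 3, 3, 3))
    for (m in 1:3) for (l in 1:3) {
      M <- matrix(0, 3, 3)
      for (n in 1:3) M <- M + D[, , m, n] * F[l, n]
      G[, , m, l] <- (F %*% M %*% t(F) +
                        diag(3)[, m] %o% (F %*% S %*% t(F))[l, ]) / J
    }
    expect_lt(max(abs(G / mu - H)), 1e-12 * max(abs(H)))
  }
  # frame indifference: H'(Q) is the rotation of H'(I)
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  H0 <- hprime_tensor(diag(3))
  HQ <- hprime_tensor(Q)
  Hrot <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (k in 1:3) for (m in 1:3) for (l in 1:3)
    Hrot[i, k, m, l] <- sum(outer(outer(Q[i, ], Q[k, ]), outer(Q[m, ], Q[l, ])) * H0)
  expect_equal(HQ, Hrot, tolerance = 1e-12)
})

test_that("stretch increases plane-wave stiffness along the stretched axis", {
  # acoustic-tensor oracle: for propagation direction n and polarization p,
  # the directional wave stiffness is p . Q(n) p with
  # Q(n)_ip = H'_ikml n_k n_l contracted appropriately
  lam <- 1.3
  H <- hprime_tensor(diag(c(lam, lam^-0.5, lam^-0.5)))
  wave_stiff <- function(n, p) {
    # flux response to the plane-wave gradient p n^T
    Phi <- Re(modified_gradient(H, p %o% n))
    sum(p * (Phi %*% n))
  }
  along <- wave_stiff(c(1, 0, 0), c(0, 1, 0))  # propagate along stretch
  across <- wave_stiff(c(0, 1, 0), c(1, 0, 0)) # propagate along compressed axis
  expect_gt(along, across)
})

test_that("modified gradient reduces to the symmetrised gradient at F = I", {
  H0 <- hprime_tensor(diag(3))
  set.seed(9)
  # divergence-free complex gradient
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  A[3, 3] <- -A[1, 1] - A[2, 2]
  expect_equal(modified_gradient(H0, A), A + t(A), tolerance = 1e-12)
  expect_equal(modified_gradient(H0, matrix(0, 3, 3)), matrix(0 + 0i, 3, 3))
})

test_that("vectorized H' volume and contraction match the naive loops", {
  Fs <- random_unimodular(4, seed = 13)
  Fmat <- do.call(rbind, lapply(Fs, as.numeric))
  Hvol <- elastopress:::hprime_volume(Fmat)
  set.seed(14)
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  Avol <- matrix(rep(as.numeric(Re(A)), each = 4) +
                   1i * rep(as.numeric(Im(A)), each = 4), 4, 9)
  ph <- elastopress:::cpp_contract_hprime(Hvol, Re(Avol), Im(Avol))
  for (v in seq_along(Fs)) {
    H <- hprime_tensor(Fs[[v]])
    expect_equal(Hvol[v, ], as.numeric(H), tolerance = 1e-12)
    expect_equal(matrix(ph$re[v, ] + 1i * ph$im[v, ], 3, 3),
                 contract_loop(H, A), tolerance = 1e-12)
  }
})
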