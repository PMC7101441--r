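#' Neo-Hookean second Piola-Kirchhoff stress
#'
#' Elastic PK2 stress of the isochoric neo-Hookean law,
#' `S_e = (mu_e / J^(2/3)) (I - (I_C / 3) C^{-1})`, with `C = F^T F`,
#' `I_C = tr(C)`, `J = det F`. `S_e` is symmetric and satisfies the isochoric
#' orthogonality `S_e : C = 0`.
#'
#' @param F 3 x 3 deformation gradient with `det F > 0`.
#' @param mu_e intrinsic shear modulus (Pa).
#' @return 3 x 3 stress matrix (Pa).
#' @export
pk2_elastic <- function(F, mu_e) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("'F' must have positive determinant")
  C <- crossprod(F)
  IC <- sum(diag(C))
  mu_e * J^(-2 / 3) * (diag(3) - IC / 3 * solve(C))
}

#' Derivative of the PK2 stress with respect to the deformation gradient
#'
#' Fourth-order tensor `(grad_F S_e)_{qjmn} = d(S_e)_{qj} / dF_{mn}` for the
#' neo-Hookean law, in closed form:
#' \deqn{\frac{\mu_e}{J^{2/3}}\Big(-\tfrac{2}{3}\delta_{qj}F^{-1}_{nm}
#'   + \tfrac{2}{9}F^{-1}_{nm}C^{-1}_{qj}I_C
#'   - \tfrac{2}{3}F_{mn}C^{-1}_{qj}
#'   + \tfrac{I_C}{3}\big(F^{-1}_{qm}C^{-1}_{nj} + F^{-1}_{jm}C^{-1}_{qn}\big)\Big)}
#' The expression is validated against central finite differences of
#' [pk2_elastic()] (the derivative, not any printed variant of it, is the
#' ground truth).
#'
#' @inheritParams pk2_elastic
#' @return 3 x 3 x 3 x 3 array, index order `[q, j, m, n]`.
#' @export
grad_F_Se <- function(F, mu_e) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("'F' must have positive determinant")
  Fi <- solve(F)
  C <- crossprod(F)
  Ci <- solve(C)
  IC <- sum(diag(C))
  D <- array(0, c(3, 3, 3, 3))
  for (m in 1:3) for (n in 1:3) {
    D[, , m, n] <- -2 / 3 * Fi[n, m] * diag(3) +
      (2 / 9 * Fi[n, m] * IC - 2 / 3 * F[m, n]) * Ci +
      IC / 3 * (outer(Fi[, m], Ci[n, ]) + outer(Ci[, n], Fi[, m]))
  }
  mu_e * J^(-2 / 3) * D
}

#' Fourth-order wave-modification tensor H'
#'
#' The deformation-induced modification of the wave operator for a
#' neo-Hookean medium: with `S_hat = S_e / mu_e` (the stress at unit shear
#' modulus),
#' \deqn{H'_{ikml} = \frac{1}{J}\big(F_{iq}(\nabla_F \hat S_e)_{qjmn} F_{ln} F_{kj}
#'   + (\hat S_e)_{nj}\,\delta_{im} F_{ln} F_{kj}\big).}
#' `H'` is independent of `mu_e`; the full modification tensor for a medium
#' of shear modulus `mu` is `mu * H'`. The repo-wide contraction convention
#' is `(T : A)_{ik} = T_{ikml} A_{ml}` (sum over `m`, `l`).
#'
#' At `F = I`, `H' : A = A + A^T - (2/3) tr(A) I`, so for divergence-free
#' wave gradients the modified gradient reduces *exactly* to the standard
#' symmetrised gradient: the normalization constant between the modified and
#' standard reconstructions is 1.
#'
#' @param F 3 x 3 deformation gradient with `det F > 0`.
#' @return 3 x 3 x 3 x 3 array, index order `[i, k, m, l]`.
#' @export
hprime_tensor <- function(F) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("'F' must have positive determinant")
  D <- grad_F_Se(F, 1)
  S <- pk2_elastic(F, 1)
  H <- array(0, c(3, 3, 3, 3))
  FS <- F %*% S %*% t(F)      # second term: (A tau)_{ik} with tau = F S F^T
  for (m in 1:3) for (l in 1:3) {
    # contract q,j,n:  F_iq D_qjmn F_ln F_kj
    M <- matrix(0, 3, 3)
    for (n in 1:3) M <- M + D[, , m, n] * F[l, n]   # M_qj
    H[, , m, l] <- (F %*% M %*% t(F) + diag(3)[, m] %o% FS[l, ]) / J
  }
  H
}

#' Apply the fourth-order modification to a wave gradient
#'
#' Contracts `H'` with a (complex) wave-displacement gradient using the
#' repo-wide convention `(H' : A)_{ik} = H'_{ikml} A_{ml}`. At `F = I` and
#' for divergence-free fields this equals `A + A^T` exactly (the isotropic
#' `tr(A)` term vanishes), which is the flux of the standard isotropic
#' reconstruction; no further normalization is required.
#'
#' @param Hprime 3 x 3 x 3 x 3 tensor from [hprime_tensor()].
#' @param grad_v 3 x 3 (possibly complex) wave gradient.
#' @return 3 x 3 complex matrix.
#' @export
modified_gradient <- function(Hprime, grad_v) {
  stopifnot(all(dim(Hprime) == 3), all(dim(grad_v) == c(3, 3)))
  out <- matrix(0 + 0i, 3, 3)
  for (i in 1:3) for (k in 1:3)
    out[i, k] <- sum(Hprime[i, k, , ] * grad_v)
  out
}

# Vectorized per-voxel H' for an N x 9 matrix of deformation gradients
# (column-major 3x3 per row). Returns N x 81 with flat index
# i + 3(k-1) + 9(m-1) + 27(l-1). Identity rows short-circuit to the constant
# reference tensor.
hprime_volume <- function(Fmat) {
  cpp_hprime_volume(Fmat)
}
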