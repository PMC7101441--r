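# Shared test fixtures, built in code.

# Analytic damped plane shear wave: z-polarized, propagating along x.
# Exact solution of the homogeneous time-harmonic equation, so the local
# inversion should recover G_star up to discretization error.
plane_wave_field <- function(shape = 40, spacing = 1, G_star = 1500 + 200i,
                             rho = 1000, frequency = 100, amplitude = 1e-5,
                             support = NULL) {
  grid <- elastopress:::centered_grid(shape, spacing)
  xyz <- elastopress:::grid_centers(grid) * 1e-3
  k <- 2 * pi * frequency * sqrt(rho / G_star)
  v <- cbind(0i * xyz[, 1], 0i * xyz[, 1], amplitude * exp(-1i * k * xyz[, 1]))
  wave_field(v, grid, frequency, rho, support)
}

# random unimodular deformation gradients (det = 1, positive)
random_unimodular <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    F <- matrix(stats::rnorm(9), 3, 3)
    if (det(F) < 0) F[1, ] <- -F[1, ]
    F / det(F)^(1 / 3)
  })
}

# naive quadruple-loop contraction (T:A)_ik = T_ikml A_ml -- oracle for the
# vectorized kernels
contract_loop <- function(H, A) {
  out <- matrix(0 + 0i, 3, 3)
  for (i in 1:3) for (k in 1:3) for (m in 1:3) for (l in 1:3)
    out[i, k] <- out[i, k] + H[i, k, m, l] * A[m, l]
  out
}
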