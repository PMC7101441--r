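# Lazily built, session-cached heavy fixtures (wave simulations are the
# expensive part; several test blocks share them).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Reference desk-scale inclusion simulation: the forward problem is solved
# on a 0.5 mm grid (resolving the void surface and the near-surface
# deformation halo) and read out at the 1 mm acquisition resolution --
# the usual relation between a well-resolved forward simulation and the
# coarser image an MRE scan produces. 100 Hz, G* = 1.5 + 0.2i kPa, 4 mm
# void sphere.
sphere_sim <- function(alpha_true) {
  cached(sprintf("sphere_%g", alpha_true), function() {
    wvf <- simulate_waves(
      simulation_config(shape = 64, spacing = 0.5, alpha_true = alpha_true,
                        tol = 1e-4, maxit = 450))
    downsample_wave(wvf, 2L)
  })
}

homog_sim <- function() {
  cached("homog", function() {
    simulate_waves(simulation_config(shape = 40, inclusion = NULL))
  })
}
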