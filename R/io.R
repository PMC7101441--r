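#' Read complex wave volumes from NIfTI
#'
#' Assembles a [wave_field()] from either six scalar NIfTI volumes (real and
#' imaginary parts of the three displacement components, in the order
#' Re(x), Re(y), Re(z), Im(x), Im(y), Im(z)) or a single 4D NIfTI volume
#' with those six scalar volumes stacked along the fourth dimension. All
#' volumes must share shape and voxel spacing; anisotropic spacing triggers
#' a warning. Displacements are stored in metres.
#'
#' @param paths character vector: six 3D NIfTI paths, or one 4D NIfTI path.
#' @param frequency vibration frequency, Hz.
#' @param rho density, kg/m^3.
#' @param support optional logical array (void mask complement); or path to
#'   a NIfTI volume (nonzero = supported).
#' @param origin optional world origin override, mm.
#' @return A [wave_field()].
#' @export
read_wave_volumes <- function(paths, frequency, rho = 1000, support = NULL,
                              origin = NULL) {
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    d <- dim(img)
    if (length(d) != 4L || d[4] != 6L)
      stop("a single wave volume must be 4D with 6 components")
    vols <- lapply(1:6, function(c) img[, , , c])
    pix <- RNifti::pixdim(img)[1:3]
    shape <- d[1:3]
  } else {
    if (length(paths) != 6L)
      stop("expected six scalar volumes (Re x,y,z then Im x,y,z) or one 4D volume")
    imgs <- lapply(paths, RNifti::readNifti)
    shapes <- vapply(imgs, function(i) paste(dim(i), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("wave component volumes have mismatched shapes: ",
           paste(unique(shapes), collapse = " vs "))
    pixs <- vapply(imgs, function(i) paste(signif(RNifti::pixdim(i)[1:3], 8),
                                           collapse = "x"), "")
    if (length(unique(pixs)) != 1L)
      stop("wave component volumes have mismatched voxel spacings")
    vols <- imgs
    pix <- RNifti::pixdim(imgs[[1]])[1:3]
    shape <- dim(imgs[[1]])
  }
  if (diff(range(pix)) > 1e-6 * mean(pix))
    warning("anisotropic voxel spacing: ", paste(signif(pix, 6), collapse = " x "),
            " mm")
  grid <- acquisition_grid(shape, pix,
                           origin = if (is.null(origin)) -(shape - 1) / 2 * pix
                                    else origin)
  v <- complex(real = 0, imaginary = 0)
  v <- cbind(as.numeric(vols[[1]]) + 1i * as.numeric(vols[[4]]),
             as.numeric(vols[[2]]) + 1i * as.numeric(vols[[5]]),
             as.numeric(vols[[3]]) + 1i * as.numeric(vols[[6]]))
  sup <- NULL
  if (!is.null(support)) {
    if (is.character(support)) support <- RNifti::readNifti(support) != 0
    sup <- array(as.logical(support), dim = shape)
  }
  wave_field(v, grid, frequency, rho, sup)
}

#' Write a wave field as NIfTI volumes plus a JSON sidecar
#'
#' Writes one 4D NIfTI volume (six scalar volumes: Re then Im of the three
#' components) and a JSON sidecar carrying frequency, spacing, density,
#' inclusion geometry, the true inflation scaling (if known) and the seed.
#'
#' @param wave a [wave_field()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param inclusion optional [sphere_inclusion()] recorded in the sidecar.
#' @param seed optional integer recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_wave_volumes <- function(wave, path, inclusion = NULL, seed = NULL) {
  d <- c(wave$grid$shape, 6L)
  arr <- array(0, dim = d)
  for (c in 1:3) {
    arr[, , , c] <- array(Re(wave$v[, c]), dim = wave$grid$shape)
    arr[, , , c + 3L] <- array(Im(wave$v[, c]), dim = wave$grid$shape)
  }
  img <- RNifti::asNifti(arr, pixdim = c(wave$grid$spacing, 1))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(frequency_hz = wave$frequency, spacing_mm = wave$grid$spacing,
               origin_mm = wave$grid$origin, rho_kg_m3 = wave$rho,
               components = c("re_x", "re_y", "re_z", "im_x", "im_y", "im_z"),
               units = "m")
  if (!is.null(inclusion))
    meta$inclusion <- list(center_mm = inclusion$center, r0_mm = inclusion$r0,
                           alpha = inclusion$alpha)
  if (!is.null(attr(wave, "alpha_true")))
    meta$alpha_true <- attr(wave, "alpha_true")
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Write an elastogram as NIfTI volumes
#'
#' Writes the storage modulus, loss modulus (Pa) and validity mask as three
#' scalar NIfTI volumes `<prefix>_gp.nii.gz`, `<prefix>_gpp.nii.gz`,
#' `<prefix>_valid.nii.gz`.
#'
#' @param elastogram an elastogram from [reconstruct()].
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_elastogram <- function(elastogram, prefix) {
  pix <- c(elastogram$grid$spacing, 1)
  gp <- elastogram$G_star
  paths <- paste0(prefix, c("_gp.nii.gz", "_gpp.nii.gz", "_valid.nii.gz"))
  vols <- list(ifelse(is.na(gp), 0, Re(gp)), ifelse(is.na(gp), 0, Im(gp)),
               elastogram$valid * 1)
  for (i in 1:3)
    RNifti::writeNifti(RNifti::asNifti(array(vols[[i]],
                                             dim = elastogram$grid$shape),
                                       pixdim = pix), paths[i])
  invisible(paths)
}

# required-field access with a named error (fail fast on malformed configs)
cfg_get <- function(cfg, name, default = NULL, required = is.null(default)) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  x <- cfg
  for (p in parts) {
    if (is.null(x[[p]])) {
      if (required) stop(sprintf("missing required config field '%s'", name))
      return(default)
    }
    x <- x[[p]]
  }
  x
}

#' Run the full pressure-estimation pipeline from a configuration
#'
#' Executes read-or-simulate, the deformation-scaling sweep, and the
#' pressure conversion, then writes a JSON report (selected alpha, pressure,
#' the full std(G') curve, the echoed configuration, package version and
#' seed) and, optionally, the elastogram at the selected alpha.
#'
#' Configuration (a nested list, or a YAML file path): either a `simulate`
#' block (`shape`, `spacing`, `g_prime`, `g_double_prime`, `alpha_true`,
#' `noise_level`, ...) or an `input` block (`wave` path(s)); `frequency`
#' (Hz), `rho`, `mu_e` (Pa); `geometry` (`center` mm, `r0` mm) unless
#' simulating with the default inclusion; a `sweep` block (`alpha_min`,
#' `alpha_max`, `alpha_step`, `smooth_sigma`, `window_radius`); `seed`; an
#' `output` block (`report`, optional `elastogram_prefix`).
#'
#' @param config nested list or path to a YAML file.
#' @param verbose print per-alpha progress.
#' @return The `"mre_pressure"` fit, invisibly, with the report attached as
#'   attribute `"report"`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- cfg_get(config, "seed", 1L)
  frequency <- cfg_get(config, "frequency")
  rho <- cfg_get(config, "rho", 1000)
  mu_e <- cfg_get(config, "mu_e", default = NULL, required = FALSE)
  sim_blk <- cfg_get(config, "simulate", default = NULL, required = FALSE)
  if (!is.null(sim_blk)) {
    gstar <- complex(real = cfg_get(config, "simulate.g_prime"),
                     imaginary = cfg_get(config, "simulate.g_double_prime", 0))
    center <- unlist(cfg_get(config, "geometry.center", c(0, 0, 0)))
    r0 <- cfg_get(config, "geometry.r0", 4)
    inc <- sphere_inclusion(center, r0, cfg_get(config, "simulate.alpha_true", 0))
    cfgs <- simulation_config(
      shape = unlist(cfg_get(config, "simulate.shape", 50)),
      spacing = cfg_get(config, "simulate.spacing", 1),
      material = material_model(gstar, mu_e = if (is.null(mu_e)) Re(gstar) else mu_e,
                                rho = rho),
      inclusion = inc, frequency = frequency,
      void = isTRUE(cfg_get(config, "simulate.void", TRUE)))
    wave <- simulate_waves(cfgs, verbose = verbose)
    noise <- cfg_get(config, "simulate.noise_level", 0)
    if (noise > 0) {
      roi <- build_roi(wave$grid, inc)
      wave <- add_noise(wave, noise, roi, seed = seed)
      wave <- smooth_waves(wave)
    }
    inclusion <- sphere_inclusion(center, r0, 0)
  } else {
    paths <- unlist(cfg_get(config, "input.wave"))
    support <- cfg_get(config, "input.support", default = NULL, required = FALSE)
    wave <- read_wave_volumes(paths, frequency, rho, support = support)
    maskp <- cfg_get(config, "input.inclusion_mask", default = NULL, required = FALSE)
    if (!is.null(maskp)) {
      inclusion <- inclusion_from_mask(RNifti::readNifti(maskp) != 0, wave$grid)
    } else {
      inclusion <- sphere_inclusion(unlist(cfg_get(config, "geometry.center")),
                                    cfg_get(config, "geometry.r0"))
    }
  }
  grid_spec <- list(alpha_min = cfg_get(config, "sweep.alpha_min", -0.2),
                    alpha_max = cfg_get(config, "sweep.alpha_max", 1.0),
                    alpha_step = cfg_get(config, "sweep.alpha_step", 0.01))
  ag <- default_alpha_grid(grid_spec$alpha_min, grid_spec$alpha_max,
                           grid_spec$alpha_step)
  fit <- mre_pressure(wave, inclusion, mu_e = mu_e, alpha_grid = ag,
                      smooth_sigma = cfg_get(config, "sweep.smooth_sigma", 0),
                      window_radius = as.integer(cfg_get(config, "sweep.window_radius", 3)),
                      verbose = verbose)
  fit$call <- NULL  # the full internal call is noise in pipeline reports
  report <- list(alpha_min = fit$alpha_min,
                 p_inc_pa = fit$p_inc,
                 p_inc_kpa = fit$p_inc / 1000,
                 mu_e_pa = fit$mu_e,
                 mu_e_source = fit$mu_e_source,
                 curve = fit$curve,
                 roi = list(inner_mm = fit$roi$inner_radius,
                            outer_mm = fit$roi$outer_radius,
                            n_voxels = length(fit$roi$index)),
                 config = config, seed = seed,
                 package_version = as.character(utils::packageVersion("elastopress")))
  rp <- cfg_get(config, "output.report", default = NULL, required = FALSE)
  if (!is.null(rp)) {
    dir.create(dirname(rp), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  ep <- cfg_get(config, "output.elastogram_prefix", default = NULL, required = FALSE)
  if (!is.null(ep)) write_elastogram(fit$elastogram, ep)
  attr(fit, "report") <- report
  invisible(fit)
}
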