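# Shared fixtures, computed once per test run.  The heavy objects (basis
# sets, fitted healthy grids) are reused across test files through this
# memoizing environment.

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .cache)) assign(key, compute(), envir = .cache)
  get(key, envir = .cache)
}

std_metabolites <- function() {
  c("NAA", "NAAG", "Cho", "GPC", "Cr", "Glu", "Gln", "mI", "Lac",
    "GABA", "GSH", "Gly", "Ala", "Glc", "Val")
}

cached_basis <- function(te, n_points = 2048,
                         metabolites = std_metabolites()) {
  key <- paste0("basis_", te, "_", n_points, "_",
                paste(metabolites, collapse = "."))
  cache_get(key, function()
    make_basis_set(metabolites, te, acq_params(n_points = n_points)))
}

# Study-condition noise model (target SNR 27, FWHM 0.029 +/- 0.005 ppm,
# small frequency/phase jitter).
study_noise <- function(basis) {
  nm <- noise_model(noise_sd = 0, lorentz_hz = 2, fwhm_ppm = 0.029,
                    fwhm_sd_ppm = 0.005, freq_jitter_sd = 0.3,
                    phase_jitter_sd = 1)
  nm$noise_sd <- calibrate_noise_sd(
    reference_composition("healthy_brain")$concentrations, basis, 27, nm)
  nm
}

fast_cfg <- function(...) fit_config(maxit = 150, reltol = 1e-7, ...)

# Healthy-brain grid at the study conditions, all 100 interior voxels
# fitted with the TE-matched basis.
cached_healthy_fits <- function(te, seed_scene = 101, seed_grid = 202) {
  key <- paste0("healthy_fits_", te, "_", seed_scene, "_", seed_grid)
  cache_get(key, function() {
    basis <- cached_basis(te)
    scene <- make_healthy_scene(seed = seed_scene)
    nm <- study_noise(basis)
    grid <- generate_mrsi_grid(scene, basis, nm, seed = seed_grid)
    interior <- exclude_voi_edge(grid$voi_mask)
    cfg <- if (te <= 60) fast_cfg(baseline_knot_spacing = 0.3) else fast_cfg()
    fits <- fit_grid(grid, basis, cfg,
                     voxels = which(interior, arr.ind = TRUE))
    fits <- quality_filter(fits, cfg)
    list(scene = scene, grid = grid, fits = fits, noise = nm,
         interior = interior)
  })
}
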