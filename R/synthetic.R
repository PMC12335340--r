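## Synthetic phantom spectra and brain-tumor MRSI grids carrying the
## statistical structure the downstream analysis assumes: per-voxel
## metabolite concentrations, Lorentzian-Gaussian linewidths drawn from a
## target FWHM distribution, small frequency/phase jitter, i.i.d. complex
## Gaussian time-domain noise, a paired low-resolution water grid, tissue
## fractions and tumor-subregion labels, plus scan-rescan replicates.

#' Phantom composition (metabolite concentrations in mM)
#' @param concentrations Named numeric vector of concentrations (mM).
#' @param label Annotation only.
#' @return Object of class `composition`.
#' @export
composition <- function(concentrations, label = "") {
  stopifnot(all(concentrations >= 0), !is.null(names(concentrations)))
  structure(list(concentrations = concentrations, label = label),
            class = "composition")
}

#' Reference compositions used in validation experiments
#'
#' `"phantom1"`: 20 mM Glu, 20 mM Gln, 10 mM Cr in buffered saline.
#' `"phantom2"`: brain-mimicking mixture (10 mM Cr, 10 mM Glu, 5 mM Gln,
#' 3 mM Cho, 3 mM GSH, 2 mM GABA, 7.5 mM mI, 5 mM Lac, 12.5 mM NAA).
#' `"healthy_brain"`: typical adult white-matter dominated concentrations
#' with Glu 10.84 and Gln 2.94 mM.
#'
#' @param which One of `"phantom1"`, `"phantom2"`, `"healthy_brain"`.
#' @return A [composition()].
#' @export
reference_composition <- function(which = c("phantom1", "phantom2",
                                            "healthy_brain")) {
  which <- match.arg(which)
  conc <- switch(which,
    phantom1 = c(Glu = 20, Gln = 20, Cr = 10),
    phantom2 = c(Cr = 10, Glu = 10, Gln = 5, Cho = 3, GSH = 3, GABA = 2,
                 mI = 7.5, Lac = 5, NAA = 12.5),
    healthy_brain = c(NAA = 12.0, NAAG = 1.5, Cr = 8.0, Cho = 0.6,
                      GPC = 1.2, Glu = 10.84, Gln = 2.94, mI = 6.0,
                      Lac = 0.6, GABA = 1.3, GSH = 2.0, Gly = 1.0,
                      Ala = 0.4, Glc = 1.2, Val = 0.2))
  composition(conc, which)
}

#' Noise and lineshape model for synthetic spectra
#'
#' @param noise_sd SD of the i.i.d. complex Gaussian time-domain noise
#'   (per real/imaginary channel, per sample).
#' @param lorentz_hz Lorentzian linewidth component (Hz).
#' @param fwhm_ppm Target mean total linewidth (ppm); the Gaussian
#'   component per voxel is chosen so the total FWHM hits a draw from
#'   `Normal(fwhm_ppm, fwhm_sd_ppm)` truncated below.
#' @param fwhm_sd_ppm Across-voxel SD of the drawn linewidth (ppm).
#' @param freq_jitter_sd Per-voxel frequency offset SD (Hz).
#' @param phase_jitter_sd Per-voxel zero-order phase SD (degrees).
#' @param baseline_humps Optional macromolecule/lipid stand-in: a list
#'   with numeric fields `ppm` (centers), `amp` (absorptive amplitudes in
#'   concentration units) and `fwhm_ppm` (common width).  Off by default;
#'   intended for short-TE experiments that exercise baseline handling.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(noise_sd = 0, lorentz_hz = 2, fwhm_ppm = 0.029,
                        fwhm_sd_ppm = 0, freq_jitter_sd = 0,
                        phase_jitter_sd = 0, baseline_humps = NULL) {
  stopifnot(noise_sd >= 0, lorentz_hz >= 0, fwhm_ppm > 0,
            fwhm_sd_ppm >= 0, freq_jitter_sd >= 0, phase_jitter_sd >= 0)
  if (!is.null(baseline_humps))
    stopifnot(length(baseline_humps$ppm) == length(baseline_humps$amp),
              baseline_humps$fwhm_ppm > 0)
  structure(as.list(environment()), class = "noise_model")
}

## Noiseless time-domain signal of a composition on a basis.
composition_fid <- function(conc, basis) {
  mets <- names(conc)
  missing <- setdiff(mets, names(basis$entries))
  if (length(missing))
    stop("metabolite(s) missing from basis: ", paste(missing, collapse = ", "))
  fid <- complex(basis$acq$n_points)
  for (m in mets) fid <- fid + conc[[m]] * basis$entries[[m]]$fid
  fid
}

#' Time-domain noise SD that yields a target spectral SNR
#'
#' Computes the noiseless spectrum of `conc` on `basis` at the model's
#' mean linewidth, takes the maximum of the real channel over the analysis
#' window, and returns the time-domain SD for which the LCModel-style SNR
#' (peak over twice the frequency-domain noise SD) equals `target_snr`.
#'
#' @param conc Named concentration vector (mM).
#' @param basis A basis set.
#' @param target_snr Desired SNR.
#' @param noise A [noise_model()] supplying the lineshape.
#' @param ppm_window Window over which the peak is taken.
#' @return Time-domain noise SD.
#' @export
calibrate_noise_sd <- function(conc, basis, target_snr,
                               noise = noise_model(),
                               ppm_window = c(0.2, 4.2)) {
  acq <- basis$acq
  ls <- lineshape_for_fwhm(noise$fwhm_ppm * acq$larmor_freq,
                           noise$lorentz_hz)
  fid <- composition_fid(conc, basis)
  sp <- spectrum_from_fid(fid, acq, ls)
  sel <- sp$ppm_axis >= ppm_window[1] & sp$ppm_axis <= ppm_window[2]
  peak <- max(Re(sp$spectrum[sel]))
  sigma_f <- peak / (2 * target_snr)
  sigma_f / sqrt(acq$n_points)
}

#' Ground-truth scene for a synthetic MRSI measurement
#'
#' Builds per-voxel subregion labels (`ET`, `NETC`, `SNFH`, `CL`), tissue
#' fractions, metabolite concentration maps and a VOI mask on a regular
#' grid.  The default geometry places a concentric tumor (necrotic core
#' `NETC`, enhancing rim `ET`, surrounding FLAIR hyperintensity `SNFH`)
#' inside normal-appearing tissue (`CL`) on a 16 x 16 grid with a centered
#' 12 x 12 VOI.  Per-region Glu and Gln means/SDs default to values typical
#' of IDH wild-type glioblastoma subregions and contralateral tissue.
#'
#' @param grid_dims Grid size (rows, cols).
#' @param voi_dims VOI size (rows, cols), centered.
#' @param voxel_size_mm Nominal in-plane voxel size (annotation).
#' @param tumor Logical; `FALSE` gives an all-`CL` (healthy) scene.
#' @param tumor_center,tumor_radii Tumor geometry in voxel units:
#'   radii for NETC, ET and SNFH (increasing).
#' @param region_means Named list per region of named mean concentration
#'   vectors (mM).
#' @param region_sds As `region_means`, across-voxel SDs; concentrations
#'   are drawn per voxel from truncated normals.
#' @param tissue_fractions Named list per region of `c(wm, gm, csf)`
#'   fractions (must sum to 1).
#' @param seed RNG seed for the concentration draws.
#' @return Object of class `ground_truth_scene`.
#' @export
make_tumor_scene <- function(grid_dims = c(16, 16), voi_dims = c(12, 12),
                             voxel_size_mm = 6, tumor = TRUE,
                             tumor_center = c(7.5, 7.5),
                             tumor_radii = c(NETC = 1.6, ET = 3.0,
                                             SNFH = 4.6),
                             region_means = NULL, region_sds = NULL,
                             tissue_fractions = NULL, seed = 1) {
  if (tumor && any(diff(tumor_radii) <= 0))
    stop("tumor radii must be strictly increasing (non-overlapping rings)")
  healthy <- reference_composition("healthy_brain")$concentrations
  scale_to <- function(glu, gln, naa_scale = 1) {
    v <- healthy
    v["Glu"] <- glu; v["Gln"] <- gln
    v[c("NAA", "NAAG")] <- v[c("NAA", "NAAG")] * naa_scale
    v
  }
  region_means <- region_means %||% list(
    CL = scale_to(10.84, 2.94),
    NETC = scale_to(5.35, 4.92, 0.35),
    ET = scale_to(7.60, 7.20, 0.55),
    SNFH = scale_to(7.39, 9.17, 0.80))
  region_sds <- region_sds %||% list(
    CL = region_means$CL * 0.05,
    NETC = local({ s <- region_means$NETC * 0.15
                   s["Glu"] <- 4.45; s["Gln"] <- 3.38; s }),
    ET = local({ s <- region_means$ET * 0.15
                 s["Glu"] <- 4.16; s["Gln"] <- 4.42; s }),
    SNFH = local({ s <- region_means$SNFH * 0.15
                   s["Glu"] <- 2.62; s["Gln"] <- 6.84; s }))
  tissue_fractions <- tissue_fractions %||% list(
    CL = c(wm = 0.729, gm = 0.188, csf = 0.083),
    NETC = c(wm = 0.15, gm = 0.05, csf = 0.80),
    ET = c(wm = 0.60, gm = 0.20, csf = 0.20),
    SNFH = c(wm = 0.75, gm = 0.15, csf = 0.10))
  for (fr in tissue_fractions)
    if (abs(sum(fr) - 1) > 1e-9) stop("tissue fractions must sum to 1")

  nr <- grid_dims[1]; nc <- grid_dims[2]
  labels <- matrix("CL", nr, nc)
  if (tumor) {
    d <- sqrt(outer((seq_len(nr) - tumor_center[1])^2,
                    (seq_len(nc) - tumor_center[2])^2, "+"))
    labels[d <= tumor_radii["SNFH"]] <- "SNFH"
    labels[d <= tumor_radii["ET"]] <- "ET"
    labels[d <= tumor_radii["NETC"]] <- "NETC"
  }
  r0 <- (nr - voi_dims[1]) %/% 2
  c0 <- (nc - voi_dims[2]) %/% 2
  voi <- matrix(FALSE, nr, nc)
  voi[r0 + seq_len(voi_dims[1]), c0 + seq_len(voi_dims[2])] <- TRUE

  mets <- names(region_means$CL)
  conc <- array(0, c(nr, nc, length(mets)), dimnames = list(NULL, NULL, mets))
  fractions <- array(0, c(nr, nc, 3),
                     dimnames = list(NULL, NULL, c("wm", "gm", "csf")))
  set.seed(seed)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    reg <- labels[i, j]
    mu <- region_means[[reg]]; sdv <- region_sds[[reg]]
    conc[i, j, ] <- pmax(stats::rnorm(length(mets), mu[mets], sdv[mets]), 0)
    fractions[i, j, ] <- tissue_fractions[[reg]]
  }
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 labels = labels, tissue_fractions = fractions,
                 conc_maps = conc, voi_mask = voi, seed = seed,
                 region_means = region_means, region_sds = region_sds,
                 metabolites = mets), class = "ground_truth_scene")
}

#' Healthy (all-contralateral) scene
#' @inheritParams make_tumor_scene
#' @param conc_cv Across-voxel coefficient of variation of the
#'   concentration draws.
#' @return A `ground_truth_scene` with a single `CL` class.
#' @export
make_healthy_scene <- function(grid_dims = c(16, 16), voi_dims = c(12, 12),
                               conc_cv = 0.05, seed = 1) {
  mu <- reference_composition("healthy_brain")$concentrations
  make_tumor_scene(grid_dims = grid_dims, voi_dims = voi_dims,
                   tumor = FALSE,
                   region_means = list(CL = mu),
                   region_sds = list(CL = mu * conc_cv),
                   seed = seed)
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("<ground_truth_scene>", paste(x$grid_dims, collapse = "x"),
      "grid; classes:", paste(names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

## One voxel's noisy spectrum from a noiseless FID (RNG state is advanced
## deterministically; callers set the seed).
voxel_spectrum <- function(fid0, acq, noise) {
  fw <- noise$fwhm_ppm
  if (noise$fwhm_sd_ppm > 0)
    fw <- max(stats::rnorm(1, fw, noise$fwhm_sd_ppm), 0.012)
  ls <- lineshape_for_fwhm(fw * acq$larmor_freq, noise$lorentz_hz)
  t_s <- time_axis(acq)
  fid <- fid0
  if (noise$freq_jitter_sd > 0)
    fid <- fid * exp(2i * pi * stats::rnorm(1, 0, noise$freq_jitter_sd) * t_s)
  if (noise$phase_jitter_sd > 0)
    fid <- fid * exp(1i * stats::rnorm(1, 0, noise$phase_jitter_sd) * pi / 180)
  fid <- fid * apod_vector(ls, t_s)
  if (noise$noise_sd > 0)
    fid <- fid + complex(real = stats::rnorm(acq$n_points, 0, noise$noise_sd),
                         imaginary = stats::rnorm(acq$n_points, 0,
                                                  noise$noise_sd))
  sp <- fid_to_spec(fid)
  bh <- noise$baseline_humps
  if (!is.null(bh)) {
    ppm <- ppm_axis(acq)
    for (k in seq_along(bh$ppm))
      sp <- sp + bh$amp[k] *
        exp(-4 * log(2) * ((ppm - bh$ppm[k]) / bh$fwhm_ppm)^2)
  }
  sp
}

#' Generate a single-voxel phantom spectrum
#'
#' @param comp A [composition()].
#' @param basis Basis set providing the metabolite signal model.
#' @param noise A [noise_model()].
#' @param seed RNG seed (the output is a pure function of inputs + seed).
#' @return An `mrsi_grid` with a 1 x 1 spectra array.
#' @export
generate_phantom_spectrum <- function(comp, basis, noise = noise_model(),
                                      seed = 1) {
  acq <- basis$acq
  fid0 <- composition_fid(comp$concentrations, basis)
  set.seed(seed)
  sp <- voxel_spectrum(fid0, acq, noise)
  spectra <- array(sp, c(1, 1, acq$n_points))
  structure(list(spectra = spectra, acq = acq, te = basis$te,
                 noise = noise, seed = seed,
                 voi_mask = matrix(TRUE, 1, 1),
                 ppm_axis = ppm_axis(acq), water = NULL, scene = NULL),
            class = "mrsi_grid")
}

#' Generate a full MRSI grid from a ground-truth scene
#'
#' Per voxel: the noiseless FID from the scene's concentration maps is
#' broadened by a linewidth drawn from the noise model's FWHM
#' distribution, frequency/phase jittered, and complex Gaussian noise is
#' added.  A companion water grid is built from the tissue-water
#' concentration map, filtered to the poorer point spread function of the
#' low-resolution water reference acquisition.
#'
#' @param scene A [make_tumor_scene()] / [make_healthy_scene()] scene.
#' @param basis Basis set (defines TE and the acquisition grid).
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @param water_table A [water_content_table()] for the water map.
#' @param water_kspace K-space extent (points) of the emulated
#'   low-resolution water acquisition.
#' @return Object of class `mrsi_grid` with fields `spectra`
#'   (rows x cols x points), `water` (total water signal per voxel,
#'   2 protons x water concentration, PSF-filtered), `acq`, `te`,
#'   `noise`, `seed`, `voi_mask`, `scene`.
#' @export
generate_mrsi_grid <- function(scene, basis, noise = noise_model(),
                               seed = 1, water_table = water_content_table(),
                               water_kspace = 8) {
  acq <- basis$acq
  nr <- scene$grid_dims[1]; nc <- scene$grid_dims[2]
  mets <- intersect(scene$metabolites, names(basis$entries))
  Bfid <- vapply(basis$entries[mets], function(e) e$fid,
                 complex(acq$n_points))
  spectra <- array(0i, c(nr, nc, acq$n_points))
  set.seed(seed)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    fid0 <- as.vector(Bfid %*% scene$conc_maps[i, j, mets])
    spectra[i, j, ] <- voxel_spectrum(fid0, acq, noise)
  }
  cw <- water_concentration_map(scene$tissue_fractions, water_table)
  ks <- min(water_kspace, nr, nc)
  structure(list(spectra = spectra, acq = acq, te = basis$te,
                 noise = noise, seed = seed, voi_mask = scene$voi_mask,
                 ppm_axis = ppm_axis(acq),
                 water = psf_match(2 * cw, ks),     # water signal (2 protons)
                 water_conc = psf_match(cw, ks),    # PSF-matched C_W map
                 scene = scene),
            class = "mrsi_grid")
}

#' @export
print.mrsi_grid <- function(x, ...) {
  d <- dim(x$spectra)
  cat("<mrsi_grid>", d[1], "x", d[2], "voxels,", d[3], "points, TE =",
      x$te, "ms, noise_sd =", signif(x$noise$noise_sd, 3), "\n")
  invisible(x)
}

#' Generate a scan-rescan pair of grids from one scene
#'
#' Two acquisitions of the same ground truth with independent noise
#' realizations (identical seeds give identical grids).
#'
#' @inheritParams generate_mrsi_grid
#' @param seed_pair Integer vector of two seeds.
#' @return List of two `mrsi_grid` objects.
#' @export
generate_scan_rescan <- function(scene, basis, noise = noise_model(),
                                 seed_pair = c(1, 2), ...) {
  stopifnot(length(seed_pair) == 2)
  list(generate_mrsi_grid(scene, basis, noise, seed_pair[1], ...),
       generate_mrsi_grid(scene, basis, noise, seed_pair[2], ...))
}
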