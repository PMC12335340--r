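## Absolute metabolite quantification: internal-water referencing with a
## tissue-water concentration map filtered to the point spread function of
## the low-resolution water acquisition, contralateral referencing for the
## tumor area, and steady-state T1/T2 relaxation correction.

#' Literature water content per tissue type
#'
#' Pure-water concentration is 55,510 mM; the defaults correspond to the
#' commonly used water contents of about 65% (WM), 78% (GM) and 97%
#' (CSF).  All values are editable.
#'
#' @param wm,gm,csf Water concentration (mM) in white matter, gray matter
#'   and CSF.
#' @param source Annotation string.
#' @return Object of class `water_content_table`.
#' @export
water_content_table <- function(wm = 36080, gm = 43300, csf = 53840,
                                source = "standard literature values") {
  if (!(csf >= gm && gm >= wm && wm > 0))
    stop("expected CSF >= GM >= WM > 0 water content")
  structure(list(wm = wm, gm = gm, csf = csf, source = source),
            class = "water_content_table")
}

#' Per-voxel water concentration from tissue fractions
#'
#' `C_W = f_wm c_wm + f_gm c_gm + f_csf c_csf`.  In CSF-exclusion mode the
#' metabolite-visible compartment is assumed CSF-free and the water
#' concentration is rescaled to the non-CSF fraction; pure-CSF voxels are
#' flagged undefined (`NA`).
#'
#' @param fractions Array (rows x cols x 3, slices wm/gm/csf) or a
#'   length-3 named vector for a single voxel.
#' @param table A [water_content_table()].
#' @param exclude_csf Logical.
#' @return Matrix (or scalar) of water concentrations in mM.
#' @export
water_concentration_map <- function(fractions, table = water_content_table(),
                                    exclude_csf = FALSE) {
  single <- is.null(dim(fractions))
  if (single) fractions <- array(fractions, c(1, 1, 3))
  fsum <- fractions[, , 1] + fractions[, , 2] + fractions[, , 3]
  if (any(abs(fsum - 1) > 1e-6))
    stop("tissue fractions must sum to 1 in every voxel")
  cw <- fractions[, , 1] * table$wm + fractions[, , 2] * table$gm +
    fractions[, , 3] * table$csf
  if (exclude_csf) {
    tis <- 1 - fractions[, , 3]
    cw <- ifelse(tis <= 1e-6, NA_real_,
                 (fractions[, , 1] * table$wm + fractions[, , 2] * table$gm) /
                   tis)
  }
  if (single) as.numeric(cw) else cw
}

#' Filter a high-resolution map to the MRSI point spread function
#'
#' Transforms the map to k-space, truncates to the central harmonics
#' `|k| <= acq_matrix / 2` in each dimension (the k-space coverage of the
#' low-resolution acquisition, symmetrized so the filter kernel is real
#' and the operation is an exact projection), optionally applies a
#' Hamming weighting, and transforms back on the original grid.  The DC
#' component - hence the total sum of the map - is conserved.
#'
#' @param map Numeric matrix.
#' @param acq_matrix K-space extent (points) retained in each dimension.
#' @param hamming Logical; apply a Hamming window to the retained extent.
#' @return Filtered matrix of the same size.
#' @export
psf_match <- function(map, acq_matrix, hamming = FALSE) {
  nr <- nrow(map); nc <- ncol(map)
  if (acq_matrix > nr || acq_matrix > nc)
    stop("map dimensions must be at least the acquisition matrix")
  K <- stats::fft(map)
  keep_idx <- function(n, m) {
    h <- m %/% 2
    c(seq_len(h + 1), if (h > 0) seq(n - h + 1, n))
  }
  ri <- keep_idx(nr, acq_matrix); ci <- keep_idx(nc, acq_matrix)
  W <- matrix(0, nr, nc)
  W[ri, ci] <- 1
  if (hamming) {
    hw <- function(n, m) {
      k <- c(0:(m %/% 2), if (m %/% 2 > 0) seq(-(m %/% 2), -1))
      w <- 0.54 + 0.46 * cos(2 * pi * k / (m + 1))
      out <- numeric(n); out[keep_idx(n, m)] <- w; out
    }
    W <- outer(hw(nr, acq_matrix), hw(nc, acq_matrix)) * (W > 0)
    W <- W / W[1, 1]  # preserve DC
  }
  Re(stats::fft(K * W, inverse = TRUE)) / (nr * nc)
}

#' Multiplicative relaxation factor of the observed signal
#'
#' Standard mono-exponential steady-state model:
#' `exp(-TE/T2) * (1 - exp(-TR/T1))`.  Quantification divides the
#' metabolite signal by its factor and multiplies by the water factor.
#'
#' @param tr,te Repetition and echo time (ms).
#' @param t1,t2 Relaxation times (ms).
#' @return Signal attenuation factor in (0, 1\].
#' @export
relaxation_correction <- function(tr, te, t1, t2) {
  if (t1 <= 0 || t2 <= 0) stop("T1 and T2 must be positive")
  stopifnot(tr > 0, te >= 0)
  exp(-te / t2) * (1 - exp(-tr / t1))
}

#' Quantification context for water referencing
#'
#' Bundles the constants of the water-reference equation and the optional
#' relaxation correction.  With `tr = NULL` no relaxation correction is
#' applied (factors = 1).
#'
#' @param c_w Water concentration (mM): scalar or per-voxel map.
#' @param n_w Water protons (2).
#' @param tr,te Sequence timing (ms) for relaxation correction.
#' @param t1_met,t2_met,t1_w,t2_w Relaxation times (ms).
#' @return Object of class `quant_context`.
#' @export
quant_context <- function(c_w, n_w = 2, tr = NULL, te = NULL,
                          t1_met = 1300, t2_met = 200,
                          t1_w = 1100, t2_w = 80) {
  if (n_w != 2) stop("water has 2 protons")
  structure(list(c_w = c_w, n_w = n_w, tr = tr, te = te,
                 t1_met = t1_met, t2_met = t2_met, t1_w = t1_w, t2_w = t2_w),
            class = "quant_context")
}

relax_ratio <- function(ctx) {
  if (is.null(ctx$tr)) return(1)
  relaxation_correction(ctx$tr, ctx$te, ctx$t1_w, ctx$t2_w) /
    relaxation_correction(ctx$tr, ctx$te, ctx$t1_met, ctx$t2_met)
}

#' Absolute concentration by internal water referencing
#'
#' `C_met = (S_met / S_W) * (N_W / N_met) * C_W`, followed by the
#' relaxation correction (divide by the metabolite factor, multiply by the
#' water factor).  `S_met` is the total metabolite resonance signal; a
#' per-proton fit amplitude must be multiplied by `n_met` first (see
#' [metabolite_signal()]).
#'
#' @param s_met Metabolite signal (scalar or map).
#' @param s_w Water signal (scalar or map); zero water yields `NA`.
#' @param n_met Protons contributing to the fitted resonance.
#' @param ctx A [quant_context()].
#' @return Concentration(s) in mM.
#' @export
quantify_internal_water <- function(s_met, s_w, n_met, ctx) {
  out <- ifelse(s_w > 0,
                (s_met / s_w) * (ctx$n_w / n_met) * ctx$c_w * relax_ratio(ctx),
                NA_real_)
  out
}

#' Total resonance signal of a metabolite from a fit
#' @param fit A `fit_result`.
#' @param met Metabolite name.
#' @return Fitted amplitude scaled by the proton count of the entry.
#' @export
metabolite_signal <- function(fit, met) {
  unname(fit$concentrations[met] * fit$n_protons[met])
}

#' Absolute concentration by contralateral referencing
#'
#' `C_met = (S_met / S_met_CLref) * C_met_CLref`, where the reference
#' concentration was obtained by internal water referencing in
#' contralateral normal-appearing tissue.
#'
#' @param s_met Metabolite signal(s) in the target voxel(s).
#' @param s_met_clref Reference metabolite signal (must be > 0).
#' @param c_met_clref Reference concentration (mM).
#' @return Concentration(s) in mM.
#' @export
quantify_contralateral_ref <- function(s_met, s_met_clref, c_met_clref) {
  if (is.na(s_met_clref) || s_met_clref <= 0)
    stop("missing or nonpositive contralateral reference signal")
  (s_met / s_met_clref) * c_met_clref
}

#' Per-voxel concentration maps for a fitted grid
#'
#' Quantifies every fitted voxel by internal water referencing against the
#' grid's PSF-matched water map, then (optionally) re-references the
#' tumor voxels to the mean of the QC-accepted contralateral voxels.
#'
#' @param fits [fit_grid()] results (after [quality_filter()]).
#' @param grid The `mrsi_grid` the fits came from (supplies the water map).
#' @param metabolites Metabolites to quantify.
#' @param ctx Optional [quant_context()]; defaults to the grid water map
#'   with no relaxation correction.
#' @param contralateral Logical; apply contralateral re-referencing using
#'   the scene's `CL` label (requires a scene-bearing grid).
#' @return Named list of concentration matrices (mM, `NA` outside fitted
#'   voxels).
#' @export
concentration_maps <- function(fits, grid, metabolites = c("Glu", "Gln"),
                               ctx = NULL, contralateral = FALSE) {
  idx <- attr(fits, "voxels")
  nr <- nrow(grid$voi_mask); nc <- ncol(grid$voi_mask)
  ctx <- ctx %||% quant_context(c_w = grid$water_conc)
  acc <- vapply(fits, function(f) isTRUE(f$accepted) || is.na(f$accepted),
                logical(1))
  maps <- list()
  for (met in metabolites) {
    m <- matrix(NA_real_, nr, nc)
    for (k in seq_len(nrow(idx))) {
      f <- fits[[k]]
      cw <- if (is.matrix(ctx$c_w)) ctx$c_w[idx[k, 1], idx[k, 2]] else ctx$c_w
      sw <- if (is.matrix(grid$water)) grid$water[idx[k, 1], idx[k, 2]]
            else grid$water
      ctx_v <- ctx; ctx_v$c_w <- cw
      m[idx[k, 1], idx[k, 2]] <-
        quantify_internal_water(metabolite_signal(f, met), sw,
                                f$n_protons[met], ctx_v)
    }
    if (contralateral && !is.null(grid$scene)) {
      cl <- grid$scene$labels == "CL"
      ref_vox <- which(cl, arr.ind = TRUE)
      keep <- logical(nrow(idx))
      for (k in seq_len(nrow(idx)))
        keep[k] <- cl[idx[k, 1], idx[k, 2]] && acc[k]
      if (any(keep)) {
        s_ref <- mean(vapply(which(keep), function(k)
          metabolite_signal(fits[[k]], met), numeric(1)))
        c_ref <- mean(m[cbind(idx[keep, 1], idx[keep, 2])])
        for (k in seq_len(nrow(idx))) {
          if (!cl[idx[k, 1], idx[k, 2]]) {
            m[idx[k, 1], idx[k, 2]] <-
              quantify_contralateral_ref(metabolite_signal(fits[[k]], met),
                                         s_ref, c_ref)
          }
        }
      }
    }
    maps[[met]] <- m
  }
  maps
}

#' Write a map to NIfTI
#' @param map Numeric matrix.
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = 6) {
  img <- RNifti::asNifti(array(map, c(dim(map), 1)),
                         pixdim = c(voxel_size_mm, voxel_size_mm, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
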