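# Linear-combination fitting: recovery on matched data, Fisher/CRLB/CMC
# algebra, SNR/FWHM estimation and the quality-control filter.

test_that("a lone Cr spectrum is recovered exactly", {
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr", "NAA"))
  g <- generate_phantom_spectrum(composition(c(Cr = 10)), basis,
                                 noise_model(noise_sd = 0,
                                             fwhm_ppm = 0.029), seed = 1)
  sp <- list(spectrum = g$spectra[1, 1, ], ppm_axis = g$ppm_axis,
             acq = basis$acq)
  f <- fit_spectrum(sp, basis, fit_config(noise_sd = 1))
  expect_lt(abs(f$concentrations[["Cr"]] - 10) / 10, 0.001)
  expect_true(all(f$concentrations[c("Glu", "Gln", "NAA")] <= 0.01 * 10))
})

test_that("noiseless phantom-2 amplitude ratios match the composition", {
  basis <- cached_basis(120, n_points = 2048,
                        metabolites = names(
                          reference_composition("phantom2")$concentrations))
  g <- generate_phantom_spectrum(reference_composition("phantom2"), basis,
                                 noise_model(noise_sd = 0,
                                             fwhm_ppm = 0.029), seed = 1)
  sp <- list(spectrum = g$spectra[1, 1, ], ppm_axis = g$ppm_axis,
             acq = basis$acq)
  f <- fit_spectrum(sp, basis, fit_config(noise_sd = 1))
  cr <- f$concentrations[["Cr"]]
  expect_equal(f$concentrations[["Glu"]] / cr, 1.00, tolerance = 0.02)
  expect_equal(f$concentrations[["Gln"]] / cr, 0.50, tolerance = 0.02)
  expect_equal(f$concentrations[["Cho"]] / cr, 0.30, tolerance = 0.02)
})

test_that("amplitudes are recovered on noiseless random compositions", {
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr", "NAA", "mI"))
  set.seed(99)
  for (rep in 1:20) {
    conc <- stats::runif(5, 2, 15)
    names(conc) <- names(basis$entries)
    g <- generate_phantom_spectrum(composition(conc), basis,
                                   noise_model(noise_sd = 0,
                                               fwhm_ppm = 0.025), seed = rep)
    sp <- list(spectrum = g$spectra[1, 1, ], ppm_axis = g$ppm_axis,
               acq = basis$acq)
    f <- fit_spectrum(sp, basis, fit_config(noise_sd = 1, maxit = 300))
    expect_lt(max(abs(f$concentrations - conc) / conc), 0.005)
  }
})

test_that("residual RMS matches the injected noise at SNR 27", {
  hh <- cached_healthy_fits(120)
  sig_t <- hh$noise$noise_sd
  sig_f <- sig_t * sqrt(dim(hh$grid$spectra)[3])
  rms <- vapply(hh$fits[1:20], function(f)
    sqrt(mean(c(Re(f$residual), Im(f$residual))^2)), numeric(1))
  expect_equal(mean(rms), sig_f, tolerance = 0.10)
})

test_that("Fisher information obeys the closed-form scalings", {
  # orthogonal two-entry design: diagonal F; doubling noise quarters F
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Gly", "Lac"))
  g <- generate_phantom_spectrum(composition(c(Gly = 5, Lac = 5)), basis,
                                 noise_model(noise_sd = 0,
                                             fwhm_ppm = 0.029), seed = 1)
  sp <- list(spectrum = g$spectra[1, 1, ], ppm_axis = g$ppm_axis,
             acq = basis$acq)
  f <- fit_spectrum(sp, basis, fit_config(noise_sd = 2))
  F1 <- fisher_information(f, noise_sd = 2)
  expect_lt(abs(F1["Gly", "Lac"]) / sqrt(F1["Gly", "Gly"] * F1["Lac", "Lac"]),
            0.02)
  F2 <- fisher_information(f, noise_sd = 4)
  expect_equal(unclass(F2)[, ], unclass(F1)[, ] / 4, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("CRLB percent follows the scalar closed form", {
  # single unit-norm basis vector b, amplitude C, noise sigma:
  # CRLB% = 100 sigma / (C ||b||)
  f <- structure(list(
    basis_at_fit = matrix(complex(real = c(3, 4) / 5), 2, 1,
                          dimnames = list(NULL, "M")),
    nuisance_at_fit = matrix(0i, 2, 0), baseline_at_fit = matrix(0, 4, 0),
    metabolites = "M", noise_sd = 0.5), class = "fit_result")
  F <- fisher_information(f, noise_sd = 0.5)
  expect_equal(unname(crlb_percent(F, c(M = 2))[["M"]]),
               100 * 0.5 / 2, tolerance = 1e-9)
  # halving C doubles CRLB%
  expect_equal(crlb_percent(F, c(M = 1))[["M"]],
               2 * crlb_percent(F, c(M = 2))[["M"]], tolerance = 1e-12)
  # zero amplitude reported as undefined, not infinite
  expect_true(is.na(crlb_percent(F, c(M = 0))[["M"]]))
})

test_that("CMC hits the collinearity limits", {
  mk_fit <- function(b1, b2) structure(list(
    basis_at_fit = cbind(A = b1, B = b2),
    nuisance_at_fit = NULL, baseline_at_fit = NULL,
    metabolites = c("A", "B"), noise_sd = 1), class = "fit_result")
  # orthogonal -> 0
  f <- mk_fit(complex(real = c(1, 0, 0, 0)), complex(real = c(0, 1, 0, 0)))
  expect_lt(abs(cmc(fisher_information(f, 1), "A", "B")), 1e-10)
  # nearly collinear (cosine 0.999) -> <= -0.99
  b1 <- complex(real = c(1, 0, 0.01, 0)); b1 <- b1 / sqrt(sum(Mod(b1)^2))
  th <- acos(0.999)
  b2 <- complex(real = cos(th) * Re(b1) + sin(th) * c(0, 1, 0, 0))
  f2 <- mk_fit(b1, b2)
  expect_lte(cmc(fisher_information(f2, 1), "A", "B"), -0.99)
  # invariant under joint rescaling of both basis vectors
  f3 <- mk_fit(7 * b1, 7 * b2)
  expect_equal(cmc(fisher_information(f3, 1), "A", "B"),
               cmc(fisher_information(f2, 1), "A", "B"), tolerance = 1e-12)
})

test_that("estimates are invariant to a common gain on data and noise", {
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr", "NAA"))
  sc <- make_healthy_scene(grid_dims = c(4, 4), voi_dims = c(4, 4), seed = 6)
  nm <- noise_model(noise_sd = 1.5, fwhm_ppm = 0.029)
  g <- generate_mrsi_grid(sc, basis, nm, seed = 2)
  sp <- list(spectrum = g$spectra[2, 2, ], ppm_axis = g$ppm_axis,
             acq = basis$acq)
  f1 <- fit_spectrum(sp, basis, fit_config(noise_sd = 1.5 * sqrt(1024)))
  k <- 3.7
  sp2 <- sp; sp2$spectrum <- sp$spectrum * k
  f2 <- fit_spectrum(sp2, basis,
                     fit_config(noise_sd = k * 1.5 * sqrt(1024)))
  expect_equal(f2$concentrations / k, f1$concentrations, tolerance = 1e-3)
  expect_equal(f2$crlb_pct, f1$crlb_pct, tolerance = 0.02)
  expect_equal(cmc(f2, "Glu", "Gln"), cmc(f1, "Glu", "Gln"),
               tolerance = 0.01)
})

test_that("SNR and FWHM estimates are consistent with the generator", {
  hh <- cached_healthy_fits(120)
  snr <- vapply(hh$fits, function(f) f$snr, numeric(1))
  fw <- vapply(hh$fits, function(f) f$fwhm, numeric(1))
  expect_equal(mean(snr), 27, tolerance = 0.15)
  expect_equal(mean(fw), 0.029, tolerance = 0.20)
  # doubling all concentrations doubles SNR
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr", "NAA"))
  nm <- noise_model(noise_sd = 1.2, fwhm_ppm = 0.029)
  g1 <- generate_phantom_spectrum(composition(c(Cr = 8, NAA = 12)), basis,
                                  nm, seed = 4)
  g2 <- generate_phantom_spectrum(composition(c(Cr = 16, NAA = 24)), basis,
                                  nm, seed = 4)
  f1 <- fit_spectrum(list(spectrum = g1$spectra[1, 1, ],
                          ppm_axis = g1$ppm_axis, acq = basis$acq), basis)
  f2 <- fit_spectrum(list(spectrum = g2$spectra[1, 1, ],
                          ppm_axis = g2$ppm_axis, acq = basis$acq), basis)
  expect_equal(f2$snr / f1$snr, 2, tolerance = 0.05)
})

test_that("empirical scatter is bounded below by the CRLB", {
  # 200 noisy replicates of one composition: SD(amplitude) >= mean CRLB
  # and <= 1.5x CRLB for the well-conditioned singlet metabolites
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr", "NAA", "mI"))
  conc <- c(Glu = 10.84, Gln = 2.94, Cr = 8, NAA = 12, mI = 6)
  nm <- noise_model(noise_sd = 0, fwhm_ppm = 0.029)
  nm$noise_sd <- calibrate_noise_sd(conc, basis, 27, nm)
  cfg <- fast_cfg()
  amps <- crlbs <- crlbs_marg <- NULL
  for (r in 1:200) {
    g <- generate_phantom_spectrum(composition(conc), basis, nm, seed = r)
    f <- fit_spectrum(list(spectrum = g$spectra[1, 1, ],
                           ppm_axis = g$ppm_axis, acq = basis$acq),
                      basis, cfg)
    amps <- rbind(amps, f$concentrations)
    crlbs <- rbind(crlbs, f$crlb_pct * f$concentrations / 100)
    Fm <- fisher_information(f, marginalize = TRUE)
    crlbs_marg <- rbind(crlbs_marg,
                        sqrt(diag(attr(Fm, "inverse"))))
  }
  for (m in c("Cr", "NAA")) {
    sd_emp <- stats::sd(amps[, m])
    # the conditioned CRLB is a lower bound on the scatter (5% sampling
    # slack); the estimator also carries nuisance-parameter variance, so
    # the upper comparison uses the nuisance-marginalized CRLB
    expect_gte(sd_emp, 0.95 * mean(crlbs[, m]))
    expect_lte(sd_emp, 1.5 * mean(crlbs_marg[, m]))
  }
})

test_that("quality filter applies the rejection rules with reasons", {
  hh <- cached_healthy_fits(120)
  f_good <- hh$fits[[1]]
  mk <- function(f, fwhm = NULL, snr = NULL) {
    if (!is.null(fwhm)) f$fwhm <- fwhm
    if (!is.null(snr)) f$snr <- snr
    f
  }
  res <- quality_filter(list(mk(f_good, fwhm = 0.12),
                             mk(f_good, snr = 2.9),
                             f_good), fit_config())
  expect_false(res[[1]]$accepted)
  expect_true("fwhm" %in% res[[1]]$reject_reasons)
  expect_false(res[[2]]$accepted)
  expect_true("snr" %in% res[[2]]$reject_reasons)
  expect_true(res[[3]]$accepted)
  # artifact masks are honored as an external exclusion
  res2 <- quality_filter(list(f_good), fit_config(),
                         artifact_mask = TRUE)
  expect_true("artifact" %in% res2[[1]]$reject_reasons)
})

test_that("mismatched axes raise an error", {
  basis <- cached_basis(120, n_points = 1024,
                        metabolites = c("Glu", "Gln", "Cr"))
  sp <- list(spectrum = complex(2048), ppm_axis = ppm_axis(acq_params()),
             acq = acq_params())
  expect_error(fit_spectrum(sp, basis, fit_config()), "axis")
})
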