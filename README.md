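# mrsiglx

Separate mapping of glutamate (Glu) and glutamine (Gln) from proton MR
spectroscopic imaging (MRSI) at 3 T is hard: their spectra overlap almost
completely between 2.0 and 2.5 ppm, so clinical studies usually report
only the sum (Glx).  Because both are J-coupled spin systems, a long echo
time (TE ≈ 120 ms) under a semi-LASER (sLASER) echo train drives their
multiplets into distinguishable phase patterns — Glu mostly in phase, Gln
a mix of in-phase and anti-phase — which a linear-combination fit can
separate.  `mrsiglx` implements that method end to end for researchers in
MRS methodology and neuro-oncology imaging:

- **Spin simulation** — density-matrix evolution of J-coupled metabolite
  spin systems (16 shipped, including 2HG) under an idealized sLASER echo
  train at arbitrary TE; TE-specific basis sets on a shared ppm axis.
- **Linear-combination fitting** — frequency-domain fit of each voxel
  with nonnegative amplitudes, phase/shift/damping nuisance parameters
  and a stiff spline baseline; Cramér–Rao lower bounds (CRLB%), the
  coefficient of modeling covariance (CMC) between any two metabolites
  from the Fisher information matrix, SNR/FWHM estimates, and the
  quality filter (reject FWHM > 0.1 ppm, SNR < 3, tCho CRLB ≥ 10%).
- **Quantification** — internal-water referencing
  `C_met = (S_met/S_W)(N_W/N_met) C_W` with PSF-matched tissue-water
  maps, contralateral referencing for tumor voxels, steady-state T1/T2
  relaxation correction.
- **Tumor subregions** — exact label-fraction computation, VOI-edge
  exclusion (a 12×12 VOI yields 100 analyzed spectra), the
  majority-fraction/top-3-with-ties voxel assignment rule, per-subregion
  summaries.
- **Statistics** — Bland–Altman scan–rescan agreement; Shapiro–Wilk-gated
  ANOVA+Tukey / Kruskal–Wallis+Dunn(BH) subregion comparisons.
- **Synthetic data** — phantom spectra and brain-tumor MRSI grids
  (per-voxel concentrations, linewidth distribution, frequency/phase
  jitter, complex Gaussian noise calibrated to a target SNR, paired
  low-resolution water grids, scan–rescan replicates), all pure
  functions of configuration and seed.

The core quantity for Glu/Gln distinguishability is the CMC,
`[F⁻¹]₁₂ / sqrt([F⁻¹]₁₁ [F⁻¹]₂₂)` with `F = JᵀJ/σ²` the Fisher matrix of
the metabolite amplitudes: values near −1 mean the fit cannot tell the
two models apart, values near 0 mean independent estimates.

## Worked example

Simulate the brain-mimicking phantom (10 mM Cr, 10 mM Glu, 5 mM Gln,
3 mM Cho, …) at TE 120 ms, fit it, and read concentrations off the Cr
reference:

```r
library(mrsiglx)

comp  <- reference_composition("phantom2")
basis <- make_basis_set(names(comp$concentrations), te = 120, acq_params())
ph    <- generate_phantom_spectrum(comp, basis,
                                   noise_model(noise_sd = 0, fwhm_ppm = 0.029))
fit   <- fit_spectrum(list(spectrum = ph$spectra[1, 1, ],
                           ppm_axis = ph$ppm_axis, acq = basis$acq),
                      basis, fit_config(noise_sd = 1))
round(fit$concentrations * 10 / fit$concentrations[["Cr"]], 3)
#>   Cr  Glu  Gln  Cho  GSH GABA   mI  Lac  NAA
#> 10.0 10.0  5.0  3.0  3.0  2.0  7.5  5.0 12.5
```

The fitted amplitudes, scaled to the known 10 mM creatine, reproduce the
full composition — the relaxation-free analog of a phantom validation.
The TE dependence of the Glu–Gln overlap is one line:

```r
round(te_separability_scan("Glu", "Gln", c(40, 80, 120), acq_params(),
                           lineshape_for_fwhm(0.029 * 127.73, 2)), 3)
#>    40    80   120
#> 0.603 0.012 0.358
```

Lower scores mean more separable basis shapes: the overlap at 120 ms is
roughly half that at the conventional 40 ms.  A full synthetic
tumor-scene analysis (fit, QC, quantification, subregion table, CMC map)
runs from one call:

```r
bundle <- run_pipeline(default_config(), out_dir = "out")
```

or from the shell via the thin wrapper `inst/cli/mrsiglx run config.yaml`.

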