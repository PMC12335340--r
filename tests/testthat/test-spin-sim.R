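# Spin-system loading and density-matrix simulation under the idealized
# echo train.

test_that("constants table loads all basis metabolites with valid systems", {
  mets <- c(std_metabolites(), "2HG")
  for (m in mets) {
    sys <- load_spin_system(m)
    expect_s3_class(sys, "spin_system")
    expect_true(isSymmetric(unname(sys$J)))
  }
  glu <- load_spin_system("Glu")
  expect_length(glu$protons, 5)
  expect_length(unique(glu$subsystems), 1)
  cr <- load_spin_system("Cr")
  expect_true(all(cr$J == 0))
  expect_setequal(unique(cr$groups), c("me", "ch2"))
  expect_length(unique(cr$subsystems), 2)
})

test_that("unknown metabolites and malformed tables are rejected", {
  expect_error(load_spin_system("Xx"), "unknown")
  bad <- list(
    shifts = data.frame(metabolite = "B", proton = c("a", "b"),
                        shift_ppm = c(1, 2), group = c("a", "b"),
                        subsystem = c("s1", "s2")),
    j = data.frame(metabolite = "B", proton_i = "a", proton_j = "b",
                   j_hz = 7))
  expect_error(load_spin_system("B", bad), "subsystems")
  bad2 <- list(
    shifts = data.frame(metabolite = "B", proton = c("a", "b"),
                        shift_ppm = c(1, 2), group = c("g", "g"),
                        subsystem = c("s1", "s1")),
    j = data.frame(metabolite = character(0), proton_i = character(0),
                   proton_j = character(0), j_hz = numeric(0)))
  expect_error(load_spin_system("B", bad2), "group")
})

test_that("uncoupled systems are TE-invariant and hermitian at t = 0", {
  acq <- acq_params()
  cr40 <- simulate_fid(load_spin_system("Cr"), sequence_timing(40), acq)
  cr120 <- simulate_fid(load_spin_system("Cr"), sequence_timing(120), acq)
  expect_lt(max(Mod(cr40$fid - cr120$fid)), 1e-10)
  expect_lt(abs(Im(cr40$fid[1])), 1e-10)
  # per-proton normalization: 5 protons give fid(0) = 5
  expect_equal(Re(cr40$fid[1]), 5, tolerance = 1e-10)
})

test_that("weak-coupling AX doublet follows cos(pi J TE)", {
  acq <- acq_params()
  # shift difference >> J so the secular approximation holds; the total
  # in-phase component is the (real) transverse magnetization at the echo
  # top, i.e. fid(0) / 2 per proton pair
  tab <- list(
    shifts = data.frame(metabolite = "AX", proton = c("A", "X"),
                        shift_ppm = c(0.5, 20), group = c("A", "X"),
                        subsystem = c("s1", "s1")),
    j = data.frame(metabolite = "AX", proton_i = "A", proton_j = "X",
                   j_hz = 10))
  ax <- load_spin_system("AX", tab)
  for (te in c(40, 50, 80, 100, 120, 144)) {
    s <- simulate_fid(ax, sequence_timing(te), acq)
    expect_lt(abs(Re(s$fid[1]) / 2 - cos(pi * 10 * te / 1000)), 0.02)
    # pure anti-phase at TE = 1/(2J): in-phase component vanishes
    if (te == 50) expect_lt(abs(Re(s$fid[1]) / 2), 0.02)
  }
})

test_that("oversized coupled blocks raise an explicit error", {
  acq <- acq_params()
  expect_error(
    simulate_fid(load_spin_system("Val"), sequence_timing(120), acq,
                 max_spins = 6),
    "exceeds")
})

test_that("sequence timing validates refocusing and TE consistency", {
  expect_error(sequence_timing(120, c(10, 10, 10, 10, 10)), "sum")
  expect_error(sequence_timing(100, c(50, 10, 10, 10, 20)), "refocusing")
  tm <- sequence_timing(120)
  expect_equal(sum(tm$delays), 120)
})

test_that("spectrum_from_fid maps frequencies and widths correctly", {
  acq <- acq_params()
  cr <- simulate_fid(load_spin_system("Cr"), sequence_timing(120), acq)
  sp <- spectrum_from_fid(cr$fid, acq, lineshape(3, 0))
  # the CH3 singlet (3 protons) is the tallest line: at 3.027 ppm +/- 1 bin
  pk <- sp$ppm_axis[which.max(Re(sp$spectrum))]
  bin <- acq$spectral_width / acq$n_points / acq$larmor_freq
  expect_lt(abs(pk - 3.027), bin + 1e-9)
  # Lorentzian FWHM gamma Hz -> gamma / larmor ppm (+/- 10%)
  half <- max(Re(sp$spectrum)) / 2
  above <- sp$ppm_axis[Re(sp$spectrum) > half &
                         abs(sp$ppm_axis - 3.027) < 0.2]
  fwhm <- diff(range(above)) + bin
  expect_equal(fwhm, 3 / acq$larmor_freq, tolerance = 0.10)
  # zero broadening keeps the transform invertible
  sp0 <- spectrum_from_fid(cr$fid, acq, lineshape(0, 0))
  back <- stats::fft(mrsiglx:::ifftshift(sp0$spectrum),
                     inverse = TRUE) / acq$n_points
  back[1] <- back[1] * 2   # undo the first-point convention
  expect_lt(max(Mod(back - cr$fid)), 1e-8)
  expect_error(spectrum_from_fid(complex(0), acq), "zero-length")
})

test_that("basis sets are deterministic, share an axis, and J-evolve", {
  acq <- acq_params(n_points = 1024)
  mets <- c("Glu", "Gln", "Cr", "Gly")
  b1 <- make_basis_set(mets, 120, acq)
  b2 <- make_basis_set(mets, 120, acq)
  expect_identical(b1$entries$Glu$fid, b2$entries$Glu$fid)
  expect_length(b1$entries, 4)
  b40 <- make_basis_set(mets, 40, acq)
  for (m in mets) {
    d <- max(Mod(b1$entries[[m]]$fid - b40$entries[[m]]$fid))
    if (m %in% c("Cr", "Gly")) expect_lt(d, 1e-10)   # pure singlets
    else expect_gt(d, 1e-3)                          # J-coupled
  }
})

test_that("total absorptive area at short TE scales with proton count", {
  # total spin conservation: at TE -> 0+ every proton contributes the
  # same absorptive (real) spectral area under the per-proton
  # normalization convention, for singlets and crowded multiplets alike.
  # (The magnitude-spectrum integral is subadditive where multiplet lines
  # overlap, so the area is measured on the real channel.)
  acq <- acq_params()
  tm <- sequence_timing(0.4)   # TE -> 0 limit
  ls <- lineshape(2, 0)
  per_proton <- NULL
  for (m in c("Cr", "Glu", "Lac", "mI")) {
    sys <- load_spin_system(m)
    sp <- spectrum_from_fid(simulate_fid(sys, tm, acq)$fid, acq, ls)
    tot <- sum(Re(sp$spectrum)) / length(sys$protons)
    if (is.null(per_proton)) per_proton <- tot
    expect_equal(tot, per_proton, tolerance = 0.01)
  }
})

test_that("in-phase fraction separates absorptive and anti-phase patterns", {
  acq <- acq_params()
  cr <- simulate_fid(load_spin_system("Cr"), sequence_timing(120), acq)
  # pure absorptive singlet: a real nonnegative line at one bin
  k <- 300
  sp <- spectrum_from_fid(rep(0i, acq$n_points), acq)
  sp$spectrum[k] <- 100 + 0i
  band <- sp$ppm_axis[c(k - 3, k + 3)]
  expect_equal(inphase_fraction(sp, band), 1.0, tolerance = 1e-9)
  nu <- (k - acq$n_points %/% 2 - 1) * acq$spectral_width / acq$n_points
  # anti-phase doublet: two opposite-sign on-bin lines
  fid2 <- exp(2i * pi * nu * time_axis(acq)) -
    exp(2i * pi * (nu + 20 * acq$spectral_width / acq$n_points) *
          time_axis(acq))
  sp2 <- spectrum_from_fid(fid2, acq)
  band2 <- sp$ppm_axis[c(k - 30, k + 50)]
  expect_lt(abs(inphase_fraction(sp2, band2)), 1e-6)
  expect_error(inphase_fraction(sp, c(20, 25)), "band")
})

test_that("Glu is more in-phase than Gln at 2.0-2.4 ppm at long TE", {
  b <- cached_basis(120, n_points = 1024, metabolites = c("Glu", "Gln"))
  ls <- lineshape_for_fwhm(0.029 * b$acq$larmor_freq, 2)
  ip <- vapply(b$entries, function(e)
    inphase_fraction(spectrum_from_fid(e$fid, b$acq, ls), c(2.0, 2.4)),
    numeric(1))
  expect_gt(ip[["Glu"]], ip[["Gln"]])
})

test_that("TE-separability scan behaves as a normalized overlap", {
  acq <- acq_params(n_points = 1024)
  s_self <- te_separability_scan("Glu", "Glu", c(40, 120), acq)
  expect_equal(unname(s_self), c(1, 1), tolerance = 1e-9)
  # two singlets >= 1 ppm apart with ~0.03 ppm linewidth: disjoint support
  tab <- list(
    shifts = data.frame(metabolite = c("S1", "S2"), proton = "H",
                        shift_ppm = c(2.0, 3.0), group = "H",
                        subsystem = "s1"),
    j = data.frame(metabolite = character(0), proton_i = character(0),
                   proton_j = character(0), j_hz = numeric(0)))
  s_far <- te_separability_scan("S1", "S2", 120, acq,
                                broadening = lineshape_for_fwhm(3.7, 2),
                                tables = tab)
  expect_lt(s_far[[1]], 0.01)
  s_gg <- te_separability_scan("Glu", "Gln", c(40, 120), acq,
                               broadening = lineshape_for_fwhm(3.7, 2))
  expect_lt(s_gg[["120"]], s_gg[["40"]])
})
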