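# sandwich hook model, peak calibration, monomer/polymer deconvolution,
# 4PL potency

test_that("sandwich signal limits: background, linearity, hook asymptote", {
  pa <- polymer_assay()
  expect_equal(sandwich_signal(species_mix(0, 0), pa), pa$background)
  # analyte far below antibody totals: signal linear in analyte within 1%
  s1 <- sandwich_signal(species_mix(polymer = 1e-12), pa) - pa$background
  s2 <- sandwich_signal(species_mix(polymer = 2e-12), pa) - pa$background
  expect_equal(s2 / s1, 2, tolerance = 0.01)
  # analyte far above: signal ~ 1/analyte (log-log slope -1)
  cc <- 10^seq(-4.5, -3.5, length.out = 5)
  sg <- vapply(cc, function(x)
    sandwich_signal(species_mix(polymer = x), pa) - pa$background,
    numeric(1))
  slopes <- diff(log(sg)) / diff(log(cc))
  expect_equal(slopes, rep(-1, 4), tolerance = 0.05)
  # monomer does not produce polymer-assay signal (capture Kd infinite)
  expect_equal(sandwich_signal(species_mix(monomer = 1e-7), pa),
               pa$background)
})

test_that("noiseless hook curves are unimodal with interior peaks far above the tails", {
  pa <- polymer_assay(); ta <- total_assay()
  dil <- 10^seq(0, 6, length.out = 121)
  for (mix in list(species_mix(polymer = 5e-6),
                   species_mix(monomer = 5e-6),
                   species_mix(monomer = 3e-6, polymer = 2e-6))) {
    assay <- if (mix[["polymer"]] > 0) pa else ta
    s <- serpinassay:::dilution_signals(mix, assay, dil) - assay$background
    i <- which.max(s)
    expect_gt(i, 1); expect_lt(i, length(s))
    # single interior maximum: rises then falls (tolerance at solver
    # precision)
    tol <- 1e-9 * s[i]
    expect_true(all(diff(s[1:i]) > -tol))
    expect_true(all(diff(s[i:length(s)]) < tol))
    # signal at extreme dilutions below 1% of peak
    expect_lt(s[length(s)] / s[i], 0.01)
    expect_lt(s[1] / s[i], 0.01)
  }
})

test_that("hook peak finding: symmetry, interpolation accuracy, monotone error", {
  # symmetric synthetic bell in log-dilution: exact centre
  d <- 10^seq(0, 4, length.out = 21)
  y <- exp(-(log(d) - log(100))^2)
  pk <- find_hook_peak(list(dilution_factors = d, fret_ratios = y))
  expect_equal(pk$peak_dilution, 100, tolerance = 1e-9)
  expect_true(pk$interior)
  # noiseless generator series: interpolated peak within 2% of a dense-grid
  # oracle even when the truth falls between grid points
  pa <- polymer_assay()
  mix <- species_mix(polymer = 1.7e-6)
  dense <- serpinassay:::dilution_signals(mix, pa, dense_dilutions(4001))
  d_true <- dense_dilutions(4001)[which.max(dense)]
  ser <- gen_dilution_series(mix, pa, dilutions = 10^seq(0, 5, by = 0.1),
                             cfg = generator_config(1, 0))
  expect_equal(find_hook_peak(ser)$peak_dilution, d_true, tolerance = 0.02)
  # strictly monotone series has no hook peak
  expect_error(find_hook_peak(list(dilution_factors = d,
                                   fret_ratios = sort(y))),
               "no interior peak")
})

test_that("dilution invariance: scaling the mix scales the peak dilution", {
  pa <- polymer_assay()
  base <- species_mix(monomer = 5e-7, polymer = 1e-6)
  d0 <- find_hook_peak(gen_dilution_series(base, pa,
                                           dilutions = dense_dilutions(201),
                                           cfg = generator_config(1, 0)))
  for (f in c(0.25, 0.5, 2, 4)) {
    scaled <- species_mix(5e-7 * f, 1e-6 * f)
    dpk <- find_hook_peak(gen_dilution_series(scaled, pa,
                                              dilutions = dense_dilutions(201),
                                              cfg = generator_config(1, 0)))
    expect_equal(dpk$peak_dilution / d0$peak_dilution, f, tolerance = 0.01)
  }
})

test_that("peak calibration has theoretical slope -1 and doubles with concentration", {
  pa <- polymer_assay()
  cal <- make_calibration(pa)
  expect_gt(cal$slope, -1.2); expect_lt(cal$slope, -0.8)
  expect_equal(cal$slope, -1, tolerance = 0.05)
  # concentration doubled => predicted peak fold-dilution doubled
  expect_equal(serpinassay:::predict_peak_dilution(cal, 2e-6) /
                 serpinassay:::predict_peak_dilution(cal, 1e-6),
               2, tolerance = 0.01)
  expect_error(calibrate_peaks(list(make_standard(1e-6, pa))),
               ">= 3")
})

test_that("polymer quantification: self-consistency, noisy recovery, monomer-only error", {
  pa <- polymer_assay()
  cal <- make_calibration(pa)
  # a standard re-quantified recovers its own concentration
  std <- make_standard(2e-6, pa)
  expect_equal(quantify_polymer(std$series, cal)$concentration, 2e-6,
               tolerance = 1e-3)
  # synthetic polymer-only sample at 1.7 uM, 3% noise, 20 seeds: within 10%
  recov <- vapply(1:20, function(s) quantify_polymer(
    gen_dilution_series(species_mix(polymer = 1.7e-6), pa,
                        dilutions = dense_dilutions(31),
                        cfg = generator_config(seed = s, noise_cv = 0.03)),
    cal)$concentration, numeric(1))
  expect_lt(abs(mean(recov) - 1.7e-6) / 1.7e-6, 0.10)
  expect_lt(median(abs(recov - 1.7e-6) / 1.7e-6), 0.10)
  # the literal peak-inversion method agrees on a noiseless sample
  clean <- gen_dilution_series(species_mix(polymer = 1.7e-6), pa,
                               dilutions = dense_dilutions(),
                               cfg = generator_config(1, 0))
  expect_equal(quantify_polymer(clean, cal, method = "peak")$concentration,
               1.7e-6, tolerance = 0.02)
  # monomer-only sample gives background-level series: no peak to quantify
  mono <- gen_dilution_series(species_mix(monomer = 2e-6), pa,
                              dilutions = dense_dilutions(31),
                              cfg = generator_config(1, 0))
  expect_error(quantify_polymer(mono, cal))
})

test_that("monomer deconvolution is exact at zero noise in the additive regime", {
  # independent antibody pools: the regime in which peak-subtraction is the
  # model's exact inverse
  pa <- polymer_assay(); ta <- total_assay()
  cal_p <- make_calibration(pa, "polymer", dilutions = dense_dilutions(201))
  cal_tp <- make_calibration(ta, "polymer", dilutions = dense_dilutions(201))
  cal_tm <- make_calibration(ta, "monomer", dilutions = dense_dilutions(201))
  for (m in c(1e-6, 3e-6)) for (p in c(3e-7, 1e-6, 3e-6)) {
    mix <- species_mix(monomer = m, polymer = p)
    pol_ser <- gen_dilution_series(mix, pa, dilutions = dense_dilutions(201),
                                   cfg = generator_config(1, 0),
                                   shared_antibodies = FALSE)
    tot_ser <- gen_dilution_series(mix, ta, dilutions = dense_dilutions(201),
                                   cfg = generator_config(1, 0),
                                   shared_antibodies = FALSE)
    p_est <- quantify_polymer(pol_ser, cal_p)$concentration
    expect_equal(p_est, p, tolerance = 1e-3)
    dec <- deconvolve_monomer(tot_ser, p_est, cal_tp, cal_tm)
    expect_equal(dec$monomer, m, tolerance = 1e-3)
  }
})

test_that("peak-position subtraction is exact for the species-blind total assay", {
  # with pooled antibodies the total assay reads monomer + polymer subunits
  # as one analyte, so inverting the peak-position calibration and
  # subtracting the (known) polymer concentration recovers monomer
  ta <- total_assay()
  cal_tm <- make_calibration(ta, "monomer", dilutions = dense_dilutions(201))
  cal_tp <- make_calibration(ta, "polymer", dilutions = dense_dilutions(201))
  for (m in c(1e-6, 3e-6)) for (p in c(1e-6, 3e-6)) {
    tot_ser <- gen_dilution_series(species_mix(m, p), ta,
                                   dilutions = dense_dilutions(201),
                                   cfg = generator_config(1, 0),
                                   shared_antibodies = TRUE)
    dec <- deconvolve_monomer(tot_ser, p, cal_tp, cal_tm,
                              method = "peak-position")
    expect_equal(dec$monomer, m, tolerance = 0.02)
  }
})

test_that("monomer recovery on the 3x3 mix grid at 3% noise stays within 15% median error", {
  pa <- polymer_assay(); ta <- total_assay()
  cal_p <- make_calibration(pa, "polymer")
  cal_tp <- make_calibration(ta, "polymer")
  cal_tm <- make_calibration(ta, "monomer",
                             concs = c(0.5, 1, 2, 4, 8, 16) * 1e-6)
  grid <- expand.grid(m = c(1, 3, 10) * 1e-6, p = c(0.3, 1, 3) * 1e-6)
  errs <- unlist(lapply(seq_len(nrow(grid)), function(g) {
    vapply(1:20, function(s) {
      mix <- species_mix(monomer = grid$m[g], polymer = grid$p[g])
      cfgp <- generator_config(seed = 100 * g + s, noise_cv = 0.03,
                               replicate_count = 3)
      cfgt <- generator_config(seed = 100 * g + s + 50, noise_cv = 0.03,
                               replicate_count = 3)
      pol_ser <- gen_dilution_series(mix, pa, dilutions = dense_dilutions(31),
                                     cfg = cfgp, shared_antibodies = FALSE)
      tot_ser <- gen_dilution_series(mix, ta, dilutions = dense_dilutions(31),
                                     cfg = cfgt, shared_antibodies = FALSE)
      p_est <- quantify_polymer(pol_ser, cal_p)$concentration
      dec <- deconvolve_monomer(tot_ser, p_est, cal_tp, cal_tm)
      abs(dec$monomer - grid$m[g]) / grid$m[g]
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.15)
})

test_that("cross-species antibody competition biases polymer quantification upward", {
  # with shared antibody pools, monomer hooks the detection antibody of the
  # polymer assay and shifts its peak toward higher dilution; the additive
  # deconvolution premise therefore overestimates polymer. This quantifies
  # the approximation error instead of hiding it.
  pa <- polymer_assay()
  cal_p <- make_calibration(pa, "polymer")
  mix <- species_mix(monomer = 3e-6, polymer = 1e-6)
  shared <- gen_dilution_series(mix, pa, dilutions = dense_dilutions(31),
                                cfg = generator_config(1, 0),
                                shared_antibodies = TRUE)
  p_est <- quantify_polymer(shared, cal_p)$concentration
  expect_gt(p_est, 1e-6)          # biased upward
  expect_lt(p_est, 10e-6)         # but bounded
})

test_that("deconvolution degenerate and inconsistent cases", {
  ta <- total_assay()
  cal_tp <- make_calibration(ta, "polymer")
  cal_tm <- make_calibration(ta, "monomer")
  tot_ser <- gen_dilution_series(species_mix(monomer = 2e-6), ta,
                                 dilutions = dense_dilutions(61),
                                 cfg = generator_config(1, 0),
                                 shared_antibodies = FALSE)
  # zero polymer: plain inversion of the monomer calibration
  dec <- deconvolve_monomer(tot_ser, 0, cal_tp, cal_tm)
  expect_equal(dec$monomer, 2e-6, tolerance = 2e-3)
  # a gross polymer overestimate is inconsistent with the observed peak
  expect_error(deconvolve_monomer(tot_ser, 1e-4, cal_tp, cal_tm,
                                  method = "peak-position"),
               "inconsistent composition")
})

test_that("pre/post-treatment monomer fold change is recovered within 20%", {
  # generative scenario: sevenfold rise in circulating monomer at fixed
  # polymer, as in the treated transgenic-mouse plasma
  pa <- polymer_assay(); ta <- total_assay()
  cal_p <- make_calibration(pa, "polymer")
  cal_tp <- make_calibration(ta, "polymer")
  cal_tm <- make_calibration(ta, "monomer",
                             concs = c(0.5, 1, 2, 4, 8, 16) * 1e-6)
  run_one <- function(m, p, seed) {
    mix <- species_mix(monomer = m, polymer = p)
    ps <- gen_dilution_series(mix, pa, dilutions = dense_dilutions(31),
                              cfg = generator_config(seed, 0.03, 3),
                              shared_antibodies = FALSE)
    ts <- gen_dilution_series(mix, ta, dilutions = dense_dilutions(31),
                              cfg = generator_config(seed + 7, 0.03, 3),
                              shared_antibodies = FALSE)
    p_est <- quantify_polymer(ps, cal_p)$concentration
    deconvolve_monomer(ts, p_est, cal_tp, cal_tm)$monomer
  }
  folds <- vapply(1:10, function(s)
    run_one(7e-6, 1e-6, 1000 + s) / run_one(1e-6, 1e-6, 2000 + s),
    numeric(1))
  expect_lt(abs(mean(folds) - 7) / 7, 0.2)
})

test_that("4PL fitting: printed-potency recovery, flat flag, Monte-Carlo accuracy", {
  crv <- gen_dose_response(cfg = generator_config(2, 0))
  f <- fit_4pl(crv)
  expect_equal(f$pXC50, 8.3, tolerance = 1e-6)
  # all-equal responses: flat flag, no error
  flat <- fit_4pl(list(doses = 10^seq(-9, -4), responses = rep(50, 6)))
  expect_true(flat$flat)
  # 100-seed recovery at 3% noise of the cellular potency 6.3
  est <- vapply(1:100, function(s) fit_4pl(gen_dose_response(
    truth = list(pXC50 = 6.3, hill = 1, bottom = 0, top = 100),
    doses = 1e-4 / 3^(0:10),
    cfg = generator_config(seed = s, noise_cv = 0.03)))$pXC50, numeric(1))
  expect_lt(abs(mean(est) - 6.3), 0.05)
  expect_lt(sd(est), 0.1)
})

test_that("response normalization and secretion fold change", {
  expect_equal(normalize_response(10, 10, 60), 0)
  expect_equal(normalize_response(60, 10, 60), 100)
  expect_equal(normalize_response(35, 10, 60), 50)
  expect_error(normalize_response(5, 10, 10), "differ")
  # threefold secretion scenario: fitted top/bottom reports the maximal fold
  crv <- gen_dose_response(truth = list(pXC50 = 6.5, hill = 1, bottom = 100,
                                        top = 300),
                           cfg = generator_config(4, 0))
  expect_equal(fold_change(fit_4pl(crv)), 3, tolerance = 1e-6)
})
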