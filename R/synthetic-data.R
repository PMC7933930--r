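## Seeded synthetic-data generators for every assay type the package
## analyses. Each generator draws multiplicative log-normal (mean-one)
## noise scaled by the config's noise CV, records the generative truth on
## the returned object, and is byte-reproducible for a fixed seed.
## Defaults are the campaign's printed assay conditions (5 nM analyte,
## 37 degC/72 h polymerisation end point, 1 degC/min thermal ramp,
## 0-240 min depletion time points, 8-h TID dosing).

#' Generate pseudo-first-order association traces
#'
#' One trace per compound concentration following
#' `F(t) = baseline + amplitude * exp(-kobs * t)` with
#' `kobs = kon * [C] + koff`, plus multiplicative noise.
#'
#' @param truth list with `kon` (1/M/s), `koff` (1/s), `amplitude`,
#'   `baseline`. Defaults are the Z-protein scenario (`kon = 4.1e4`).
#' @param concentrations compound concentrations (M), > 0.
#' @param cfg a [generator_config()].
#' @param times sampling times (s); default 200 points over 5 half-lives of
#'   the slowest trace.
#' @param variant_label free-text variant tag stored on each trace.
#' @return list of `association_trace` objects (each with `times`,
#'   `intensity`, `compound_concentration`, `variant_label`, `truth`).
#' @export
gen_association_traces <- function(truth = list(kon = 4.1e4, koff = 1.3e-4,
                                                amplitude = 1, baseline = 0.2),
                                   concentrations = c(5, 10, 20, 40) * 1e-6,
                                   cfg = generator_config(),
                                   times = NULL, variant_label = "Z") {
  assert_that(all(concentrations > 0), "concentrations must be > 0")
  assert_that(truth$kon > 0 && truth$koff > 0,
              "rate constants must be > 0")
  with_seed(cfg$seed, {
    lapply(concentrations, function(cc) {
      kobs <- truth$kon * cc + truth$koff
      tt <- if (is.null(times)) seq(0, 5 * log(2) / kobs, length.out = 200)
            else times
      f <- truth$baseline + truth$amplitude * exp(-kobs * tt)
      structure(list(times = tt, intensity = apply_noise(f, cfg$noise_cv),
                     compound_concentration = cc,
                     variant_label = variant_label,
                     truth = c(truth, list(kobs = kobs))),
                class = "association_trace")
    })
  })
}

#' Generate a competition-binding curve
#'
#' Signals computed from the exact ternary equilibrium
#' ([solve_competitive_equilibrium()]) through the polarization signal
#' model, plus multiplicative noise. A grid that does not span the
#' tracer-displacement range triggers a warning.
#'
#' @param truth list with `pKD_competitor` (default 8.5, the Z-protein
#'   scenario; `-Inf` pKD i.e. infinite Kd encodes a non-binder).
#' @param assay list with `receptor_total`, `tracer_total`, `tracer_Kd`
#'   (M) and the `signal_free`/`signal_bound` plateaus.
#' @param concentrations competitor concentrations (M); default 12-point
#'   3-fold dilutions from 10 uM.
#' @param cfg a [generator_config()].
#' @return object of class `competition_curve` with
#'   `competitor_concentrations`, `signals`, `assay`, `truth`.
#' @export
gen_competition_curve <- function(truth = list(pKD_competitor = 8.5),
                                  assay = list(receptor_total = 1e-8,
                                               tracer_total = 2e-9,
                                               tracer_Kd = 5e-9,
                                               signal_free = 50,
                                               signal_bound = 200),
                                  concentrations = 1e-5 / 3^(0:11),
                                  cfg = generator_config()) {
  assert_that(all(concentrations > 0), "concentrations must be > 0")
  assert_that(assay$receptor_total > 0 && assay$tracer_total > 0 &&
                assay$tracer_Kd > 0, "assay concentrations and Kd must be > 0")
  pKD <- truth$pKD_competitor
  noiseless <- competition_signal(concentrations, pKD, assay$receptor_total,
                                  assay$tracer_total, assay$tracer_Kd,
                                  assay$signal_free, assay$signal_bound)
  if (is.finite(pKD)) {
    full_span <- abs(
      competition_signal(0, pKD, assay$receptor_total, assay$tracer_total,
                         assay$tracer_Kd, assay$signal_free,
                         assay$signal_bound) - assay$signal_free)
    if (full_span > 0 && diff(range(noiseless)) < 0.8 * full_span)
      warning("competitor grid does not span the tracer-displacement range")
  }
  with_seed(cfg$seed, {
    structure(list(competitor_concentrations = concentrations,
                   signals = apply_noise(noiseless, cfg$noise_cv),
                   assay = assay, truth = truth),
              class = "competition_curve")
  })
}

#' Generate a sandwich-assay dilution series
#'
#' Evaluates the equilibrium sandwich model over a fold-dilution grid of a
#' monomer/polymer stock mix and adds multiplicative noise. In noiseless
#' mode the curve is unimodal (hook effect) whenever the peak lies inside
#' the grid.
#'
#' @param mix a [species_mix()] (stock concentrations, M).
#' @param assay an [assay_definition()].
#' @param dilutions fold-dilution factors (>= 1, strictly increasing);
#'   default 16 log-spaced points from 1 to 1e5.
#' @param cfg a [generator_config()].
#' @param shared_antibodies passed to [sandwich_signal()].
#' @return object of class `dilution_series` with `dilution_factors`,
#'   `fret_ratios`, `mix`, `assay`, `truth`.
#' @export
gen_dilution_series <- function(mix, assay,
                                dilutions = 10^seq(0, 5, length.out = 16),
                                cfg = generator_config(),
                                shared_antibodies = TRUE) {
  assert_that(all(dilutions >= 1) && all(diff(dilutions) > 0),
              "dilutions must be >= 1 and strictly increasing")
  noiseless <- dilution_signals(mix, assay, dilutions, shared_antibodies)
  with_seed(cfg$seed, {
    ## replicate_count independent noisy realizations, reported as their
    ## mean (the usual plate-assay readout); noise is mean-one so the
    ## average converges on the noiseless curve
    reps <- vapply(seq_len(cfg$replicate_count),
                   function(r) apply_noise(noiseless, cfg$noise_cv),
                   numeric(length(noiseless)))
    structure(list(dilution_factors = dilutions,
                   fret_ratios = rowMeans(as.matrix(reps)),
                   replicates = as.matrix(reps),
                   mix = mix, assay = assay,
                   truth = list(monomer = mix[["monomer"]],
                                polymer = mix[["polymer"]],
                                shared_antibodies = shared_antibodies)),
              class = "dilution_series")
  })
}

#' Generate a 4PL dose-response curve
#'
#' @param truth list with `pXC50`, `hill`, `bottom`, `top`; default is the
#'   TR-FRET polymerisation-inhibition scenario (`pXC50 = 8.3`).
#' @param doses doses (M); default 11-point 3-fold dilutions from 10 uM.
#' @param cfg a [generator_config()].
#' @return object of class `dose_response_curve` with `doses`, `responses`,
#'   `truth`.
#' @export
gen_dose_response <- function(truth = list(pXC50 = 8.3, hill = 1,
                                           bottom = 0, top = 100),
                              doses = 1e-5 / 3^(0:10),
                              cfg = generator_config()) {
  assert_that(all(doses > 0), "doses must be > 0")
  assert_that(truth$top != truth$bottom, "top and bottom must differ")
  x <- log10(doses)
  noiseless <- truth$bottom + (truth$top - truth$bottom) /
    (1 + 10^(truth$hill * (-truth$pXC50 - x)))
  with_seed(cfg$seed, {
    structure(list(doses = doses,
                   responses = apply_noise(noiseless, cfg$noise_cv),
                   truth = truth),
              class = "dose_response_curve")
  })
}

#' Three-state unfolding scenario parameters
#'
#' Ground-truth parameter sets placing the intermediate-occupancy peak at
#' the apo (1.3 M GdnHCl) or compound-bound (1.9 M) position, with equal
#' m-values of 2.5 kcal/mol/M.
#'
#' @param scenario `"apo"` or `"bound"`.
#' @return a [three_state_params()].
#' @export
unfolding_scenario <- function(scenario = c("apo", "bound")) {
  scenario <- match.arg(scenario)
  if (scenario == "apo")
    three_state_params(dG1 = 2.8, dG2 = 3.7, m1 = 2.5, m2 = 2.5,
                       amp_I = 1, base_N = 0.05, base_U = 0.05)
  else
    three_state_params(dG1 = 4.2, dG2 = 5.3, m1 = 2.5, m2 = 2.5,
                       amp_I = 1, base_N = 0.05, base_U = 0.05)
}

#' Generate a three-state unfolding curve
#'
#' Dye intensity proportional to the intermediate fraction plus baselines
#' and multiplicative noise; the truth records the analytic peak position.
#'
#' @param truth a [three_state_params()]; default the apo scenario
#'   (peak 1.3 M).
#' @param denaturant_grid denaturant concentrations (M); default 0-4 M in
#'   0.1 M steps.
#' @param cfg a [generator_config()].
#' @return object of class `unfolding_curve` with `denaturant`,
#'   `intensity`, `truth` (including `peak_denaturant`).
#' @export
gen_unfolding_curve <- function(truth = unfolding_scenario("apo"),
                                denaturant_grid = seq(0, 4, by = 0.1),
                                cfg = generator_config()) {
  assert_that(all(diff(denaturant_grid) > 0),
              "denaturant grid must be strictly increasing")
  noiseless <- three_state_signal(truth, denaturant_grid)
  with_seed(cfg$seed, {
    structure(list(denaturant = denaturant_grid,
                   intensity = apply_noise(noiseless, cfg$noise_cv),
                   truth = c(unclass(truth),
                             list(peak_denaturant =
                                    intermediate_peak_denaturant(truth)))),
              class = "unfolding_curve")
  })
}

#' Generate a stoichiometry-of-inhibition titration
#'
#' Residual protease activity `max(0, 1 - ratio / SI)` plus multiplicative
#' noise.
#'
#' @param truth list with `SI` >= 1.
#' @param ratios serpin:protease molar ratios, >= 0.
#' @param cfg a [generator_config()].
#' @return object of class `si_titration` with `ratios`,
#'   `residual_activity`, `truth`.
#' @export
gen_si_titration <- function(truth = list(SI = 1),
                             ratios = seq(0, 2.5, by = 0.25),
                             cfg = generator_config()) {
  assert_that(truth$SI >= 1, "SI must be >= 1")
  assert_that(all(ratios >= 0), "ratios must be >= 0")
  noiseless <- pmax(0, 1 - ratios / truth$SI)
  with_seed(cfg$seed, {
    structure(list(ratios = ratios,
                   residual_activity = apply_noise(noiseless, cfg$noise_cv),
                   truth = truth),
              class = "si_titration")
  })
}

#' Generate a hepatocyte substrate-depletion series
#'
#' ln(peak-area ratio) linear in time with slope implied by the intrinsic
#' clearance through the scaling chain
#' `CLint_per_cell = CLint_per_g / hepatocellularity`;
#' `slope = -CLint_per_cell * cell_density`. Noise is applied
#' multiplicatively to the area ratio (so additively, on the log scale).
#'
#' @param truth list with `CLint_per_g` (ml/min/g); default the mouse
#'   hepatocyte scenario (4.56).
#' @param cell_density incubation cell density (cells/ml), default 0.5e6.
#' @param hepatocellularity liver cell content (cells/g), default 120e6.
#' @param times sampling times (min), >= 3; default the 0-240 min design.
#' @param cfg a [generator_config()].
#' @return object of class `depletion_series` with `times`, `ln_ratio`,
#'   `truth`.
#' @export
gen_depletion_series <- function(truth = list(CLint_per_g = 4.56),
                                 cell_density = 0.5e6,
                                 hepatocellularity = 120e6,
                                 times = c(0, 20, 40, 60, 120, 240),
                                 cfg = generator_config()) {
  assert_that(length(times) >= 3, "need >= 3 time points")
  assert_that(cell_density > 0 && hepatocellularity > 0,
              "cell_density and hepatocellularity must be > 0")
  slope <- -truth$CLint_per_g / hepatocellularity * cell_density
  ratio <- exp(slope * times)
  with_seed(cfg$seed, {
    structure(list(times = times,
                   ln_ratio = log(apply_noise(ratio, cfg$noise_cv)),
                   truth = c(truth, list(slope = slope,
                                         cell_density = cell_density,
                                         hepatocellularity =
                                           hepatocellularity))),
              class = "depletion_series")
  })
}

#' Generate a PK concentration-profile fixture
#'
#' Deterministic wrapper around [simulate_tid_pk()] recording the
#' generative parameters as truth; used to build test fixtures for NCA and
#' threshold computations.
#'
#' @param params a [pk_params()].
#' @param sink a [sink_params()] (defaults: 5 uM sink, 1.5 nM Kd).
#' @param regimen a [dose_regimen()].
#' @return a `concentration_profile` with a `truth` element attached.
#' @export
gen_pk_truth_fixture <- function(params = pk_params(),
                                 sink = sink_params(),
                                 regimen = dose_regimen(100)) {
  prof <- simulate_tid_pk(params, sink, regimen)
  prof$truth <- list(params = params, sink = sink, regimen = regimen)
  prof
}
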