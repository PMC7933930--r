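## Equilibrium sandwich TR-FRET model with high-dose hook effect,
## peak-position calibration, and deconvolution of monomeric vs polymeric
## antitrypsin from paired total/polymer-specific assays.
##
## The sandwich requires one capture-side and one detection-side antibody on
## the same analyte subunit; at analyte excess the two antibody pools are
## captured on *different* molecules and the doubly-bound fraction collapses,
## producing the bell-shaped signal-vs-dilution curves used throughout.

#' Define a sandwich immunoassay
#'
#' Effective two-antibody model of a four-antibody TR-FRET sandwich
#' (primary + labelled secondary on each side): effective totals are the
#' limiting reagent of each side. Per-species dissociation constants allow a
#' species-specific capture side (`Inf` encodes non-binding, e.g. a
#' polymer-specific monoclonal that does not recognise monomer).
#'
#' @param capture_antibody_total,detection_antibody_total effective totals (M).
#' @param Kd_capture,Kd_detection named numeric vectors of per-species
#'   dissociation constants (M), names matching the species mix
#'   (`monomer`, `polymer`); `Inf` = non-binding.
#' @param signal_scale FRET-ratio units per M of doubly-bound subunit.
#' @param background FRET-ratio background.
#' @return object of class `assay_definition`.
#' @export
assay_definition <- function(capture_antibody_total, detection_antibody_total,
                             Kd_capture, Kd_detection,
                             signal_scale = 1e9, background = 0.05) {
  assert_that(capture_antibody_total > 0 && detection_antibody_total > 0,
              "antibody totals must be > 0")
  assert_that(any(is.finite(Kd_capture) & is.finite(Kd_detection[names(Kd_capture)])),
              "at least one species must bind both antibodies")
  structure(list(capture_antibody_total = capture_antibody_total,
                 detection_antibody_total = detection_antibody_total,
                 Kd_capture = Kd_capture, Kd_detection = Kd_detection,
                 signal_scale = signal_scale, background = background),
            class = "assay_definition")
}

#' Default polymer-specific and total-antitrypsin assay definitions
#'
#' Defaults follow the plasma immunoassay reagent concentrations: the
#' polymer assay captures through a polymer-specific monoclonal whose
#' donor-labelled secondary (1.5 nM) is limiting; the total assay captures
#' through an all-forms monoclonal at about 1.1 nM. Both detect through an
#' all-forms polyclonal whose acceptor-labelled secondary caps the effective
#' detection pool at 30 nM. Antibody affinities default to 1 nM (capture
#' monoclonals) and 2 nM (detection polyclonal) per subunit epitope.
#'
#' @param shared_detection unused placeholder kept for config round-trips.
#' @return an `assay_definition`.
#' @name default_assays
#' @export
polymer_assay <- function(shared_detection = TRUE) {
  assay_definition(
    capture_antibody_total = 1.5e-9,
    detection_antibody_total = 3.0e-8,
    Kd_capture = c(monomer = Inf, polymer = 1e-9),
    Kd_detection = c(monomer = 2e-9, polymer = 2e-9),
    signal_scale = 2e9, background = 0.05)
}

#' @rdname default_assays
#' @export
total_assay <- function(shared_detection = TRUE) {
  assay_definition(
    capture_antibody_total = 1.13e-9,
    detection_antibody_total = 3.0e-8,
    Kd_capture = c(monomer = 1e-9, polymer = 1e-9),
    Kd_detection = c(monomer = 2e-9, polymer = 2e-9),
    signal_scale = 2e9, background = 0.05)
}

#' Species mix of monomeric and polymeric antitrypsin
#'
#' Concentrations are in subunit equivalents (one capture epitope and one
#' detection epitope per subunit for the antibody classes that bind it).
#'
#' @param monomer,polymer concentrations in M subunit equivalents, >= 0.
#' @return named numeric vector of class `species_mix`.
#' @export
species_mix <- function(monomer = 0, polymer = 0) {
  assert_that(monomer >= 0 && polymer >= 0, "species must be >= 0")
  structure(c(monomer = monomer, polymer = polymer), class = "species_mix")
}

## Free antibody concentration given per-species epitope totals and Kds:
## conservation  Ab_total = Ab_free + sum_s  S_s * Ab_free / (Ab_free + Kd_s)
## (single-site occupancy per epitope, epitopes independent). Monotone in
## Ab_free, bracketed on [0, Ab_total].
free_antibody <- function(ab_total, species, Kd) {
  fin <- is.finite(Kd[names(species)]) & species > 0
  if (!any(fin)) return(ab_total)
  s <- species[fin]; k <- Kd[names(species)][fin]
  g <- function(a) a + sum(s * a / (a + k)) - ab_total
  a <- uniroot(g, c(0, ab_total), tol = .Machine$double.eps * ab_total,
               maxiter = 1000L)$root
  for (i in 1:3) {
    dg <- 1 + sum(s * k / (a + k)^2)
    an <- a - g(a) / dg
    if (an < 0 || an > ab_total) break
    a <- an
  }
  a
}

#' Equilibrium sandwich TR-FRET signal for a species mix
#'
#' Solves the free capture- and detection-antibody concentrations from
#' single-site conservation over all analyte epitopes (the two epitopes of a
#' subunit bind independently) and returns
#' `background + signal_scale * sum_s [s] * p_capture(s) * p_detection(s)`,
#' with `p = free_ab / (free_ab + Kd)`. With `shared_antibodies = FALSE`
#' each species is given its own antibody pools (no cross-species
#' competition), the regime in which peak-subtraction deconvolution is exact.
#'
#' @param mix a [species_mix()] (M subunit equivalents at the instrument).
#' @param assay an [assay_definition()].
#' @param shared_antibodies species compete for the same antibody pools
#'   (default, physically realistic).
#' @return FRET ratio (scalar).
#' @export
sandwich_signal <- function(mix, assay, shared_antibodies = TRUE) {
  sp <- unclass(mix)
  if (all(sp <= 0)) return(assay$background)
  kA <- assay$Kd_capture[names(sp)]
  kB <- assay$Kd_detection[names(sp)]
  bound <- if (shared_antibodies) {
    A <- free_antibody(assay$capture_antibody_total, sp, assay$Kd_capture)
    B <- free_antibody(assay$detection_antibody_total, sp, assay$Kd_detection)
    sum(sp * (A / (A + kA)) * (B / (B + kB)), na.rm = TRUE)
  } else {
    sum(vapply(names(sp), function(s) {
      one <- sp[s]
      A <- free_antibody(assay$capture_antibody_total, one,
                         assay$Kd_capture[s])
      B <- free_antibody(assay$detection_antibody_total, one,
                         assay$Kd_detection[s])
      one * (A / (A + kA[s])) * (B / (B + kB[s]))
    }, numeric(1)), na.rm = TRUE)
  }
  assay$background + assay$signal_scale * bound
}

## Noiseless dilution-series evaluation of a stock mix.
dilution_signals <- function(mix, assay, dilution_factors,
                             shared_antibodies = TRUE) {
  vapply(dilution_factors, function(d)
    sandwich_signal(species_mix(mix[["monomer"]] / d, mix[["polymer"]] / d),
                    assay, shared_antibodies), numeric(1))
}

#' Locate the hook-effect peak of a dilution series
#'
#' Grid argmax of the FRET ratio over dilution factors, refined by a local
#' three-point quadratic interpolation in log-dilution (ties broken toward
#' the lower dilution). A strictly monotone series has no hook peak and
#' raises an error; a peak on the grid edge is returned but flagged
#' non-interior.
#'
#' @param series list with `dilution_factors` (>= 1, strictly increasing)
#'   and `fret_ratios`, e.g. from [gen_dilution_series()].
#' @return object of class `peak_estimate`: `peak_dilution`, `peak_signal`,
#'   `interior`, `method`.
#' @export
find_hook_peak <- function(series) {
  d <- series$dilution_factors; y <- series$fret_ratios
  assert_that(length(d) >= 5 && length(d) == length(y),
              "need >= 5 (dilution, signal) points")
  assert_that(all(diff(d) > 0), "dilution factors must be strictly increasing")
  if (all(diff(y) >= 0) || all(diff(y) <= 0))
    stop("no interior peak: series is monotone", call. = FALSE)
  i <- which.max(y)           # which.max takes the first (lower-dilution) tie
  n <- length(y)
  if (i == 1L || i == n) {
    return(structure(list(peak_dilution = d[i], peak_signal = y[i],
                          interior = FALSE, method = "grid-max"),
                     class = "peak_estimate"))
  }
  ## 3-point quadratic through the log-dilution points around the argmax;
  ## a vertex outside the bracketing points (noise-degenerate parabola)
  ## falls back to the grid argmax
  x <- log(d[(i - 1):(i + 1)]); z <- y[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (z[2] - z[1]) + x[2] * (z[1] - z[3]) + x[1] * (z[3] - z[2])) /
    denom
  b <- (x[3]^2 * (z[1] - z[2]) + x[2]^2 * (z[3] - z[1]) +
          x[1]^2 * (z[2] - z[3])) / denom
  if (is.finite(a) && a < 0) {
    xv <- -b / (2 * a)
    if (xv >= x[1] && xv <= x[3]) {
      c0 <- z[1] - a * x[1]^2 - b * x[1]
      return(structure(list(peak_dilution = exp(xv),
                            peak_signal = a * xv^2 + b * xv + c0,
                            interior = TRUE, method = "quadratic-interp"),
                       class = "peak_estimate"))
    }
  }
  structure(list(peak_dilution = d[i], peak_signal = y[i],
                 interior = TRUE, method = "grid-max"),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Hook peak: dilution %.4g, signal %.4g (%s%s)\n",
              x$peak_dilution, x$peak_signal, x$method,
              if (x$interior) "" else ", NON-INTERIOR"))
  invisible(x)
}

#' Calibrate hook-peak positions against known concentrations
#'
#' Builds the peak-position calibration used for quantification: the log
#' peak *dilution fraction* (1 / fold-dilution) is regressed on the log
#' known stock concentration. Because the analyte concentration at the hook
#' peak is a constant of the assay, the theoretical slope is -1 (the peak
#' fold-dilution doubles when the stock concentration doubles). The pooled
#' signal-vs-analyte-concentration curve of all standards is stored for
#' signal-space deconvolution.
#'
#' @param standards list of `list(concentration = M, series = DilutionSeries)`.
#' @return object of class `calibration_model`: `slope`, `intercept` (of
#'   `log(1/peak_dilution) ~ log(concentration)`), `peak_signals`,
#'   `signal_curve` (function of analyte M), `background`,
#'   `concentration_range`, `peak_analyte_concentration`.
#' @export
calibrate_peaks <- function(standards) {
  assert_that(length(standards) >= 3, "need >= 3 calibration standards")
  conc <- vapply(standards, `[[`, numeric(1), "concentration")
  assert_that(max(conc) / min(conc) >= 8,
              "standards must span >= 8-fold in concentration")
  peaks <- lapply(standards, function(s) find_hook_peak(s$series))
  interior <- vapply(peaks, `[[`, logical(1), "interior")
  if (any(!interior)) {
    warning(sum(!interior), " standard(s) with non-interior peak excluded")
    standards <- standards[interior]; peaks <- peaks[interior]
    conc <- conc[interior]
    assert_that(length(standards) >= 3, "fewer than 3 usable standards")
  }
  pd <- vapply(peaks, `[[`, numeric(1), "peak_dilution")
  ps <- vapply(peaks, `[[`, numeric(1), "peak_signal")
  fit <- lm(log(1 / pd) ~ log(conc))
  cf <- coef(fit)

  ## pooled signal vs analyte concentration at the instrument
  ac <- unlist(lapply(standards, function(s)
    s$concentration / s$series$dilution_factors))
  sg <- unlist(lapply(standards, function(s) s$series$fret_ratios))
  o <- order(ac)
  ac <- ac[o]; sg <- sg[o]
  curve <- approxfun(log(ac), sg, rule = 2)
  signal_curve <- function(analyte_M) curve(log(pmax(analyte_M, min(ac))))
  background <- min(sg)
  ## analyte concentration at the peak: standard conc / its peak dilution
  cpk <- exp(mean(log(conc / pd)))

  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 peak_dilutions = pd, peak_signals = ps,
                 concentrations = conc,
                 signal_curve = signal_curve, background = background,
                 peak_analyte_concentration = cpk,
                 analyte_grid_range = range(ac),
                 concentration_range = range(conc), fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Hook-peak calibration\n")
  cat(sprintf("  log(peak fraction) = %.3f %+.3f * log(conc)   (theory slope -1)\n",
              x$intercept, x$slope))
  cat(sprintf("  valid range: %.3g - %.3g M; peak analyte conc %.3g M\n",
              x$concentration_range[1], x$concentration_range[2],
              x$peak_analyte_concentration))
  invisible(x)
}

## Predicted peak fold-dilution for a given stock concentration.
predict_peak_dilution <- function(cal, concentration)
  1 / exp(cal$intercept + cal$slope * log(concentration))

## Least-squares alignment of an observed dilution series to the
## calibration's pooled bell shape: the sample concentration only shifts
## the curve along log-dilution, so the best-fitting shift estimates the
## concentration using every point of the series (far more noise-robust
## than the vertex of a local parabola, and identical to peak-position
## comparison in the noiseless limit).
align_to_calibration <- function(d, y, cal, span = 1) {
  rng <- log(cal$concentration_range)
  obj <- function(lc) {
    conc_at_instrument <- exp(lc) / d
    keep <- conc_at_instrument >= cal$analyte_grid_range[1] &
      conc_at_instrument <= cal$analyte_grid_range[2]
    if (sum(keep) < 5) return(Inf)
    mean((y[keep] - cal$signal_curve(conc_at_instrument[keep]))^2)
  }
  opt <- optimize(obj, c(rng[1] - span, rng[2] + span), tol = 1e-10)
  exp(opt$minimum)
}

#' Quantify polymer from the hook-effect position of a sample
#'
#' `method = "template"` (default) estimates the concentration by
#' least-squares alignment of the whole bell-shaped series to the
#' calibration's pooled signal curve along log-dilution; `method = "peak"`
#' inverts the peak-position calibration at the sample's interpolated hook
#' peak only. The two coincide in the noiseless limit; the alignment uses
#' every point and is markedly more precise on noisy series. Samples whose
#' implied concentration is outside the calibrated range are flagged
#' `extrapolated`.
#'
#' @param sample a dilution series of the polymer-specific assay.
#' @param cal a [calibrate_peaks()] model built from polymer standards.
#' @param method `"template"` or `"peak"`.
#' @return object of class `polymer_quant`: `concentration` (M),
#'   `peak`, `extrapolated`, `method`.
#' @export
quantify_polymer <- function(sample, cal, method = c("template", "peak")) {
  method <- match.arg(method)
  pk <- find_hook_peak(sample)
  if (!pk$interior)
    stop("no interior peak in sample series", call. = FALSE)
  conc <- if (method == "peak")
    exp((log(1 / pk$peak_dilution) - cal$intercept) / cal$slope)
  else align_to_calibration(sample$dilution_factors, sample$fret_ratios, cal)
  structure(list(concentration = conc, peak = pk, method = method,
                 extrapolated = conc < cal$concentration_range[1] ||
                   conc > cal$concentration_range[2]),
            class = "polymer_quant")
}

#' @export
print.polymer_quant <- function(x, ...) {
  cat(sprintf("Polymer concentration: %.4g M%s\n", x$concentration,
              if (x$extrapolated) "  [extrapolated]" else ""))
  invisible(x)
}

#' Deconvolve the monomer concentration from a total-antitrypsin assay
#'
#' Implements peak-subtraction deconvolution: the polymer concentration
#' (from the polymer-specific assay) predicts, through the total-assay
#' polymer calibration, the polymer contribution to the FRET signal at the
#' total-assay hook peak of the sample; the residual signal is inverted
#' through the rising branch of the total-assay monomer calibration. The
#' `"peak-position"` method instead inverts the peak-dilution calibration to
#' the total subunit concentration and subtracts the polymer concentration
#' directly (exact when the total assay is species-blind).
#'
#' @param total_series total-assay dilution series of the sample.
#' @param polymer_conc polymer concentration (M) from [quantify_polymer()].
#' @param cal_total_polymer,cal_total_monomer total-assay calibrations built
#'   from polymer-only and monomer-only standards.
#' @param method `"curve-subtraction"` (default): the polymer contribution
#'   predicted from the total-assay polymer calibration is subtracted at
#'   every dilution and the monomer concentration is read from the hook-peak
#'   position of the residual curve — well-conditioned for any
#'   monomer:polymer ratio. `"peak-signal"`: subtraction and signal-space
#'   inversion at the total-assay peak only (ill-conditioned when monomer
#'   dominates the peak, kept for comparison). `"peak-position"`: inverts
#'   the peak-dilution calibration to total subunits and subtracts the
#'   polymer concentration (exact only for a species-blind total assay
#'   with pooled antibodies).
#' @param noise_allowance fraction of the observed peak signal by which the
#'   predicted polymer contribution may exceed it before the composition is
#'   declared inconsistent.
#' @return object of class `monomer_deconvolution`: `monomer` (M),
#'   `polymer` (M, as supplied), `clipped`, `method`, `peak`.
#' @export
deconvolve_monomer <- function(total_series, polymer_conc, cal_total_polymer,
                               cal_total_monomer,
                               method = c("curve-subtraction", "peak-signal",
                                          "peak-position"),
                               noise_allowance = 0.1) {
  method <- match.arg(method)
  assert_that(polymer_conc >= 0, "polymer_conc must be >= 0")
  pk <- find_hook_peak(total_series)
  if (!pk$interior)
    stop("no interior peak in total-assay series", call. = FALSE)
  clipped <- FALSE

  if (method == "curve-subtraction") {
    d <- total_series$dilution_factors
    bg <- cal_total_polymer$background
    contrib_p <- if (polymer_conc > 0)
      cal_total_polymer$signal_curve(polymer_conc / d) - bg
    else rep(0, length(d))
    residual <- total_series$fret_ratios - contrib_p
    if (min(residual) < bg - noise_allowance * (pk$peak_signal - bg))
      stop("inconsistent composition: predicted polymer contribution exceeds observed signal",
           call. = FALSE)
    rs <- list(dilution_factors = d, fret_ratios = residual)
    mono_pk <- tryCatch(find_hook_peak(rs), error = function(e) NULL)
    if (is.null(mono_pk) || !mono_pk$interior ||
        mono_pk$peak_signal - bg <
          noise_allowance * (pk$peak_signal - bg)) {
      monomer <- 0; clipped <- TRUE
    } else {
      monomer <- align_to_calibration(d, residual, cal_total_monomer)
      pk <- mono_pk
    }
  } else if (method == "peak-position") {
    total_conc <- exp((log(1 / pk$peak_dilution) - cal_total_monomer$intercept) /
                        cal_total_monomer$slope)
    monomer <- total_conc - polymer_conc
    if (monomer < -noise_allowance * total_conc)
      stop("inconsistent composition: polymer exceeds total", call. = FALSE)
    if (monomer < 0) { monomer <- 0; clipped <- TRUE }
  } else {
    bg <- cal_total_polymer$background
    contrib_p <- if (polymer_conc > 0)
      cal_total_polymer$signal_curve(polymer_conc / pk$peak_dilution) - bg
    else 0
    residual <- pk$peak_signal - bg - contrib_p
    if (residual < -noise_allowance * (pk$peak_signal - bg))
      stop("inconsistent composition: predicted polymer contribution exceeds observed peak signal",
           call. = FALSE)
    if (residual <= 0) {
      monomer <- 0; clipped <- TRUE
    } else {
      ## invert the rising branch of the monomer signal curve
      cm <- cal_total_monomer
      cpk <- cm$peak_analyte_concentration
      lo <- cm$analyte_grid_range[1]
      f <- function(cc) cm$signal_curve(cc) - cm$background - residual
      if (f(cpk) < 0) {
        ## residual at or above the monomer curve maximum: take the peak conc
        monomer_at_instrument <- cpk
      } else {
        monomer_at_instrument <- uniroot(f, c(lo, cpk), tol = lo * 1e-9)$root
      }
      monomer <- monomer_at_instrument * pk$peak_dilution
    }
  }
  structure(list(monomer = monomer, polymer = polymer_conc,
                 clipped = clipped, method = method, peak = pk),
            class = "monomer_deconvolution")
}

#' @export
print.monomer_deconvolution <- function(x, ...) {
  cat(sprintf("Monomer deconvolution (%s): monomer %.4g M, polymer %.4g M%s\n",
              x$method, x$monomer, x$polymer,
              if (x$clipped) "  [clipped at 0]" else ""))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (x50 - log10 dose)))`,
#' reporting the potency as `pXC50 = -x50`. Curves with less than 20%
#' dynamic range are returned with a `flat` flag instead of an error so
#' non-responders survive batch analysis; a midpoint outside the dosed
#' range is flagged `out_of_range`.
#'
#' @param curve list with `doses` (M, >= 6) and `responses`, e.g. from
#'   [gen_dose_response()].
#' @return object of class `fourpl_fit`: `pXC50`, `hill`, `bottom`, `top`,
#'   `flat`, `out_of_range`, `vcov`, `fitted`, `residuals`.
#' @export
fit_4pl <- function(curve) {
  d <- curve$doses; y <- curve$responses
  assert_that(length(d) >= 6 && length(d) == length(y),
              "need >= 6 (dose, response) points")
  assert_that(all(d > 0), "doses must be > 0")
  x <- log10(d)
  rng <- diff(range(y))
  if (rng < 0.2 * max(abs(y), .Machine$double.eps)) {
    return(structure(list(pXC50 = NA_real_, hill = NA_real_,
                          bottom = mean(y), top = mean(y), flat = TRUE,
                          out_of_range = NA, vcov = NULL,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y)),
                     class = "fourpl_fit"))
  }
  bottom0 <- min(y); top0 <- max(y)
  hill0 <- if (suppressWarnings(stats::cor(x, y)) >= 0) 1 else -1
  mid <- (bottom0 + top0) / 2
  x50_0 <- x[which.min(abs(y - mid))]
  df <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^(hill * (x50 - x))), data = df,
    start = list(bottom = bottom0, top = top0, hill = hill0, x50 = x50_0),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000,
                                         ftol = 1e-12))
  cf <- coef(fit)
  structure(list(pXC50 = -unname(cf[["x50"]]), hill = unname(cf[["hill"]]),
                 bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
                 flat = FALSE,
                 out_of_range = cf[["x50"]] < min(x) || cf[["x50"]] > max(x),
                 vcov = tryCatch(vcov(fit), error = function(e) NULL),
                 fitted = fitted(fit), residuals = residuals(fit), fit = fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$flat) {
    cat("4PL fit: FLAT curve (dynamic range < 20%)\n")
  } else {
    cat(sprintf("4PL fit: pXC50 = %.3f, hill = %.3f, bottom = %.3g, top = %.3g%s\n",
                x$pXC50, x$hill, x$bottom, x$top,
                if (isTRUE(x$out_of_range)) "  [midpoint outside dosed range]"
                else ""))
  }
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...)
  c(pXC50 = object$pXC50, hill = object$hill, bottom = object$bottom,
    top = object$top)

#' Maximal fold change of a fitted dose-response
#'
#' Ratio of the fitted top to bottom plateau, used to report e.g. the
#' maximal fold increase in secreted protein over vehicle.
#'
#' @param fit a `fourpl_fit`.
#' @return dimensionless fold.
#' @export
fold_change <- function(fit) {
  assert_that(inherits(fit, "fourpl_fit") && !fit$flat,
              "need a non-flat fourpl_fit")
  fit$top / fit$bottom
}

#' Normalize a raw response to vehicle and saturating control
#'
#' `100 * (raw - vehicle) / (control - vehicle)`: percent of the maximal
#' effect defined by a saturating control, 0% at vehicle.
#'
#' @param raw raw response value(s).
#' @param vehicle_level,saturating_control_level the two anchor levels.
#' @return percent effect.
#' @export
normalize_response <- function(raw, vehicle_level, saturating_control_level) {
  assert_that(saturating_control_level != vehicle_level,
              "control and vehicle levels must differ")
  100 * (raw - vehicle_level) / (saturating_control_level - vehicle_level)
}
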