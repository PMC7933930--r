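## Conformational stability (thermal shift, three-state chemical
## denaturation reported by an intermediate-sensitive dye) and serpin
## inhibitory-stoichiometry titrations.

RT_KCAL <- 0.593   # kcal/mol at 25 degrees C

#' Three-state unfolding parameters
#'
#' N <-> I <-> U linear extrapolation model: each transition has a free
#' energy `dG_i - m_i * D` at denaturant concentration D, with `dG` in
#' kcal/mol at zero denaturant and `m` in kcal/mol/M.
#'
#' @param dG1,dG2 unfolding free energies (kcal/mol) of N->I and I->U.
#' @param m1,m2 denaturant m-values (kcal/mol/M), > 0.
#' @param amp_I dye response amplitude of the intermediate.
#' @param base_N,slope_N,base_U,slope_U linear native / unfolded baselines.
#' @return object of class `three_state_params`.
#' @export
three_state_params <- function(dG1, dG2, m1, m2, amp_I = 1,
                               base_N = 0.05, slope_N = 0,
                               base_U = 0.05, slope_U = 0) {
  assert_that(m1 > 0 && m2 > 0, "m-values must be > 0")
  structure(list(dG1 = dG1, dG2 = dG2, m1 = m1, m2 = m2, amp_I = amp_I,
                 base_N = base_N, slope_N = slope_N,
                 base_U = base_U, slope_U = slope_U),
            class = "three_state_params")
}

#' Equilibrium fractions of the three-state unfolding model
#'
#' Boltzmann-weighted occupancies of native (N), intermediate (I) and
#' unfolded (U) states with linear free-energy dependence on denaturant:
#' `K1 = exp(-(dG1 - m1 D)/RT)`, `K2 = exp(-(dG2 - m2 D)/RT)`,
#' `fN : fI : fU = 1 : K1 : K1 K2` (normalized to sum to one exactly).
#'
#' @param params a [three_state_params()].
#' @param denaturant denaturant concentrations (M), vectorized.
#' @return matrix with columns `fN`, `fI`, `fU`.
#' @export
three_state_fractions <- function(params, denaturant) {
  ## work in log space for numerical stability at extreme denaturant
  l1 <- -(params$dG1 - params$m1 * denaturant) / RT_KCAL
  l2 <- -(params$dG2 - params$m2 * denaturant) / RT_KCAL
  lw <- cbind(fN = 0, fI = l1, fU = l1 + l2)
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

#' Denaturant concentration of maximal intermediate occupancy
#'
#' Closed form for the N <-> I <-> U linear-extrapolation model:
#' `D* = (dG1 + dG2 + RT log(m1/m2)) / (m1 + m2)`.
#'
#' @param params a [three_state_params()].
#' @return denaturant concentration (M) at peak intermediate occupancy.
#' @export
intermediate_peak_denaturant <- function(params)
  (params$dG1 + params$dG2 + RT_KCAL * log(params$m1 / params$m2)) /
    (params$m1 + params$m2)

## Noiseless dye signal of the three-state model: intermediate-sensitive
## dye with linear native and unfolded baselines.
three_state_signal <- function(params, denaturant) {
  f <- three_state_fractions(params, denaturant)
  (params$base_N + params$slope_N * denaturant) * f[, "fN"] +
    params$amp_I * f[, "fI"] +
    (params$base_U + params$slope_U * denaturant) * f[, "fU"]
}

#' Fit a three-state unfolding curve
#'
#' Least-squares fit of the intermediate-reported three-state model to a
#' dye-fluorescence denaturation profile, returning the fitted parameters
#' and the denaturant concentration at maximal intermediate occupancy (the
#' analytic peak of the fitted model). A curve without a rise-and-fall
#' raises a "no intermediate detected" error.
#'
#' @param curve list with `denaturant` (M, increasing) and `intensity`,
#'   e.g. from [gen_unfolding_curve()].
#' @param fit_baseline_slopes also fit linear baseline slopes (default
#'   intercept-only baselines).
#' @return object of class `three_state_fit`: `params`, `peak_denaturant`,
#'   `fitted`, `residuals`.
#' @export
fit_three_state <- function(curve, fit_baseline_slopes = FALSE) {
  D <- curve$denaturant; y <- curve$intensity
  assert_that(length(D) == length(y) && length(D) >= 8,
              "need >= 8 (denaturant, intensity) points")
  i_max <- which.max(y)
  if (i_max <= 1L || i_max >= length(y) ||
      max(y) - max(y[1], y[length(y)]) <
        0.1 * diff(range(y)))
    stop("no intermediate detected: curve shows no interior rise and fall",
         call. = FALSE)

  ## starting values: peak position anchors dG sums; spread anchors m
  Dpk <- D[i_max]
  m0 <- 2.5
  amp0 <- max(y) - min(y)
  base0 <- min(y)
  half <- base0 + amp0 / 2
  left <- D[D < Dpk][which.min(abs(y[D < Dpk] - half))]
  right <- D[D > Dpk][which.min(abs(y[D > Dpk] - half))]
  if (length(left)) m0 <- max(1, RT_KCAL * 2.2 / max(Dpk - left, 0.2))
  dG1_0 <- m0 * (2 * Dpk - (if (length(right)) right else Dpk + 0.4))
  dG2_0 <- m0 * (if (length(right)) right else Dpk + 0.4)

  df <- data.frame(D = D, y = y)
  mk <- function(dG1, dG2, m1, m2, ampI, bN, bU, sN, sU)
    three_state_signal(three_state_params(dG1, dG2, m1, m2, ampI,
                                          bN, sN, bU, sU), D)
  fit <- if (fit_baseline_slopes) {
    minpack.lm::nlsLM(
      y ~ mk(dG1, dG2, m1, m2, ampI, bN, bU, sN, sU), data = df,
      start = list(dG1 = dG1_0, dG2 = dG2_0, m1 = m0, m2 = m0,
                   ampI = amp0 + base0, bN = base0, bU = base0,
                   sN = 0, sU = 0),
      lower = c(-Inf, -Inf, 0.05, 0.05, rep(-Inf, 5)),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 20000,
                                           ftol = 1e-12))
  } else {
    minpack.lm::nlsLM(
      y ~ mk(dG1, dG2, m1, m2, ampI, bN, bU, 0, 0), data = df,
      start = list(dG1 = dG1_0, dG2 = dG2_0, m1 = m0, m2 = m0,
                   ampI = amp0 + base0, bN = base0, bU = base0),
      lower = c(-Inf, -Inf, 0.05, 0.05, rep(-Inf, 3)),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 20000,
                                           ftol = 1e-12))
  }
  cf <- as.list(coef(fit))
  params <- three_state_params(cf$dG1, cf$dG2, cf$m1, cf$m2, cf$ampI,
                               cf$bN, if (fit_baseline_slopes) cf$sN else 0,
                               cf$bU, if (fit_baseline_slopes) cf$sU else 0)
  structure(list(params = params,
                 peak_denaturant = intermediate_peak_denaturant(params),
                 fitted = fitted(fit), residuals = residuals(fit), fit = fit),
            class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  p <- x$params
  cat("Three-state unfolding fit\n")
  cat(sprintf("  dG1 = %.2f, dG2 = %.2f kcal/mol; m1 = %.2f, m2 = %.2f kcal/mol/M\n",
              p$dG1, p$dG2, p$m1, p$m2))
  cat(sprintf("  intermediate peak at %.3f M denaturant\n", x$peak_denaturant))
  invisible(x)
}

#' @export
coef.three_state_fit <- function(object, ...) {
  p <- object$params
  c(dG1 = p$dG1, dG2 = p$dG2, m1 = p$m1, m2 = p$m2,
    peak_denaturant = object$peak_denaturant)
}

#' Fit a thermal-shift melting midpoint
#'
#' Boltzmann sigmoid fit of a dye-fluorescence thermal ramp,
#' `y = base + amp / (1 + exp((Tm - T)/slope))`, returning the transition
#' midpoint Tm. An alternative midpoint from the maximum of the smoothed
#' first derivative is available via `method = "derivative"`.
#'
#' @param curve list with `temperatures` (degC, increasing, >= 20 points
#'   over >= 20 degC) and `dye_fluorescence`.
#' @param method `"boltzmann"` (default) or `"derivative"`.
#' @return object of class `tm_fit`: `Tm` (degC), `method`, `fitted`.
#' @export
fit_thermal_midpoint <- function(curve, method = c("boltzmann", "derivative")) {
  method <- match.arg(method)
  Tt <- curve$temperatures; y <- curve$dye_fluorescence
  assert_that(length(Tt) >= 20 && diff(range(Tt)) >= 20,
              "need >= 20 points spanning >= 20 degC")
  rng <- diff(range(y))
  if (rng < 3 * sd(diff(y)) / sqrt(2) || rng == 0)
    stop("non-sigmoidal input: no transition detected", call. = FALSE)
  if (method == "derivative") {
    sm <- stats::smooth.spline(Tt, y, spar = 0.5)
    dgrid <- seq(min(Tt), max(Tt), length.out = 500)
    dy <- predict(sm, dgrid, deriv = 1)$y
    return(structure(list(Tm = dgrid[which.max(dy)], method = method,
                          fitted = predict(sm, Tt)$y),
                     class = "tm_fit"))
  }
  base0 <- min(y); amp0 <- max(y) - min(y)
  Tm0 <- Tt[which.min(abs(y - (base0 + amp0 / 2)))]
  df <- data.frame(Tt = Tt, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ base + amp / (1 + exp((Tm - Tt) / slope)), data = df,
    start = list(base = base0, amp = amp0, Tm = Tm0, slope = 1),
    lower = c(-Inf, 0, min(Tt), 0.01),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000))
  if (coef(fit)[["Tm"]] >= max(Tt) || coef(fit)[["Tm"]] <= min(Tt))
    stop("non-sigmoidal input: midpoint outside ramp", call. = FALSE)
  structure(list(Tm = unname(coef(fit)[["Tm"]]), method = method,
                 fitted = fitted(fit), fit = fit), class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Thermal midpoint: Tm = %.2f degC (%s)\n", x$Tm, x$method))
  invisible(x)
}

#' Fit the stoichiometry of inhibition from an activity titration
#'
#' The serpin:protease titration is linear while serpin still partitions
#' into inhibitory complex: residual activity falls as
#' `1 - ratio / SI` until the x-axis is reached. The SI is the abscissa
#' intercept of an OLS regression over the descending linear region
#' (residual activity within `band`, default [0.1, 0.9], avoiding the upper
#' plateau and x-axis censoring).
#'
#' @param titration list with `ratios` (mol serpin per mol protease) and
#'   `residual_activity` (fraction of uninhibited protease activity).
#' @param band activity band defining the linear region.
#' @return object of class `si_fit`: `SI`, `slope`, `intercept`,
#'   `n_used`.
#' @export
fit_si <- function(titration, band = c(0.1, 0.9)) {
  r <- titration$ratios; a <- titration$residual_activity
  assert_that(length(r) == length(a), "ratio/activity lengths differ")
  sel <- a >= band[1] & a <= band[2]
  if (sum(sel) < 2)
    stop("no descending linear region within the activity band",
         call. = FALSE)
  fit <- lm(a[sel] ~ r[sel])
  cf <- coef(fit)
  if (cf[2] >= -1e-10 * max(abs(a)))
    stop("no descending region: titration slope is non-negative",
         call. = FALSE)
  structure(list(SI = unname(-cf[1] / cf[2]), slope = unname(cf[2]),
                 intercept = unname(cf[1]), n_used = sum(sel), fit = fit),
            class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  cat(sprintf("Stoichiometry of inhibition: SI = %.3f (x-intercept of %d-point regression)\n",
              x$SI, x$n_used))
  invisible(x)
}

#' @export
coef.si_fit <- function(object, ...) c(SI = object$SI)

#' Percent loss of inhibitory activity between two SI determinations
#'
#' `100 * (1 - SI_ref / SI_treated)`: the fraction of serpin molecules
#' diverted from the inhibitory pathway under treatment, relative to the
#' reference stoichiometry.
#'
#' @param SI_ref,SI_treated stoichiometries of inhibition, both >= 1
#'   (`Inf` allowed for complete loss).
#' @return percent loss.
#' @export
percent_activity_loss <- function(SI_ref, SI_treated) {
  assert_that(SI_ref >= 1 && SI_treated >= 1, "SI values must be >= 1")
  100 * (1 - SI_ref / SI_treated)
}
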