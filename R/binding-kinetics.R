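## Association kinetics from intrinsic-fluorescence progress curves:
## single-exponential kobs fits, the pseudo-first-order kobs-vs-concentration
## regression giving the second-order association rate constant, and the
## derived dissociation rate from an independently measured affinity.

#' Fit a single-exponential association trace
#'
#' Least-squares fit of `F(t) = baseline + amplitude * exp(-kobs * t)` to a
#' fluorescence progress curve. Initial values come from the trace endpoints
#' and a log-linearization of the early decay; the fit is refined with
#' Levenberg-Marquardt (ftol 1e-10, up to 10,000 evaluations). A trace whose
#' amplitude is indistinguishable from zero raises a "no-signal" error,
#' distinct from fit non-convergence.
#'
#' @param trace an `association_trace` or list with numeric `times` (s,
#'   strictly increasing, >= 10 points) and `intensity`.
#' @return object of class `exp_fit`: `kobs` (1/s), `amplitude`, `baseline`,
#'   `fitted`, `residuals`, `rmse`.
#' @export
fit_single_exponential <- function(trace) {
  t <- trace$times; y <- trace$intensity
  assert_that(length(t) >= 10 && length(t) == length(y),
              "trace needs >= 10 (time, intensity) points")
  assert_that(all(diff(t) > 0), "times must be strictly increasing")

  n <- length(y)
  q <- max(3L, n %/% 4L)
  y_early <- mean(y[seq_len(q)])
  y_late <- mean(y[(n - q + 1L):n])
  resid_sd <- sd(diff(y)) / sqrt(2)           # noise floor from differencing
  if (abs(y_early - y_late) < 3 * max(resid_sd, .Machine$double.eps))
    stop("no-signal: trace amplitude indistinguishable from zero",
         call. = FALSE)

  baseline0 <- y_late
  amplitude0 <- y[1] - baseline0
  ## log-linearized rate guess from the first/last quartile means
  dt <- mean(t[(n - q + 1L):n]) - mean(t[seq_len(q)])
  ratio <- (y_early - baseline0) / amplitude0
  kobs0 <- if (is.finite(ratio) && ratio > 0 && ratio < 1)
    -log(ratio) / dt else 2 / (t[n] - t[1])
  kobs0 <- max(kobs0, 1e-6 / (t[n] - t[1]))

  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ b + a * exp(-k * t), data = df,
    start = list(b = baseline0, a = amplitude0, k = kobs0),
    lower = c(-Inf, -Inf, 0),
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                         ftol = 1e-10))
  cf <- coef(fit)
  assert_that(cf[["k"]] > 0, "fitted kobs must be > 0")
  structure(list(kobs = unname(cf[["k"]]),
                 amplitude = unname(cf[["a"]]),
                 baseline = unname(cf[["b"]]),
                 fitted = fitted(fit), residuals = residuals(fit),
                 rmse = sqrt(mean(residuals(fit)^2))),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Single-exponential fit: kobs = %.4g 1/s, amplitude = %.4g, baseline = %.4g (rmse %.3g)\n",
              x$kobs, x$amplitude, x$baseline, x$rmse))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...)
  c(kobs = object$kobs, amplitude = object$amplitude,
    baseline = object$baseline)

#' Second-order association rate constant from kobs vs concentration
#'
#' Ordinary least-squares regression of the pseudo-first-order model
#' `kobs = kon * [C] + koff`. The slope is the second-order association rate
#' constant kon; the intercept estimates the dissociation rate. A negative
#' fitted slope is flagged (`error_flag`) but the result is retained for
#' inspection. The regression is unweighted.
#'
#' @param kobs_list observed rates (1/s), one per concentration.
#' @param concentrations compound concentrations (M), >= 3 distinct values.
#' @return object of class `kon_fit`: `kon` (1/M/s), `intercept` (1/s),
#'   `error_flag`, `se`, `r_squared`.
#' @export
fit_kon <- function(kobs_list, concentrations) {
  assert_that(length(kobs_list) == length(concentrations),
              "kobs and concentration lengths differ")
  assert_that(length(unique(concentrations)) >= 2 &&
                length(concentrations) >= 2,
              "need >= 2 distinct concentrations (>= 3 recommended)")
  fit <- lm(kobs_list ~ concentrations)
  cf <- coef(fit)
  slope <- unname(cf[2]); icpt <- unname(cf[1])
  structure(list(
    kon = slope, intercept = icpt,
    error_flag = if (slope <= 0) "non-positive slope" else NA_character_,
    se = tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                  error = function(e) NA),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    fit = fit), class = "kon_fit")
}

#' @export
print.kon_fit <- function(x, ...) {
  cat(sprintf("Pseudo-first-order regression: kon = %.4g 1/M/s, intercept = %.4g 1/s\n",
              x$kon, x$intercept))
  if (!is.na(x$error_flag)) cat("  FLAG:", x$error_flag, "\n")
  invisible(x)
}

#' @export
coef.kon_fit <- function(object, ...)
  c(kon = object$kon, intercept = object$intercept)

#' Dissociation rate constant from kon and affinity
#'
#' `koff = kon * Kd = kon * 10^(-pKD)`: combines a measured association rate
#' constant with an independently determined affinity, so that
#' `log10(koff) = log10(kon) - pKD` exactly.
#'
#' @param kon association rate constant (1/M/s), > 0.
#' @param pKD affinity as -log10 of the dissociation constant (M).
#' @return koff in 1/s.
#' @export
derive_koff <- function(kon, pKD) {
  assert_that(kon > 0, "kon must be > 0")
  kon * 10^(-pKD)
}

#' Affinity selectivity fold between two targets
#'
#' `10^(pKD_a - pKD_b)`: how many-fold tighter target a binds than target b.
#'
#' @param pKD_a,pKD_b affinities as -log10 M.
#' @return dimensionless fold.
#' @export
selectivity_fold <- function(pKD_a, pKD_b) 10^(pKD_a - pKD_b)

#' Association half-time of a progress curve
#'
#' Fits the trace with [fit_single_exponential()] and returns
#' `t_half = ln(2) / kobs`. Half-times shorter than the stopped-flow
#' instrument dead time (default 10 s) are flagged `faster_than_dead_time`;
#' such traces are conventionally excluded from kon regressions.
#'
#' @param trace an `association_trace`.
#' @param dead_time instrument dead time in s.
#' @return object of class `half_time`: `t_half` (s), `kobs`,
#'   `faster_than_dead_time`.
#' @export
association_half_time <- function(trace, dead_time = 10) {
  f <- fit_single_exponential(trace)
  th <- log(2) / f$kobs
  structure(list(t_half = th, kobs = f$kobs,
                 faster_than_dead_time = th < dead_time,
                 dead_time = dead_time),
            class = "half_time")
}

#' @export
print.half_time <- function(x, ...) {
  cat(sprintf("Association half-time: %.3g s (kobs %.4g 1/s)%s\n", x$t_half,
              x$kobs,
              if (x$faster_than_dead_time) "  [faster than dead-time]" else ""))
  invisible(x)
}

#' End-to-end kinetics analysis over a set of association traces
#'
#' Fits each trace to a single exponential, regresses kobs on concentration
#' to obtain kon, and combines with a supplied pKD to derive koff. Traces
#' whose half-time falls below the instrument dead time are excluded from
#' the kon regression by default.
#'
#' @param traces list of `association_trace` objects (each carrying its
#'   `compound_concentration` in M).
#' @param pKD affinity used to derive koff (optional).
#' @param dead_time instrument dead time (s) for exclusion.
#' @param exclude_dead_time drop too-fast traces from the regression.
#' @return object of class `kinetics_result` with `kobs_by_concentration`,
#'   `kon`, `kobs_intercept`, `koff_derived`, `pKD_used`, `half_times`.
#' @export
analyze_association_kinetics <- function(traces, pKD = NULL, dead_time = 10,
                                         exclude_dead_time = TRUE) {
  fits <- lapply(traces, fit_single_exponential)
  kobs <- vapply(fits, `[[`, numeric(1), "kobs")
  conc <- vapply(traces, `[[`, numeric(1), "compound_concentration")
  th <- log(2) / kobs
  keep <- if (exclude_dead_time) th >= dead_time else rep(TRUE, length(th))
  assert_that(sum(keep) >= 2, "fewer than 2 usable traces for kon regression")
  kf <- fit_kon(kobs[keep], conc[keep])
  koff <- if (!is.null(pKD) && kf$kon > 0) derive_koff(kf$kon, pKD)
          else NA_real_
  structure(list(
    kobs_by_concentration = setNames(kobs, signif(conc, 6)),
    kon = kf$kon, kobs_intercept = kf$intercept,
    koff_derived = koff, pKD_used = pKD %||% NA_real_,
    half_times = th, excluded = !keep, kon_fit = kf,
    trace_fits = fits), class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("Association kinetics\n")
  cat(sprintf("  kon = %.4g 1/M/s (intercept %.4g 1/s)\n", x$kon,
              x$kobs_intercept))
  if (!is.na(x$koff_derived))
    cat(sprintf("  koff = kon * 10^(-pKD=%.2f) = %.4g 1/s\n", x$pKD_used,
                x$koff_derived))
  if (any(x$excluded))
    cat("  traces excluded (faster than dead-time):", sum(x$excluded), "\n")
  invisible(x)
}
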