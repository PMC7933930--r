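## Oral multiple-dose pharmacokinetics with a saturable high-affinity
## circulating target sink (quasi-equilibrium target-mediated disposition),
## plus the in vitro PK computations: intrinsic clearance from hepatocyte
## substrate depletion and the time-dependent-inhibition IC50 shift.

#' One-compartment oral PK parameters
#'
#' @param ka first-order absorption rate (1/h).
#' @param V apparent volume of distribution (L/kg).
#' @param CLu clearance referenced to free drug (L/h/kg).
#' @param fu_ns nonspecific unbound fraction (linear binding), in (0, 1].
#' @param F_oral oral bioavailability fraction.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(ka = 1.5, V = 2, CLu = 15, fu_ns = 0.2, F_oral = 0.8) {
  assert_that(ka > 0 && V > 0 && CLu > 0, "ka, V, CLu must be > 0")
  assert_that(fu_ns > 0 && fu_ns <= 1, "fu_ns must be in (0, 1]")
  assert_that(F_oral > 0 && F_oral <= 1, "F_oral must be in (0, 1]")
  structure(list(ka = ka, V = V, CLu = CLu, fu_ns = fu_ns, F_oral = F_oral),
            class = "pk_params")
}

#' Saturable circulating-sink parameters
#'
#' The circulating monomeric target acts as a high-capacity, high-affinity
#' binding sink for the drug. Defaults: 5 uM sink with 1.5 nM affinity.
#'
#' @param sink_total total sink concentration (M), >= 0.
#' @param sink_Kd sink dissociation constant (M), > 0.
#' @return object of class `sink_params`.
#' @export
sink_params <- function(sink_total = 5e-6, sink_Kd = 1.5e-9) {
  assert_that(sink_total >= 0 && sink_Kd > 0,
              "sink_total >= 0 and sink_Kd > 0 required")
  structure(list(sink_total = sink_total, sink_Kd = sink_Kd),
            class = "sink_params")
}

#' Oral TID dosing regimen
#'
#' @param dose dose in mg/kg, >= 0.
#' @param interval dosing interval in h (default 8).
#' @param doses_per_day doses per day (default 3, i.e. TID).
#' @param duration study duration in days.
#' @param molecular_weight compound molecular weight (g/mol).
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, interval = 8, doses_per_day = 3, duration = 6,
                         molecular_weight = 450) {
  assert_that(dose >= 0 && interval > 0 && duration > 0,
              "dose >= 0, interval > 0, duration > 0 required")
  structure(list(dose = dose, interval = interval,
                 doses_per_day = doses_per_day, duration = duration,
                 molecular_weight = molecular_weight),
            class = "dose_regimen")
}

#' Free drug concentration in the presence of the saturable sink
#'
#' Solves `C_total = C_free / fu_ns + sink_total * C_free / (sink_Kd +
#' C_free)` for the unique non-negative root: total drug partitions into
#' linearly bound (nonspecific, fraction `fu_ns` free) and sink-bound drug.
#' Quadratic closed form, numerically stable for all parameter regimes;
#' monotone increasing in `C_total`.
#'
#' @param C_total total concentration (M), vectorized.
#' @param fu_ns nonspecific unbound fraction.
#' @param sink a [sink_params()].
#' @return free concentration (M).
#' @export
free_from_total <- function(C_total, fu_ns, sink) {
  S <- sink$sink_total; Kd <- sink$sink_Kd
  if (S == 0) return(fu_ns * C_total)
  ## a Cf^2 + b Cf + c = 0, a = 1/fu, b = Kd/fu + S - Ct, c = -Ct Kd
  a <- 1 / fu_ns
  b <- Kd / fu_ns + S - C_total
  cc <- -C_total * Kd
  disc <- sqrt(pmax(b^2 - 4 * a * cc, 0))
  ## stable positive root (c <= 0 so the roots straddle zero)
  ifelse(C_total == 0, 0,
         ifelse(b <= 0, (-b + disc) / (2 * a), -2 * cc / (b + disc)))
}

#' Total drug concentration from free (closed-form inverse)
#'
#' @param C_free free concentration (M).
#' @param fu_ns nonspecific unbound fraction.
#' @param sink a [sink_params()].
#' @return total concentration (M).
#' @export
total_from_free <- function(C_free, fu_ns, sink)
  C_free / fu_ns + sink$sink_total * C_free / (sink$sink_Kd + C_free)

#' Simulate oral multiple-dose PK with the saturable sink
#'
#' One-compartment model with first-order absorption; elimination acts on
#' the free concentration (`dA/dt = ka*Agut - CLu*C_free`), with the free
#' concentration obtained at each step from the quasi-equilibrium sink
#' relation [free_from_total()]. Doses are superposed at the regimen
#' interval. Integrated with `deSolve::ode` (lsoda).
#'
#' @param params a [pk_params()].
#' @param sink a [sink_params()].
#' @param regimen a [dose_regimen()].
#' @param dt output time step (h).
#' @return object of class `concentration_profile`: `times` (h), `total`
#'   (M), `free` (M), `dose_times`, per-interval `cmax`/`cmin` tables.
#' @export
simulate_tid_pk <- function(params, sink, regimen, dt = 0.05) {
  mw <- regimen$molecular_weight
  dose_mol <- regimen$dose / 1000 / mw * params$F_oral   # mol/kg absorbed
  t_end <- regimen$duration * 24
  ## strictly interval-spaced dosing: doses_per_day * duration doses
  ## (TID at 8-h intervals is the q8h default)
  n_doses <- regimen$doses_per_day * regimen$duration
  dose_times <- (seq_len(n_doses) - 1L) * regimen$interval
  dose_times <- dose_times[dose_times < t_end]
  times <- sort(unique(c(seq(0, t_end, by = dt), dose_times)))

  if (dose_mol == 0) {
    prof <- list(times = times, total = numeric(length(times)),
                 free = numeric(length(times)),
                 amounts = data.frame(gut = numeric(length(times)),
                                      body = numeric(length(times))))
  } else {
    rhs <- function(t, y, p) {
      Ct <- y[2] / params$V
      Cf <- free_from_total(Ct, params$fu_ns, sink)
      list(c(-params$ka * y[1],
             params$ka * y[1] - params$CLu * Cf))
    }
    ev <- data.frame(var = "gut", time = dose_times, value = dose_mol,
                     method = "add")
    out <- deSolve::ode(y = c(gut = 0, body = 0), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        events = list(data = ev),
                        rtol = 1e-9, atol = 1e-15)
    if (attr(out, "istate")[1] < 0)
      stop("integrator failure: ", paste(attr(out, "istate"), collapse = " "),
           call. = FALSE)
    total <- out[, "body"] / params$V
    prof <- list(times = out[, "time"], total = pmax(total, 0),
                 free = free_from_total(pmax(total, 0), params$fu_ns, sink),
                 amounts = data.frame(gut = out[, "gut"],
                                      body = out[, "body"]))
  }

  ## per-dose Cmax / Cmin markers
  intervals <- data.frame(start = dose_times,
                          end = c(dose_times[-1], t_end))
  marks <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    sel <- prof$times >= intervals$start[i] & prof$times <= intervals$end[i]
    data.frame(dose = i, start = intervals$start[i],
               cmax_total = max(prof$total[sel]),
               cmin_total = prof$total[sel][sum(sel)],
               cmax_free = max(prof$free[sel]),
               cmin_free = prof$free[sel][sum(sel)])
  }))
  structure(c(prof, list(dose_times = dose_times, markers = marks,
                         params = params, sink = sink, regimen = regimen)),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d points over %.0f h, %d doses of %g mg/kg q%gh\n",
              length(x$times), max(x$times), length(x$dose_times),
              x$regimen$dose, x$regimen$interval))
  if (nrow(x$markers)) {
    last <- x$markers[nrow(x$markers), ]
    cat(sprintf("  final interval: Cmax total %.3g M (free %.3g M), Cmin total %.3g M (free %.3g M)\n",
                last$cmax_total, last$cmax_free, last$cmin_total,
                last$cmin_free))
  }
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, which = c("total", "free"), ...) {
  which <- match.arg(which)
  graphics::plot(x$times, x[[which]], type = "l", xlab = "time (h)",
                 ylab = paste(which, "concentration (M)"), ...)
  invisible(x)
}

#' Fraction of the final dosing interval spent at or above a threshold
#'
#' @param profile a `concentration_profile` (simulated to steady state).
#' @param threshold concentration threshold (M).
#' @param which compare `"free"` (default) or `"total"` concentration.
#' @return fraction in [0, 1]; the comparison is closed (at-or-above).
#' @export
fraction_interval_above <- function(profile, threshold,
                                    which = c("free", "total")) {
  which <- match.arg(which)
  t0 <- profile$dose_times[length(profile$dose_times)]
  t1 <- max(profile$times)
  sel <- profile$times >= t0 & profile$times <= t1
  tt <- profile$times[sel]; cc <- profile[[which]][sel]
  above <- cc >= threshold
  if (all(above)) return(1)
  if (!any(above)) return(0)
  ## trapezoid-style crossing interpolation
  frac <- 0
  for (i in seq_len(length(tt) - 1)) {
    dtt <- tt[i + 1] - tt[i]
    if (above[i] && above[i + 1]) frac <- frac + dtt
    else if (xor(above[i], above[i + 1])) {
      w <- (threshold - cc[i]) / (cc[i + 1] - cc[i])
      frac <- frac + if (above[i]) w * dtt else (1 - w) * dtt
    }
  }
  frac / (t1 - t0)
}

#' Non-compartmental analysis of the final dosing interval
#'
#' Linear-up/log-down trapezoidal AUC over the final interval, with Cmax,
#' Tmax (relative to the final dose) and dose-normalized values.
#'
#' @param profile a `concentration_profile`.
#' @param regimen the regimen used (defaults to the profile's own).
#' @param which analyse `"total"` (default) or `"free"` concentration.
#' @return object of class `nca_result`: `Cmax`, `Tmax`, `AUC_tau`
#'   (M*h), `Cmax_dn`, `AUC_dn` (per mg/kg).
#' @export
nca <- function(profile, regimen = profile$regimen,
                which = c("total", "free")) {
  which <- match.arg(which)
  t0 <- profile$dose_times[length(profile$dose_times)]
  sel <- profile$times >= t0
  tt <- profile$times[sel]; cc <- profile[[which]][sel]
  assert_that(length(tt) >= 10, "need >= 10 samples in the final interval")
  auc <- 0
  for (i in seq_len(length(tt) - 1)) {
    dtt <- tt[i + 1] - tt[i]
    c1 <- cc[i]; c2 <- cc[i + 1]
    auc <- auc + if (c2 < c1 && c1 > 0 && c2 > 0)
      dtt * (c1 - c2) / log(c1 / c2)    # log-down
    else dtt * (c1 + c2) / 2            # linear-up (or flat/zero)
  }
  imax <- which.max(cc)
  structure(list(Cmax = cc[imax], Tmax = tt[imax] - t0, AUC_tau = auc,
                 Cmax_dn = cc[imax] / regimen$dose,
                 AUC_dn = auc / regimen$dose, which = which),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA (%s): Cmax %.4g M at Tmax %.2f h; AUC_tau %.4g M*h\n",
              x$which, x$Cmax, x$Tmax, x$AUC_tau))
  invisible(x)
}

#' Intrinsic clearance from a hepatocyte substrate-depletion series
#'
#' OLS slope of ln(peak-area ratio) against time gives the first-order
#' depletion rate; `t_half = ln 2 / |k|`; clearance scales as
#' `CLint_per_Mcells = |k| / cell_density * 1e6` (ml/min per million cells)
#' and `CLint_per_g = CLint_per_Mcells * hepatocellularity / 1e6`.
#'
#' @param series list with `times` (min, >= 3) and `ln_ratio`.
#' @param cell_density incubation cell density (cells/ml), default 0.5e6.
#' @param hepatocellularity liver cell content (cells/g), default 120e6.
#' @return object of class `clint_result`: `slope` (1/min), `t_half` (min),
#'   `CLint_per_Mcells` (ml/min/1e6 cells), `CLint_per_g` (ml/min/g),
#'   `no_depletion` flag.
#' @export
clint_from_depletion <- function(series, cell_density = 0.5e6,
                                 hepatocellularity = 120e6) {
  t <- series$times; y <- series$ln_ratio
  assert_that(length(t) >= 3 && length(t) == length(y),
              "need >= 3 (time, ln_ratio) points")
  assert_that(cell_density > 0 && hepatocellularity > 0,
              "cell_density and hepatocellularity must be > 0")
  k <- unname(coef(lm(y ~ t))[2])
  if (k >= 0) {
    return(structure(list(slope = k, t_half = Inf, CLint_per_Mcells = 0,
                          CLint_per_g = 0, no_depletion = TRUE),
                     class = "clint_result"))
  }
  cl_mc <- -k / cell_density * 1e6
  structure(list(slope = k, t_half = log(2) / -k,
                 CLint_per_Mcells = cl_mc,
                 CLint_per_g = cl_mc * hepatocellularity / 1e6,
                 no_depletion = FALSE),
            class = "clint_result")
}

#' @export
print.clint_result <- function(x, ...) {
  if (x$no_depletion) {
    cat("Intrinsic clearance: no depletion detected (slope >= 0)\n")
  } else {
    cat(sprintf("Intrinsic clearance: t1/2 %.1f min; CLint %.4g ml/min/1e6 cells = %.4g ml/min/g\n",
                x$t_half, x$CLint_per_Mcells, x$CLint_per_g))
  }
  invisible(x)
}

#' Time-dependent-inhibition IC50 fold shift
#'
#' Fits both inhibition curves with [fit_4pl()] and reports
#' `fold_shift = IC50(no pre-incubation) / IC50(pre-incubated)`, so that
#' inhibition intensifying with pre-incubation gives a shift > 1.
#'
#' @param curve_0min,curve_30min dose-response curves without and with
#'   pre-incubation.
#' @return object of class `tdi_result`: `ic50_no_preinc`, `ic50_preinc`
#'   (M), `fold_shift`.
#' @export
tdi_fold_shift <- function(curve_0min, curve_30min) {
  f0 <- fit_4pl(curve_0min)
  f30 <- fit_4pl(curve_30min)
  assert_that(!f0$flat && !f30$flat, "flat curve: cannot compute IC50 shift")
  ic0 <- 10^(-f0$pXC50); ic30 <- 10^(-f30$pXC50)
  structure(list(ic50_no_preinc = ic0, ic50_preinc = ic30,
                 fold_shift = ic0 / ic30, fit_0min = f0, fit_30min = f30),
            class = "tdi_result")
}

#' @export
print.tdi_result <- function(x, ...) {
  cat(sprintf("TDI: IC50 %.3g M (0 min) vs %.3g M (pre-incubated) -> %.3f-fold shift\n",
              x$ic50_no_preinc, x$ic50_preinc, x$fold_shift))
  invisible(x)
}

#' Closed-form single-dose oral (Bateman) concentration
#'
#' Analytic one-compartment solution for a single oral dose with linear
#' elimination, used as an oracle for the simulator in its linear limit.
#'
#' @param t time (h), vectorized.
#' @param dose_molkg absorbed dose (mol/kg).
#' @param ka absorption rate (1/h).
#' @param ke elimination rate (1/h).
#' @param V volume (L/kg).
#' @return concentration (M).
#' @export
bateman_concentration <- function(t, dose_molkg, ka, ke, V) {
  if (abs(ka - ke) < 1e-12 * ka)
    return(dose_molkg / V * ka * t * exp(-ka * t))
  dose_molkg / V * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}
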