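## Receptor--tracer--competitor ternary equilibrium and competition-curve
## affinity fitting, as used in fluorescence-polarization competition assays
## against a labelled high-affinity ligand.

#' Solve the receptor-tracer-competitor ternary binding equilibrium
#'
#' Computes the exact equilibrium species concentrations for a receptor R
#' binding a labelled tracer T (dissociation constant `tracer_Kd`) in
#' competition with an unlabelled competitor C (`competitor_Kd`), with full
#' ligand depletion. The system reduces to a single monotone equation in free
#' receptor, solved by bracketed root-finding on `[0, receptor_total]` and
#' polished by Newton steps; no cubic case analysis is needed and convergence
#' is unconditional. An infinite `competitor_Kd` encodes a non-binder (e.g.
#' polymeric antitrypsin, which does not bind the labelled corrector).
#'
#' @param receptor_total,tracer_total,competitor_total total concentrations (M).
#' @param tracer_Kd,competitor_Kd dissociation constants (M); `Inf` allowed
#'   for the competitor.
#' @return an object of class `equilibrium_state`: list with `free_receptor`,
#'   `free_tracer`, `free_competitor`, `receptor_tracer_complex`,
#'   `receptor_competitor_complex` (all M).
#' @export
solve_competitive_equilibrium <- function(receptor_total, tracer_total,
                                          competitor_total, tracer_Kd,
                                          competitor_Kd) {
  assert_that(receptor_total >= 0 && tracer_total >= 0 &&
                competitor_total >= 0, "totals must be >= 0")
  assert_that(tracer_Kd > 0, "tracer_Kd must be > 0")
  assert_that(competitor_Kd > 0, "competitor_Kd must be > 0 (Inf allowed)")

  Rt <- receptor_total; Tt <- tracer_total; Ct <- competitor_total

  ## Free ligand given free receptor, from ligand conservation.
  free_T <- function(R) Tt / (1 + R / tracer_Kd)
  free_C <- function(R) if (is.finite(competitor_Kd))
    Ct / (1 + R / competitor_Kd) else Ct

  ## Receptor conservation residual; strictly increasing in R.
  g <- function(R) {
    R * (1 + free_T(R) / tracer_Kd +
           (if (is.finite(competitor_Kd)) free_C(R) / competitor_Kd else 0)) -
      Rt
  }

  if (Rt == 0) {
    R <- 0
  } else {
    R <- uniroot(g, c(0, Rt), tol = .Machine$double.eps * max(Rt, 1e-30),
                 maxiter = 1000L)$root
    ## Newton polish to machine precision (g is smooth and increasing).
    for (i in 1:4) {
      h <- max(R * 1e-8, 1e-18)
      dg <- (g(R + h) - g(R - h)) / (2 * h)
      if (!is.finite(dg) || dg <= 0) break
      step <- g(R) / dg
      Rn <- R - step
      if (Rn < 0 || Rn > Rt) break
      R <- Rn
    }
  }

  Tf <- free_T(R)
  Cf <- free_C(R)
  structure(list(
    free_receptor = R,
    free_tracer = Tf,
    free_competitor = Cf,
    receptor_tracer_complex = R * Tf / tracer_Kd,
    receptor_competitor_complex =
      if (is.finite(competitor_Kd)) R * Cf / competitor_Kd else 0,
    totals = c(receptor = Rt, tracer = Tt, competitor = Ct),
    Kds = c(tracer = tracer_Kd, competitor = competitor_Kd)
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Ternary binding equilibrium (M):\n")
  v <- unlist(x[c("free_receptor", "free_tracer", "free_competitor",
                  "receptor_tracer_complex", "receptor_competitor_complex")])
  print(signif(v, 6))
  invisible(x)
}

#' Fluorescence-polarization signal of an equilibrium state
#'
#' Linear two-state signal model: the observed polarization-like signal is
#' the bound-fraction-weighted mix of the free-tracer and bound-tracer levels.
#'
#' @param state an `equilibrium_state`.
#' @param signal_free,signal_bound instrument signal of fully free / fully
#'   bound tracer.
#' @return scalar signal.
#' @export
fp_signal <- function(state, signal_free, signal_bound) {
  Tt <- state$totals[["tracer"]]
  assert_that(Tt > 0, "tracer_total must be > 0 for a signal")
  fb <- state$receptor_tracer_complex / Tt
  signal_free + (signal_bound - signal_free) * fb
}

## Forward model for a full competition curve (noiseless).
competition_signal <- function(competitor_conc, pKD, receptor_total,
                               tracer_total, tracer_Kd, signal_free,
                               signal_bound) {
  Kc <- 10^(-pKD)
  vapply(competitor_conc, function(cc) {
    st <- solve_competitive_equilibrium(receptor_total, tracer_total, cc,
                                        tracer_Kd, Kc)
    fp_signal(st, signal_free, signal_bound)
  }, numeric(1))
}

#' Fit a competition-binding curve to a competitor pKD
#'
#' Nonlinear least squares of the exact ternary-equilibrium
#' fluorescence-polarization model against a competition curve. The
#' competitor affinity is fitted on the log scale (pKD = -log10 Kd); the
#' free- and bound-tracer signal plateaus are fitted by default because
#' instrument units are arbitrary, or may be fixed.
#'
#' @param curve a `competition_curve` (see [gen_competition_curve()]), or a
#'   list with `competitor_concentrations`, `signals` and an `assay` block
#'   holding `receptor_total`, `tracer_total`, `tracer_Kd`.
#' @param fit_plateaus fit the two signal plateaus (default) or fix them at
#'   the assay's declared values.
#' @return object of class `affinity_fit` with elements `pKD`, `ci`
#'   (95\% Wald interval), `converged`, `plateaus`, `fitted`, `residuals`.
#' @export
fit_competition_pKD <- function(curve, fit_plateaus = TRUE) {
  conc <- curve$competitor_concentrations
  y <- curve$signals
  a <- curve$assay
  assert_that(length(conc) >= 6, "need >= 6 competitor concentrations")
  rng <- diff(range(y))
  if (!is.finite(rng) || rng < 0.2 * max(abs(y), .Machine$double.eps))
    stop("no displacement: curve dynamic range below 20%", call. = FALSE)

  model <- function(pKD, sf, sb)
    competition_signal(conc, pKD, a$receptor_total, a$tracer_total,
                       a$tracer_Kd, sf, sb)

  ## Start pKD near the signal mid-transition concentration.
  mid <- (max(y) + min(y)) / 2
  i_mid <- which.min(abs(y - mid))
  start_pKD <- -log10(max(conc[i_mid], 1e-12))
  df <- data.frame(conc = conc, y = y)

  fit <- if (fit_plateaus) {
    sf0 <- min(y); sb0 <- max(y)
    minpack.lm::nlsLM(
      y ~ model(pKD, sf, sb), data = df,
      start = list(pKD = start_pKD, sf = sf0, sb = sb0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  } else {
    minpack.lm::nlsLM(
      y ~ model(pKD, a$signal_free, a$signal_bound), data = df,
      start = list(pKD = start_pKD),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  }

  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["pKD"]], error = function(e) NA_real_)
  structure(list(
    pKD = unname(cf[["pKD"]]),
    ci = unname(cf[["pKD"]]) + c(-1, 1) * 1.96 * se,
    converged = fit$convInfo$isConv %||% TRUE,
    plateaus = if (fit_plateaus) c(signal_free = unname(cf[["sf"]]),
                                   signal_bound = unname(cf[["sb"]]))
               else c(signal_free = a$signal_free,
                      signal_bound = a$signal_bound),
    fitted = fitted(fit),
    residuals = residuals(fit),
    fit = fit
  ), class = "affinity_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.affinity_fit <- function(x, ...) {
  cat("Competition-binding affinity fit\n")
  cat(sprintf("  pKD = %.3f  (95%% CI %.3f - %.3f)\n", x$pKD,
              x$ci[1], x$ci[2]))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.affinity_fit <- function(object, ...) c(pKD = object$pKD)
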