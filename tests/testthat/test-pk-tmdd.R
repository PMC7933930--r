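# saturable-sink free-drug algebra, multiple-dose simulator, NCA,
# intrinsic clearance, TDI shift

test_that("free_from_total: linear limit, sink example, saturation, bisection oracle", {
  s <- sink_params(5e-6, 1.5e-9)
  expect_equal(free_from_total(1e-6, 0.3, sink_params(0, 1e-9)), 0.3e-6)
  # 2 uM total against the 5 uM / 1.5 nM sink at fu 1: ~1 nM free
  cf <- free_from_total(2e-6, 1, s)
  expect_equal(cf, 1.5e-9 * 2 / 3, tolerance = 1e-3)
  # exact root agrees with brute-force bisection to 1e-12
  bisect <- function(Ct, fu, sink) {
    f <- function(x) x / fu + sink$sink_total * x / (sink$sink_Kd + x) - Ct
    lo <- 0; hi <- Ct * fu + 1e-30
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  for (Ct in c(1e-9, 1e-7, 2e-6, 4.9e-6, 5e-6, 2e-5)) {
    expect_equal(free_from_total(Ct, 0.2, s), bisect(Ct, 0.2, s),
                 tolerance = 1e-12)
  }
  # saturation: free fraction tends to fu_ns
  expect_equal(free_from_total(1, 0.2, s) / 1, 0.2, tolerance = 1e-4)
  # strict monotonicity and closed-form inverse round trip
  ct <- 10^seq(-10, -3, length.out = 200)
  cf <- free_from_total(ct, 0.2, s)
  expect_true(all(diff(cf) > 0))
  expect_equal(total_from_free(cf, 0.2, s), ct, tolerance = 1e-12)
  # sink-dominated regime: far below the 5 uM sink the free fraction is
  # much smaller than the nonspecific unbound fraction
  expect_lt(free_from_total(1e-7, 0.2, s) / 1e-7, 0.01 * 0.2)
})

test_that("simulator: zero dose, Bateman limit, mass balance, accumulation", {
  # zero dose: identically zero
  z <- simulate_tid_pk(pk_params(), sink_params(), dose_regimen(0, duration = 1))
  expect_true(all(z$total == 0) && all(z$free == 0))
  # linear regime single dose matches the closed-form Bateman curve
  p <- pk_params(ka = 1.5, V = 2, CLu = 15, fu_ns = 1, F_oral = 1)
  prof <- simulate_tid_pk(p, sink_params(0, 1.5e-9),
                          dose_regimen(10, interval = 24, doses_per_day = 1,
                                       duration = 1))
  an <- bateman_concentration(prof$times, 10 / 1000 / 450, p$ka,
                              p$CLu / p$V, p$V)
  expect_lt(max(abs(prof$total - an)) / max(an), 1e-6)
  # closed system (negligible elimination): gut + body conserved
  pc <- pk_params(ka = 0.5, V = 2, CLu = 1e-9, fu_ns = 1, F_oral = 1)
  closed <- simulate_tid_pk(pc, sink_params(0, 1.5e-9),
                            dose_regimen(30, duration = 2))
  dosed <- length(closed$dose_times) * 30 / 1000 / 450
  expect_equal(max(rowSums(closed$amounts)), dosed, tolerance = 1e-6)
  expect_equal(rowSums(closed$amounts)[length(closed$times)], dosed,
               tolerance = 1e-6)
  # steady-state accumulation in the sink-free linear case
  pl <- pk_params(ka = 5, V = 2, CLu = 0.4, fu_ns = 1, F_oral = 1)
  acc_prof <- simulate_tid_pk(pl, sink_params(0, 1.5e-9),
                              dose_regimen(10, duration = 30))
  ke <- pl$CLu / pl$V
  m <- acc_prof$markers
  ratio <- m$cmin_total[nrow(m) - 1] / m$cmin_total[3]
  pred <- (1 - exp(-ke * 8 * (nrow(m) - 1))) / (1 - exp(-ke * 8 * 3))
  expect_equal(ratio, pred, tolerance = 0.01)
})

test_that("free fraction at Cmax rises with dose under the saturable sink", {
  ff <- vapply(c(10, 30, 100), function(d) {
    pr <- simulate_tid_pk(pk_params(), sink_params(),
                          dose_regimen(d, duration = 4))
    m <- pr$markers[nrow(pr$markers), ]
    m$cmax_free / m$cmax_total
  }, numeric(1))
  expect_true(all(diff(ff) > 0))
})

test_that("fraction of interval above threshold: limits and closed boundary", {
  pr <- simulate_tid_pk(pk_params(), sink_params(),
                        dose_regimen(100, duration = 3))
  expect_equal(fraction_interval_above(pr, 0, "free"), 1)
  expect_equal(fraction_interval_above(pr, 1, "free"), 0)
  # threshold exactly at Cmin: comparison is at-or-above, so the whole
  # interval qualifies
  cmin <- pr$markers$cmin_total[nrow(pr$markers)]
  expect_equal(fraction_interval_above(pr, cmin, "total"), 1)
  # intermediate threshold strictly between
  f <- fraction_interval_above(pr, 3e-7, "free")
  expect_gt(f, 0); expect_lt(f, 1)
})

test_that("NCA: rectangular profile, Bateman AUC, dose linearity", {
  # rectangular profile of height h over the final interval: AUC = h * tau
  rect <- structure(list(times = seq(0, 8, by = 0.1),
                         total = rep(2e-6, 81), free = rep(2e-6, 81),
                         dose_times = 0,
                         regimen = dose_regimen(10)),
                    class = "concentration_profile")
  expect_equal(nca(rect)$AUC_tau, 2e-6 * 8, tolerance = 1e-9)
  # single-dose AUC to infinity approximates dose * F / CL
  p <- pk_params(ka = 1.5, V = 2, CLu = 2, fu_ns = 1, F_oral = 1)
  prof <- simulate_tid_pk(p, sink_params(0, 1e-9),
                          dose_regimen(10, interval = 480, doses_per_day = 1,
                                       duration = 20))
  expect_equal(nca(prof)$AUC_tau, (10 / 1000 / 450) / p$CLu,
               tolerance = 0.005)
  # linear regime: doubling the dose leaves dose-normalized Cmax unchanged
  n1 <- nca(simulate_tid_pk(p, sink_params(0, 1e-9),
                            dose_regimen(10, duration = 3)))
  n2 <- nca(simulate_tid_pk(p, sink_params(0, 1e-9),
                            dose_regimen(20, duration = 3)))
  expect_equal(n2$Cmax / n1$Cmax, 2, tolerance = 1e-4)
  expect_equal(n2$Cmax_dn, n1$Cmax_dn, tolerance = 1e-4)
})

test_that("intrinsic clearance: ln2 identity, no-depletion flag, mouse-value recovery", {
  # slope -0.00693/min gives a 100-min half-life
  ser <- list(times = c(0, 30, 60, 120, 240),
              ln_ratio = -0.00693 * c(0, 30, 60, 120, 240))
  expect_equal(clint_from_depletion(ser)$t_half, 100, tolerance = 1e-3)
  flat <- clint_from_depletion(list(times = c(0, 60, 120),
                                    ln_ratio = c(0, 0, 0)))
  expect_true(flat$no_depletion)
  expect_equal(flat$CLint_per_g, 0)
  # exact round trip at the mouse hepatocyte default
  expect_equal(clint_from_depletion(
    gen_depletion_series(cfg = generator_config(1, 0)))$CLint_per_g,
    4.56, tolerance = 1e-6)
})

test_that("TDI fold shift: identity, exact 10-fold, 1.59-fold noisy recovery", {
  doses <- c(2, 4, 10, 20, 40, 100, 200) * 1e-6
  mk <- function(pIC50, seed, cv = 0)
    gen_dose_response(list(pXC50 = pIC50, hill = 1, bottom = 0, top = 100),
                      doses = doses, cfg = generator_config(seed, cv))
  same <- tdi_fold_shift(mk(4.7, 1), mk(4.7, 2))
  expect_equal(same$fold_shift, 1, tolerance = 1e-6)
  ten <- tdi_fold_shift(mk(4.2, 1), mk(5.2, 2))
  expect_equal(ten$fold_shift, 10, tolerance = 1e-5)
  shifts <- vapply(1:20, function(s)
    tdi_fold_shift(mk(-log10(2e-5), 2 * s, 0.03),
                   mk(-log10(2e-5) + log10(1.59), 2 * s + 1, 0.03))$fold_shift,
    numeric(1))
  expect_equal(mean(shifts), 1.59, tolerance = 0.05 / 1.59)
})
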