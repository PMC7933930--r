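# shared fixture builders (all generated in code, no stored data)

dense_dilutions <- function(n = 61) 10^seq(0, 5, length.out = n)

make_standard <- function(conc, assay, species = "polymer",
                          seed = 1, noise_cv = 0, shared = FALSE,
                          dilutions = dense_dilutions()) {
  mix <- if (species == "polymer") species_mix(polymer = conc)
         else species_mix(monomer = conc)
  list(concentration = conc,
       series = gen_dilution_series(mix, assay, dilutions = dilutions,
                                    cfg = generator_config(seed, noise_cv),
                                    shared_antibodies = shared))
}

make_calibration <- function(assay, species = "polymer",
                             concs = c(0.5, 1, 2, 4) * 1e-6, ...) {
  calibrate_peaks(lapply(concs, make_standard, assay = assay,
                         species = species, ...))
}

## damped fixed-point oracle for the ternary equilibrium: iterate on free
## receptor/tracer/competitor until self-consistent (independent of the
## bracketed-root production solver)
oracle_ternary <- function(Rt, Tt, Ct, KdT, KdC, damp = 0.5, tol = 1e-14,
                           maxit = 50000L) {
  R <- Rt; Tf <- Tt; Cf <- Ct
  for (i in seq_len(maxit)) {
    Rn <- Rt / (1 + Tf / KdT + (if (is.finite(KdC)) Cf / KdC else 0))
    Tn <- Tt / (1 + R / KdT)
    Cn <- if (is.finite(KdC)) Ct / (1 + R / KdC) else Ct
    R2 <- damp * Rn + (1 - damp) * R
    T2 <- damp * Tn + (1 - damp) * Tf
    C2 <- damp * Cn + (1 - damp) * Cf
    if (max(abs(R2 - R) / max(R, 1e-300),
            abs(T2 - Tf) / max(Tf, 1e-300),
            abs(C2 - Cf) / max(Cf, 1e-300)) < tol) {
      R <- R2; Tf <- T2; Cf <- C2
      break
    }
    R <- R2; Tf <- T2; Cf <- C2
  }
  list(free_receptor = R, free_tracer = Tf, free_competitor = Cf,
       receptor_tracer_complex = R * Tf / KdT,
       receptor_competitor_complex = if (is.finite(KdC)) R * Cf / KdC else 0)
}

## two-component (receptor + tracer) closed-form quadratic
quadratic_bound <- function(Rt, Tt, Kd) {
  b <- Rt + Tt + Kd
  (b - sqrt(b^2 - 4 * Rt * Tt)) / 2
}
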