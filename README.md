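# serpinassay

Quantitative analysis of small-molecule corrector campaigns against
polymerogenic serpins, built around the Z variant of alpha-1-antitrypsin:
the Glu342Lys mutant polymerises in the hepatocyte endoplasmic reticulum,
causing both liver inclusions and plasma deficiency, and a corrector that
binds the monomer and blocks polymerisation must be characterised across a
stack of biophysical, cellular and pharmacokinetic assays. `serpinassay`
implements that analysis stack as composable estimators plus seeded
synthetic-data generators with known ground truth.

What it computes:

* **Binding kinetics** — single-exponential fits of association progress
  curves, the pseudo-first-order regression `kobs = kon·[C] + koff` giving
  the second-order association rate constant, derived dissociation rates
  `koff = kon·10^(−pKD)`, half-times with an instrument dead-time flag,
  and affinity selectivity folds `10^(ΔpKD)`.
* **Competition binding** — the exact receptor–tracer–competitor ternary
  equilibrium (cubic system solved by bracketed root-finding, no
  depletion-free shortcut), a fluorescence-polarization signal model, and
  nonlinear fitting of competition curves to the competitor pKD.
* **Sandwich TR-FRET immunoassay** — an equilibrium hook-effect model of
  the antibody sandwich, bell-shaped signal-vs-dilution curves, hook-peak
  calibration (log peak-dilution slope −1), and deconvolution of monomeric
  vs polymeric antitrypsin from paired total/polymer-specific assays.
* **Potency** — 4PL dose-response fits (pIC50/pEC50), normalization to
  vehicle and saturating control, plateau-ratio fold changes.
* **Stability and function** — three-state N ⇌ I ⇌ U chemical denaturation
  with closed-form intermediate peak, thermal-shift midpoints, and
  stoichiometry-of-inhibition titrations with percent activity loss.
* **Pharmacokinetics** — hepatocyte intrinsic clearance from substrate
  depletion, CYP time-dependent-inhibition IC50 shifts, and a one-compartment
  oral TID simulator in which elimination acts on free drug and free drug is
  depressed by a saturable circulating sink (5 µM target at 1.5 nM
  affinity), with NCA and time-above-threshold summaries.

## Worked example

Simulate a competition-binding experiment for the high-affinity target,
recover the affinity, estimate association kinetics, and project multiple-dose
PK against the circulating sink:

```r
library(serpinassay)

## competition curve at 2% noise, truth pKD = 8.5
crv <- gen_competition_curve(truth = list(pKD_competitor = 8.5),
                             cfg = generator_config(seed = 11, noise_cv = 0.02))
fit <- fit_competition_pKD(crv)
fit
#> Competition-binding affinity fit
#>   pKD = 8.442  (95% CI 8.378 - 8.505)
#>   converged: TRUE

## association kinetics at the same noise level
tr  <- gen_association_traces(cfg = generator_config(seed = 11, noise_cv = 0.02))
analyze_association_kinetics(tr, pKD = fit$pKD, exclude_dead_time = FALSE)
#> Association kinetics
#>   kon = 4.042e+04 1/M/s (intercept 0.006757 1/s)
#>   koff = kon * 10^(-pKD=8.44) = 0.0001462 1/s

selectivity_fold(8.5, 6.8)   # Z over M selectivity
#> [1] 50.1

## 100 mg/kg TID against the 5 uM / 1.5 nM sink
prof <- simulate_tid_pk(pk_params(), sink_params(), dose_regimen(100, duration = 6))
prof
#> Concentration profile: 2881 points over 144 h, 18 doses of 100 mg/kg q8h
#>   final interval: Cmax total 3.76e-05 M (free 6.51e-06 M), Cmin total 4.64e-06 M (free 1.56e-08 M)
fraction_interval_above(prof, 3e-7, "free")
#> [1] 0.49
```

Reading the output: the fitted pKD of 8.44 recovers the generative affinity
(Kd ≈ 3.6 nM) within the expected noise; the kobs-vs-concentration slope
recovers the second-order association rate constant near 4.1×10⁴ M⁻¹s⁻¹;
and under the saturable sink the free-drug trough collapses to ~16 nM even
though total trough drug is ~4.6 µM — free drug stays at or above the 300 nM
cellular EC50 for about half of the final dosing interval.

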