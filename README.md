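# agesim

How far can a hand/wrist MRI acquisition be accelerated before skeletal
age estimates derived from the images become unreliable?

Forensic age estimation compares hand/wrist images against skeletal
maturation references, reading the width and closure of the epiphyseal
gaps (growth plates). MRI avoids ionizing radiation but a fully sampled
3-D acquisition takes minutes; parallel-imaging undersampling can cut
this to seconds at the price of reconstruction artifacts. `agesim`
reproduces that trade-off entirely in silico:

1. **Phantom** — a seeded 3-D hand/wrist phantom whose epiphyseal gap
   widths encode a known "true" skeletal age (3 mm at age 10, linear
   closure at 18);
2. **Acquisition** — multi-coil k-space simulation with complex
   Gaussian noise and CAIPIRINHA-style sheared-lattice undersampling of
   the two phase-encode axes, with a fully sampled central calibration
   block; the default acceleration ladder maps a 113 s single-average
   reference to 29, 15, 10, 8, 7 and 6 s scans;
3. **Calibration** — SVD coil compression to virtual channels and
   ESPIRiT-style sensitivity estimation from the calibration block;
4. **Reconstruction** — second-order total generalized variation (TGV²)
   regularized SENSE, solved by a compiled primal-dual iteration with a
   conjugate-gradient warm start, plus a zero-filled baseline;
5. **Age proxy** — automated gap-width measurement (profile FWHM) mapped
   back to age, continuously (`proxy_cont`) and quantized to an
   atlas-style 0.5-year grid capped at 19 y (`proxy_gp`);
6. **Reliability** — SSD/MSD of signed differences against the
   original-image estimate, ICC(A,1)/ICC(C,1), and Bland–Altman
   bias/limits of agreement, per condition and per rater pair. External
   rater tables in the `subject,rater,condition,age` CSV schema can be
   ingested and analyzed identically.

Everything is seeded and deterministic; see `vignette("methods")` for
the model, numerical choices and limitations.

## Worked example

Simulate one 14-year-old subject, undersample to a 15 s scan
(AF 7.49), calibrate, reconstruct, and estimate the age:

```r
library(agesim)
spec <- phantom_spec(true_age = 14, seed = 7)
ph   <- make_hand_phantom(spec)
maps <- make_coil_maps(n_coils = 8, seed = 1)
ks   <- simulate_kspace(ph, maps, noise_sigma = 0.02, seed = 2)

pat <- caipirinha_pattern(dim(ph$values)[2:3], R1 = 4, R2 = 2,
                          caipi_shift = 1, n_calib = 12, AF_nominal = 7.49)
pat
#> sampling_pattern: 64 x 16 pe grid, R = 4 x 2 shift 1, 12 calib, AF nominal 7.49 net 4.03, t_acq 15 s

ku   <- apply_pattern(ks, pat)
comp <- compress_coils(ku, n_virtual = 4, pat)
comp$operator
#> compression_operator: 4 virtual <- 8 physical coils, 0.9986 energy retained

sens <- estimate_sensitivities(extract_calibration(comp$kspace, pat),
                               dim(ph$values))
rec  <- tgv2_reconstruct(comp$kspace, sens, pat)
image_quality(rec, ph)
#> quality_metrics: NRMSE 0.06711, max |diff| 0.3093

gaps_to_age(measure_gap_widths(rec, attr(ph, "sites")), spec$fusion_age)
#> [1] 13.11321
```

The 15 s reconstruction blurs the gaps slightly, so the proxy reads the
14-year-old as 13.1 y — exactly the kind of acceleration-induced bias
the study quantifies.

A miniature study (3 subjects, two ladder rungs; ages restricted to the
pre-fusion range for illustration) runs in about two minutes:

```r
cfg <- study_config(n_subjects = 3L, age_range = c(13, 17),
                    af_ladder = af_ladder()[c(1, 2), ],
                    n_coils = 4L, n_virtual = 2L, seed = 11L)
res <- run_study(cfg)
res$report
#> Reliability report (reference condition: orig)
#>
#> Per rater x condition (vs orig):
#>       rater condition n    ICC ICC_C   SSD   MSD
#>  proxy_cont   sim_29s 3 0.4008 0.869 0.217 -0.66
#>  proxy_cont   sim_15s 3 0.0142 0.719 0.245 -3.26
#>    proxy_gp   sim_29s 3 0.4000 1.000 0.000 -0.50
#>    proxy_gp   sim_15s 3 0.0242 0.750 0.289 -3.17
#>
#> Inter-rater agreement (pooling: all):
#>     rater_a  rater_b n   ICC ICC_C   bias   LOA
#>  proxy_cont proxy_gp 9 0.994 0.994 0.0526 0.319

res$nrmse
#>   subject condition   AF      nrmse
#> 1       1   sim_29s 3.89 0.07436455
#> 2       1   sim_15s 7.49 0.10060398
#> 3       2   sim_29s 3.89 0.06215103
#> 4       2   sim_15s 7.49 0.09337154
#> 5       3   sim_29s 3.89 0.06969003
#> 6       3   sim_15s 7.49 0.09751365
```

With only three subjects the statistics are noisy (the strong negative
MSD at 15 s reflects proxy saturation on blurred gaps); the full
15-subject default, `run_study(study_config())`, takes roughly 15
minutes on one CPU.

## Reproduction

* Full default study: `run_study(study_config(seed = 1L))` — 15
  subjects, the six-rung acceleration ladder, 64 × 64 × 16 phantom,
  8 → 4 coil compression.
* Command line: `inst/scripts/agesim run --out DIR [--seed N]` executes
  the study and writes NIfTI volumes, the age-estimate CSV, the YAML
  configuration and the reliability report;
  `inst/scripts/agesim report --table age_estimates.csv --out STEM`
  recomputes statistics from any age table in the CSV schema.
* Headline quantities as JSON:
  `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
  (timing ladder, net acceleration factors, solver diagnostics,
  sensitivity-map fidelity, proxy-recovery RMSE, and the per-condition
  SSD/MSD/ICC ladder of a full study).
* Tests: `testthat` suite under `tests/testthat` with per-module unit
  and property tests plus end-to-end acceptance checks
  (`test-acceptance.R`).

All randomness flows from explicit seeds; repeated runs are
bit-identical.
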