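# biokinscale

Preclinical-to-clinical radiopharmaceutical dosimetry at the biokinetic
level, for Lu-177-labelled compounds: fit organ and blood time–activity
curves with sums of exponentials, integrate the fits analytically into
time-integrated activity coefficients (TIACs, a.k.a. residence times)
with propagated uncertainties, and extrapolate animal TIACs to humans by
the five published interspecies scaling methods so the predictions can be
compared against measured human values.

Intended users: dosimetry and pharmacokinetics researchers translating
mouse or pig biodistribution data into first-in-human absorbed-dose
estimates.

## The model in brief

Each curve is modelled as $f(t) = \sum_i A_i e^{-\lambda_i t}$ with
amplitudes in %IA (%IA/mL for blood) and *effective* rates bounded below
by the Lu-177 decay constant $\lambda_{phys} = \ln 2 / 6.647\,\mathrm{d}$.
Candidate forms (mono, bi, uptake-washout) are fit by weighted least
squares with curve-peeling starts and multi-start Levenberg–Marquardt,
and selected by AICc. The TIAC is the exact integral
$\sum_i (A_i/100)/\lambda_i$ (hours for organs, h/mL for blood), with a
delta-method standard error $\sqrt{g^\top C g}$ cross-checked by a seeded
Monte-Carlo oracle. Animal TIACs are extrapolated by:

| Method | Rule |
|---|---|
| 1 same biodistribution | $\mathrm{TIAC}_h = \mathrm{TIAC}_a$ |
| 2 relative mass | $\times\,(m_{org}/m_{WB})_h \,/\, (m_{org}/m_{WB})_a$ |
| 3 time scaling | rates $\lambda \to \lambda_{phys} + (\lambda-\lambda_{phys})/c$, $c = (m_{WB,h}/m_{WB,a})^{1/4}$ |
| 4 combined | method 3 then method 2 |
| 5 allometric | $\times\,(m_{WB,h}/m_{WB,a})^{b-1}$, $b$: liver 0.92, kidneys 0.85 |

See `vignettes/biokinetics-scaling.Rmd` for the full account of
assumptions, parameter defaults and limitations.

## Worked example

Allometric extrapolation of a mouse liver TIAC of 0.75 h to a 61 kg
human:

```r
library(biokinscale)
t_liver <- tiac_estimate(0.75, species = "mouse", region = "liver")
method5_allometric(t_liver, 0.026, 61)
#> <scaled_tiac> method 5, mouse/liver: 0.4031 h
```

The 0.75 h mouse value shrinks to 0.40 h — allometry accounts for the
faster murine physiology, though still far below the measured human
5.32 h.

A full synthetic round trip — simulate a pig kidney curve at the pig
imaging schedule with 10% noise, fit, integrate, time-scale to a human:

```r
sc <- default_scenarios()[["pig/kidneys"]]
curve <- generate_curve(sc, noise_model(cv = 0.10, seed = 42))
fit <- select_model(fit_candidates(curve))
fit
#> <fit_result> pig/kidneys form=mono chi2=10.29 AICc=16.69 n=8
#> <exp_model> 1 term(s), lambda_phys = 0.004344988 1/h
#>   A = 7.25398      lambda = 0.00875987   (t1/2 eff = 79.1 h)
integrate_tiac(fit)
#> <tiac_estimate> pig/kidneys: 8.281 +/- 0.32 h
scaled <- method3_time(fit, 28, 61)$scaled
compare_tiacs(list(scaled), reference_tiac_estimates("human"))[
  , c("region", "method", "scaled", "reference", "direction",
      "factor_display")]
#>    region method   scaled reference direction factor_display
#> 1 kidneys      3 9.091435      5.85      over            1.6
```

At this noise level the faint fast phase of the truth is absorbed into a
mono fit (AICc parsimony); the fitted TIAC of 8.28 h carries a 0.32 h
delta-method standard error, and time scaling stretches it to 9.09 h, a
1.6-fold overestimate of the measured human kidney TIAC of 5.85 h.

The whole chain (simulate → fit → TIAC → scale → compare, with logs and
artifact files) runs as one deterministic pipeline:

```r
report <- run_pipeline(run_config("results", seed = 1))
```

or from a shell via the thin CLI: `Rscript inst/cli/biokin.R run
--out-dir results --seed 1`.

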