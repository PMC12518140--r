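# ribpet

Analysis toolkit for preclinical radiotherapy with **radioactive ion
beams** (RIB) monitored by in-beam PET. A C-11 ion beam is therapeutic and
PET-visible at once: the implanted positron emitters image the delivered
particle distribution, so the beam range can be verified online and the
post-irradiation signal carries physiological information. `ribpet`
implements the computational analysis such an experiment needs, end to
end, together with a seeded synthetic cohort generator for validating
every estimator against known ground truth.

## What it computes

**Washout kinetics.** After irradiation the PET activity decays by
physical decay of the emitter mixture (96% ¹¹C, 3% ¹⁰C, 0.5% ¹⁵O) and by
biological washout:

    A(t) = A0 · Σᵢ wᵢ 2^(−t/T½,ᵢ) · [Ws e^(−ks t) + (1−Ws) e^(−kf t)]

`fit_washout()` fits the model by bounded weighted least squares;
`f_test()` decides between single- and double-exponential washout by the
nested F statistic (the bare χ² ratio is reported alongside);
`detect_outliers()` and `compare_groups()` screen fitted rates and
compare dose groups.

**Range verification.** `bev_profile()` reduces 3D dose/activity volumes
to beam's-eye-view depth profiles (±1 mm aperture);
`distal_falloff_depth()` and `peak_depth()` extract the 80% distal dose
fall-off and the activity peak; `range_shift()` compares profiles. The
accompanying analytic beam model (`pristine_bragg()`, `build_sobp()`,
`implanted_activity_profile()`, `simulate_buildup()`) generates matched
synthetic dose/activity inputs, including the A/Z² isotope range scaling
that puts the ¹¹C range at 11/12 ≈ 91.7% of ¹²C at equal velocity.

**Cohort statistics.** Ellipsoid tumour volumes V = (4/3)π·a·b·(a+b)/2
from caliper readings with burden-limit censoring (`ellipsoid_volume()`,
`growth_summary()`); grip-strength toxicity metrics and their link to
spine PET counts (`grip_metrics()`, `mood_median_test()`,
`mann_whitney()`, `pearson_corr()`, `se_median()` with the √(π/2) = 1.2533
factor).

## Worked example

Fit the washout model to one synthetic low-dose animal and test whether
the fast component is needed:

```r
library(ribpet)
spec  <- cohort_spec(seed = 1)
s     <- gen_washout_series(spec, "5")[[1]]
res   <- fit_washout_auto(s, c11_beam_mixture())
res$best
#> <washout_fit> 2-component: A0 = 4.943e+04, Ws = 0.499, ks = 2.926e-04, kf = 5.416e-03 1/s
#>   chi2 = 25.89 on 26 d.o.f. (converged: TRUE)
res$selection$F
#> [1] 3188.972
```

The fitted slow weight `Ws ≈ 0.5` says half the implanted activity leaves
through the fast perfusion component (`kf ≈ 5e-3 /s`, minutes) and the
F statistic overwhelmingly favours the two-component model. The full
pipeline (`analysis/01…05`) runs the same machinery over the whole
cohort; on the default seed the pooled group fits give nested F ≈ 1133 at
5 Gy versus ≈ 3 at 20 Gy (single-exponential chosen) — the dose-dependent
vascular-damage signature — and the range-verification stage reports the
activity peak 0.45 mm proximal of the 80% distal dose fall-off, within
the 0.5 mm alignment expected of a radioactive beam.

```sh
Rscript analysis/01_simulate_cohort.R   # writes results/cohort/
Rscript analysis/02_washout_kinetics.R  # per-animal + pooled fits, group tests
Rscript analysis/03_range_verification.R
Rscript analysis/04_tumour_growth.R
Rscript analysis/05_toxicity.R
```

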