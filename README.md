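# strokevol

Brain volume, intracranial volume (ICV) and brain parenchymal fraction
(BPF = brain volume / ICV) are routine neuroimaging biomarkers of brain
reserve in acute ischemic stroke (AIS). `strokevol` implements, in R, a
clinical-resolution FLAIR volumetrics chain together with the statistical
study that asks: *is raw brain volume or BPF (a surrogate of global brain
atrophy) the better covariate for modeling 90-day functional outcome?*

The package has two halves, each paired with a synthetic-data generator so
that every stage is testable without patient data:

1. **Imaging.** For one subject: two passes of multiplicative bias-field
   correction (a robust log-domain polynomial corrector), mean-shift
   intensity normalization that anchors the normal-appearing white-matter
   (NAWM) mode at 0.75, inclusive thresholding at 0.375 to segment
   parenchyma, and voxel-count volumetry of brain volume and ICV. Brain and
   ICV masks are *inputs* (in practice produced by external deep-learning
   tools); a nested-ellipsoid head **phantom generator** with analytic
   ground-truth volumes provides the exact acceptance surface.
2. **Outcome modeling.** Logistic regressions of poor outcome (modified
   Rankin Scale mRS > 2) at 90 days,

   ```
   mRS>2 ~ age/10 + sex + HTN + DM2 + non-smoker + ln(DWIv) + X
   ```

   with `X` either logit(BPF) or brain volume in dm³, compared by the Bayes
   information criterion, BIC = k·ln(n) − 2·ln(L̂), with Raftery evidence
   categories for ΔBIC. A **cohort simulator** calibrated to the published
   cohort characteristics (n = 476, medians/IQRs, event rate 24.8%)
   generates covariates and model-based outcomes, so the published
   coefficients can be tested by parameter recovery. Assumption checks
   (VIF < 2, Box–Tidwell linearity in the logit, Cook's-distance influence
   screening) and the no-intercept agreement regression used for automated
   vs manual ICV are included.

## Worked example

```r
library(strokevol)

# a clinical-geometry FLAIR phantom (0.9 x 0.9 x 6 mm) with known anatomy
ph  <- generate_phantom(phantom_spec())
res <- run_volumetrics(ph$image, ph$truth$brain_mask, ph$truth$icv_mask)
volumetrics_row(res, "phantom-01")
#>    subject_id brain_volume_cc   icv_cc       bpf logit_bpf  wm_mode converged
#> 1  phantom-01        1309.926 1621.413 0.8078915  1.436463 1.006111      TRUE
```

The recovered brain volume equals the voxel-count truth (1309.9 cc), and
BPF lands on the anatomy's target of 0.81. The pre-normalization WM mode
(1.006) shows the mean-shift seeker locating the white-matter intensity of
1.0 to within the grey-matter pull on the kernel density.

```r
# simulate a cohort under the brain-volume outcome model, refit both models
cohort  <- simulate_cohort(476, covariate_model(), outcome_spec_bv(), seed = 1)
fit_bpf <- fit_outcome_model(cohort, "bpf")
fit_bv  <- fit_outcome_model(cohort, "bv")
compare_models(fit_bpf, fit_bv, labels = c("bpf", "bv"))[c("bic_a", "bic_b", "delta_bic", "preferred", "strength")]
#> $bic_a      [1] 525.2972   # BPF model
#> $bic_b      [1] 505.5224   # brain-volume model
#> $delta_bic  [1] 19.77476
#> $preferred  [1] "bv"
#> $strength   [1] "very strong"
```

Averaged over 200 such replicates (`run_recovery_experiment()`), the fitted
coefficients recover the generating values — e.g. mean β̂ for brain volume
−3.92 (generating −3.83), for age +0.268 per decade (generating +0.25) —
and the generating brain-volume model attains the lower BIC in 100% of
replicates.

The numbered scripts under `analysis/` run these steps end to end
(phantom validation, cohort simulation and calibration table, model fits
with assumption checks, the 200-replicate experiment) and write their
tables under `results/`.

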