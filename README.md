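# growthmorph

Spatially dense geometric morphometrics for isolating a localized orthopedic
treatment effect on a growing bone surface — the mandible under functional
appliance therapy being the motivating case. When a bone both grows and is
treated, the change observed between two scans mixes normal growth with the
treatment effect; without a longitudinal control group the two cannot be
separated by simple comparison. `growthmorph` separates them per vertex of a
densely corresponded surface mesh:

1. **Robust weighted rigid superimposition.** Surfaces sharing a template
   (vertex *i* is the same anatomical point on every shape) are aligned by
   rotation and translation only — never scaling, which would absorb growth —
   minimising `sum_i w_i ||R m_i + t - f_i||^2`, solved in closed form via SVD
   of the weighted cross-covariance (Kabsch) with a determinant-sign
   correction. Weights are re-estimated each iteration as
   `w_i = b_i exp(-r_i^2 / (2 (kappa sigma)^2))` with
   `sigma = max(1.4826 median(r), sigma_min)`, so the alignment is driven by
   the mutually stable regions; teeth carry base weight `b_i = 0` and never
   influence it. A generalized (group-wise) variant alternates pairwise
   alignment onto a consensus with consensus re-estimation.
2. **Normative growth model.** A cross-sectional reference cohort is brought
   into one consensus frame and a Nadaraya–Watson kernel regression over age,
   `v_hat(a) = sum_i K((a - a_i)/h) v_i / sum_i K((a - a_i)/h)` (Gaussian
   kernel, sex-specific), synthesizes the expected surface at any age within
   the cohort's range.
3. **Effect maps.** The treatment effect is the observed per-vertex change of
   a patient minus the model's expected change over the same age interval and
   sex, both measured as signed displacement along the earlier surface's
   outward normals (positive = outward apposition, mm).
4. **Pointwise exceedance tests.** At each vertex, the number of patients
   whose effect exceeds a clinical cutoff (0, 0.5 or 1.5 mm) is tested
   against a symmetric null (`p0 = 0.5`) with a one-tailed exact binomial
   test, `P(X >= k)`, mapped yellow (`p < 0.05`) / green (`p >= 0.05`).

A seeded synthetic study generator (parametric mandible proxy with condyles,
chin, teeth ridge and body regions; normative cohort with a sex-specific
pubertal growth spurt; treated patients with a known injected effect field)
provides ground truth for every stage, so the whole pipeline is validated by
parameter recovery.

## Worked example

```r
library(growthmorph)

cfg   <- sim_config(seed = 3L, n_vertices = 2000L, n_normative = 200L)
study <- simulate_study(cfg)          # 200 normative subjects, 20 patients
res   <- run_study(study, "results_demo")
subset(res$region_summaries, interval == "T1-T2",
       select = c(region, n_vertices, mean, sd))
```

```
         region n_vertices       mean         sd
1  condyle_left        101 1.48451427 0.03800772
2 condyle_right        101 1.48336180 0.04051556
3          chin         62 0.36963212 0.03273689
4          body       1435 0.07133020 0.22367153
5         teeth        301 0.06832502 0.08136451
```

The group carried an injected condylar effect of 1.8 mm scaled by a
per-patient response factor uniform on [0.4, 1.2] (mean 0.8), so the true
group-mean condylar effect is ≈1.44 mm; the pipeline recovers ≈1.48 mm.
The corresponding pointwise tests (`res$test_summaries`) show 99% of
patients exceeding 0.5 mm at the condyles (significant at every condylar
vertex, yellow) but only ~53% exceeding 1.5 mm (significant nowhere,
green), and essentially no exceedance over the purely orthodontic T2–T3
interval. `study_report("results_demo")` renders the same numbers as a
markdown summary, and the written PLY maps colour outward change red, zero
white, inward blue.

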