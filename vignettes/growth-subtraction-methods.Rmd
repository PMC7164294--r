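---
title: "Isolating a treatment effect on a growing bone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating a treatment effect on a growing bone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthmorph)
```

## The problem

A growing bone under orthopedic treatment changes for two confounded
reasons: it grows, and it responds to treatment. With cross-sectional
reference data only — no longitudinal untreated controls — the package
isolates the treatment component per vertex of a densely corresponded
surface: every shape lives on a shared template topology, and vertex `i`
marks the same anatomical location on every shape. All coordinates are in
millimetres; there is no unit autodetection.

The pipeline is: (1) rigidly superimpose each patient's consecutive scans
with robust weighted Procrustes; (2) fit a sex-specific kernel-regression
growth model to a superimposed normative cohort; (3) subtract the model's
expected change over the patient's exact age interval from the observed
change, vertexwise, along surface normals; (4) test, at each vertex, how
many patients exceed a clinical cutoff against a symmetric binomial null.

## Rigid superimposition

Alignment uses rotation and translation only. A similarity (scaled)
Procrustes would absorb part of the growth signal into its scale factor,
and growth in millimetres is exactly the quantity under study, so no
scaling is ever estimated.

The weighted Kabsch solve minimises
$\sum_i w_i \lVert R m_i + t - f_i \rVert^2$ in closed form via the SVD of
the weighted cross-covariance, with the usual determinant-sign correction so
the solution is a proper rotation. Configurations with fewer than three
positively weighted points, or with (near-)collinear support (second
singular value below $10^{-12}$ of the first), are hard errors.

The robust iteration alternates a Kabsch solve with the weight update
$w_i = b_i \exp(-r_i^2 / (2 (\kappa\sigma)^2))$, where $r_i$ is the current
point residual, $b_i$ the base weight (zero at teeth, one elsewhere) and
$\sigma = \max(1.4826\,\mathrm{median}(r_i),\ \sigma_{\min})$ a
median-based robust scale over the positively base-weighted vertices. The
Gaussian-in-residual kernel with a median absolute deviation (MAD) scale is
a standard smooth redescending scheme: it down-weights regions where the two
shapes genuinely differ (growth sites, treatment sites) so that alignment is
driven by the mutually stable surface. The floor $\sigma_{\min}$ (default
$10^{-6}$ mm) prevents weight collapse on near-identical shapes. Convergence
is declared when the weighted RMS residual changes by less than the
tolerance (default $10^{-6}$ mm) — a criterion tied directly to the
minimised objective rather than to parameter movement. Non-convergence
within the iteration cap is reported as a flag, not an error.

Tunable parameters (`robust_config()`):

| parameter | default | meaning |
|---|---|---|
| `max_iterations` | 100 | reweighting iterations per pair |
| `convergence_tol` | 1e-6 mm | change in weighted RMS residual |
| `scale_floor` | 1e-6 mm | minimal robust scale $\sigma_{\min}$ |
| `kappa` | 1.0 | weight-kernel width multiplier |
| `outer_max_iterations` | 20 | consensus rounds of the group-wise variant |

The generalized (group-wise) alignment seeds the consensus with the first
surface — which therefore fixes the orientation gauge — and alternates
pairwise alignment onto the consensus with a consensus update (vertexwise
mean, centroid moved to the origin for identifiability). Because the
consensus is re-centred, only the translation gauge is fully fixed; results
are reported in that consensus frame.

Two numerical choices matter for reproducibility. The cross-covariance is
accumulated with sequential column sums rather than a BLAS matrix product,
so zero-weight vertices contribute exact zeros and the solve is bit-identical
to the same problem with those vertices deleted (this is tested). Transforms
are applied elementwise for the same reason.

## The normative growth model

All normative observations — both sexes pooled — are brought into one
consensus frame; one common frame avoids a cross-sex superimposition bias
when patients of either sex are later compared to the model. Regression is
then sex-specific, as growth timing differs by sex. The expected surface at
age $a$ is the Nadaraya–Watson estimate per coordinate,
$\hat v(a) = \sum_i K((a-a_i)/h)\, v_i \,/\, \sum_i K((a-a_i)/h)$, with a
Gaussian kernel. The kernel weights are a convex combination (nonnegative,
sum to one), so the estimate is always inside the convex hull of the
observed shapes, and as $h \to \infty$ it tends to the sex mean shape.

The bandwidth `h` defaults to 1.0 year and is exposed everywhere. Queries
outside the observed age range are hard errors, not extrapolations: kernel
regression extrapolates poorly, and the reference cohort spans a fixed
range (8.5–19.5 years in the emulated design). A query whose total kernel
mass falls below $10^{-12}$ (an isolated age with a tiny bandwidth) is an
error advising a larger `h`.

The expected *change* over an interval is computed by synthesizing the two
expected surfaces and passing them through exactly the same operators as a
patient's pair of scans — robust superimposition of the later onto the
earlier, then signed displacement along the earlier surface's normals. Using
identical operators on both sides is what makes the later subtraction
meaningful; subtracting frame coordinates directly would mix in gauge
differences.

**Known limitation — bandwidth attenuation.** Kernel smoothing attenuates
curvature in the growth curve: with a pubertal-spurt width of ~1.25 years
and `h = 1` year, the spurt's amplitude is underestimated by roughly 20%
near its peak, which propagates an error of up to ~0.05–0.1 mm into
expected changes over short intervals around the peak. The same bias-variance
trade-off applies to the method on real data: a smaller `h` tracks the spurt
better but needs a denser cohort. Tests therefore validate null-patient
recovery at ages on and off the spurt with a cohort of 200, matching the
recovery tolerances to this known floor rather than to zero.

## Effect maps and subtraction

The effect is `observed - expected` on normal-projected scalars, not on
3-vectors: the reported and tested quantity is change along the surface
normal (positive = outward apposition), and vector subtraction across two
different frames would be ill-posed without a common gauge. Scalars always
project onto the *earlier* surface's normals, making the earlier scan the
common reference of each interval. Teeth vertices carry effect values — the
dento-alveolar change is clinically interesting to visualise — but are
excluded from alignment (base weight zero) and reported as a separate row
in region summaries rather than mixed into skeletal regions.

Expected change is evaluated at each patient's exact ages at the two
timepoints, not at cohort-mean ages, so every patient is compared to the
relevant portion of the growth curve for their age and sex.

## Pointwise exceedance testing

At each vertex the count of patients whose effect exceeds a cutoff
$\delta$ (strictly) is tested with the exact one-tailed binomial
upper-tail probability $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p_0)$,
computed by direct summation of the probability mass function in log space
(and verified in tests against exact rational arithmetic for all
$n \le 25$, and against the distribution-function route for general
$p_0$). The null $p_0 = 0.5$ encodes symmetry: an untreated subject is
equally likely to grow faster or slower than the model predicts. The same
$p_0$ is kept for cutoffs $\delta > 0$, where the true null exceedance
probability is at most 0.5 — so the test is conservative there. With the
$n = 20$ study size this framework makes an 85% exceedance proportion
significant ($P(X \ge 17) \approx 0.0013$) and a 50% proportion not
($P(X \ge 10) \approx 0.59$); the smallest significant count is 15/20.

Classification is strict on both sides: exceedance requires
`effect > delta`, significance requires `p < alpha`; `p = 0.05` is
classified not significant (green). No correction across vertices is
applied by default, matching pointwise mapping practice; a
Benjamini–Hochberg option exists as a clearly labelled extension
(`adjust = "BH"`), off by default.

## The synthetic study generator

Because the motivating study's scans are not public, validation rests on a
seeded generator whose defaults encode the emulated design and whose ground
truth is stored alongside every output:

* **Template** — a deterministic parametric mandible proxy: a tube swept
  along a U-shaped centerline (two vertical rami joined by a semicircular
  corpus, ~30 mm corpus radius, ~6 mm tube radius), with condylar knobs at
  the posterior-superior ends, an anterior chin prominence and a raised
  superior teeth ridge. Regions are labelled by construction; the mesh is
  closed and consistently wound, and any requested vertex count is met
  exactly (a few deterministic edge splits in the inferior corpus absorb
  the grid remainder). This is a geometric proxy, not anatomy: validation
  needs known ground truth, not realism.
* **Growth** — vertices move outward along template normals at a rate that
  is constant per region plus a Gaussian pubertal spurt (peak at 14 years
  for males, 12 for females, width 1.25 years; condylar base rate 0.25
  mm/yr with the strongest spurt gain). Rates are integrated in closed form,
  so growth is exactly additive across subintervals. Regional fields are
  worth a note: every vertex carrying a region label receives the full
  regional rate exactly, and the field decays linearly over three graph
  edges outside the label — so region-interior recovery is exact and
  boundary behaviour is smooth and testable.
* **Cohorts** — normative ages uniform on 8.5–19.5 years with 268 male /
  386 female when generated at the emulated scale (the printed sex counts,
  which sum to 654); each observation adds isotropic Gaussian noise
  (sd 0.1 mm), a random rigid pose (up to 10 degrees / 5 mm) and an
  arbitrary dental displacement inside the teeth region (up to ~1 mm) —
  the three nuisances the pipeline must be invariant to.
* **Patients** — 20 (6 male / 14 female), T1 age ~ N(12.76, 0.89) years,
  intervals 0.8 years (appliance phase) and 1.85 years (fixed orthodontic
  phase). Treatment injects an outward field of 1.8 mm at the condyles and
  0.5 mm at the chin over T1–T2 that persists unchanged to T3. Each
  responder draws a magnitude multiplier uniform on [0.4, 1.2], so
  essentially all patients exceed a 0.5 mm condylar cutoff while only
  about half exceed 1.5 mm — the heterogeneous-response pattern the test
  stage is designed to resolve; `responder_fraction` below 1 makes the
  remainder exact nulls.

What the generator does **not** emulate: correspondence error (meshes are
born corresponded; establishing dense correspondence is upstream of this
package), segmentation artefacts, spatially correlated noise, and
anatomically realistic shape variation between subjects (all subjects share
the template geometry; between-subject variation enters only through age,
sex, noise and response magnitude). Passing tests therefore demonstrate
correctness of the estimators under the stated noise model, not performance
under correspondence failure or population shape variance.

## Problem sizes used in tests

Module tests run at 800 template vertices with cohorts of up to 200;
the end-to-end validation runs the full design (20 patients, 200 normative
subjects) at 2000 vertices; type-I control uses 200 replicate null studies
of 20 patients at 500 vertices with the growth model fitted once and
per-patient expected changes cached (the cohort design is fixed across
replicates; only noise, poses and dental movement are redrawn). The
17,415-vertex template scale is exercised for construction and topology.
These sizes were chosen so the whole suite runs on a desktop in a few
minutes while keeping every tolerance meaningful at the noise levels above.

## Design choices where the design was genuinely open

* The exact reweighting rule of robust Procrustes is implementation-defined
  here (Gaussian kernel, MAD scale, `kappa` exposed); published descriptions
  of the approach do not pin the constants, so they live in
  `robust_config()` and are recorded in every run manifest.
* Whether regression should happen in a pooled or per-sex frame is not
  forced by the method; the pooled frame was chosen so that patient-to-model
  comparisons never cross a frame boundary.
* The subtraction operates on scalars along normals rather than on vectors;
  see above.
* Degenerate inputs: zero-length intervals yield exactly zero fields;
  surfaces with isolated vertices are rejected when normals are requested
  (with the offending indices listed); mixed templates are correspondence
  errors everywhere.
* Interfaces: `simulate_study()` / `write_study()` / `run_study()` /
  `study_report()` are the pipeline surface; a thin command-line wrapper
  over exactly these functions ships in `inst/cli/growthmorph.R` with
  subcommands `simulate`, `run`, `report`.
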