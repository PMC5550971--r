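---
title: "Biomechanical biomarkers of the post-infarction left ventricle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical biomarkers of the post-infarction left ventricle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`lvbiomech` implements a desk-scale pipeline for studying biomechanical
biomarkers of left-ventricular (LV) contractile function after acute
ST-elevation myocardial infarction (STEMI). The pipeline has five parts:

1. a **constitutive model** of passive and active myocardium with an
   infarct-extent field;
2. a **reduced-order LV model** (truncated prolate ellipsoid, rule-based
   fibers) that produces cavity volumes, 24 segmental circumferential
   strains and systolic biomarker fields;
3. **inverse estimation** of passive stiffness and of the patient-specific
   contractility `T_req` from volume + strain "measurements";
4. a **synthetic cohort generator** calibrated to published group
   statistics (27 healthy controls, 11 STEMI patients), standing in for
   clinical CMR data that are not publicly available;
5. a **classification and association study**: eight classifiers under
   nested leave-one-out cross-validation (LOOCV), ROC convex-hull AUROC,
   factor-importance rank fusion, and baseline-vs-six-month-outcome
   correlations.

This vignette records the models, their assumptions, the numerical
choices, and the design decisions taken where the problem was genuinely
open.

# Passive myocardium

The passive response uses the invariant-based Holzapfel–Ogden
strain-energy function with eight coefficients
$(a, b, a_f, b_f, a_s, b_s, a_{fs}, b_{fs})$:

$$
\Psi = \frac{a}{2b}\left(e^{b(\bar I_1 - 3)} - 1\right)
 + \sum_{i \in \{f,s\}} \frac{a_i}{2 b_i}
   \left(e^{b_i (I_{4i}-1)^2} - 1\right)\,[I_{4i} > 1]
 + \frac{a_{fs}}{2 b_{fs}} \left(e^{b_{fs} I_{8fs}^2} - 1\right)
$$

with $I_{4f} = \mathbf f_0 \cdot \mathbf C \mathbf f_0$,
$I_{4s} = \mathbf s_0 \cdot \mathbf C \mathbf s_0$ and
$I_{8fs} = \mathbf f_0 \cdot \mathbf C \mathbf s_0$. Two numerical
choices matter:

* **Tension-only anisotropy.** Myofibers and sheets bear load only when
  taut: the $a_f$ and $a_s$ terms engage only for $I_4 > 1$. The switch
  is $C^1$ at $I_4 = 1$ because of the $(I_4 - 1)$ factor in the stress.
* **Isochoric isotropic invariant.** The isotropic term uses
  $\bar I_1 = J^{-2/3} I_1$, which keeps the reference configuration
  stress-free in the penalty (nearly incompressible) setting. A
  volumetric penalty $\beta_s \log(J)^2$ with
  $\beta_s = 10^5\,$Pa backs up free-standing evaluations of the law;
  inside the solver the kinematic ansatz is exactly isochoric and the
  penalty vanishes identically.

Cohort-average coefficients are shipped as YAML
(`inst/extdata/healthy.yaml`, `inst/extdata/mi_remote.yaml`).

**Infarct stiffening.** A scalar field $M \in [0,1]$ (1 in the scar, 0 in
remote myocardium, linear over a 10 mm transition band) multiplies the
*entire* eight-coefficient elastic energy by $(1 + 49M)$: fully
infarcted scar is exactly 50-fold stiffer, linearly in between. Scaling
the whole energy (rather than the $a$-type coefficients only) makes the
50-fold property exact for every deformation; the incompressibility
penalty, being a numerical constraint, is not scar-scaled.

# Active contraction

Active tension is $T_a = T_{req} \, C(\lambda_f, z)\,(1 - M)$, where
$T_{req}$ is the contractility — the active tension generated at unit
fiber stretch under peak activation — and $C$ collects myofilament
kinetics:

* $z$, the available actin binding-site fraction, follows first-order
  binding kinetics driven by a prescribed analytic calcium transient
  $\mathrm{Ca}(t) = \mathrm{ca\_amp}\,(t/\tau)\,e^{1 - t/\tau}$
  (homogeneous in space: contraction is triggered simultaneously
  everywhere), with Hill-saturated binding, linear and nonlinear
  relaxation, and length-dependent calcium sensitivity;
* three fading-memory variables $Q_i$ integrate the fiber stretch rate
  ($\dot Q_i = A_i \dot\lambda_f - \alpha_i Q_i$) and feed a
  force–velocity factor $(1 + aQ)/(1 - Q)$ for shortening;
* a length-dependence factor $1 + \beta_0 (\lambda_f - 1)$.

All rate constants live in `inst/extdata/active_default.yaml`; they are
model *inputs*, chosen once from the cardiac-mechanics literature on
myofilament kinetics (fading-memory force–velocity constants, binding
and relaxation rates of order $10^{-2}$–$10^{-3}\,$ms$^{-1}$, calcium
time-to-peak 60 ms, end-systole evaluated 300 ms after activation
onset). $C$ is normalized so that $C = 1$ at $\lambda_f = 1$, peak
activation and zero stretch-rate history; the normalization constant
(the peak $z$ reached at unit stretch under the default transient) is
computed once per configuration. This makes $T_{req}$ literally "the
active tension generated when $\lambda_f = 1$". The value of $C$ at the
configured end-systolic time is the biomarker $C^s$ ("apparent" systolic
crossbridge availability). The kinetics ODEs are integrated with a
fixed-step fourth-order Runge–Kutta scheme (default 1 ms, stability
bound 5 ms declared in the configuration; a self-convergence test
guards the step choice).

# Reduced-order LV model

The full-field fluid–structure model used in image-based studies is out
of scope; the package replaces it with an explicit reduced-order
stand-in that preserves every constitutive equation and all estimation
logic. This is a deliberate, documented substitution — all downstream
quantities are defined against this solver.

**Geometry.** A truncated prolate ellipsoid (endocardial semi-axes
22 × 56 mm, 10 mm wall, base plane at 0.35 of the long semi-axis)
giving a reference cavity of ~85 ml and wall volume ~127 ml. The wall is
sampled on a transmural × longitudinal × circumferential grid (default
4 × 12 × 12 = 576 points). The basal half is divided into 4 short-axis
slices × 6 sectors = 24 strain regions.

**Fibers.** Rule-based: the helix angle runs linearly from −60° at the
endocardium to +60° at the epicardium, the sheet angle from −45° to
+45°; unit fiber/sheet vectors are built in the local
circumferential/meridian/transmural frame and are orthogonal by
construction.

**Kinematics.** Deformations live in a low-dimensional, *exactly
isochoric* ansatz: an endocardial inflation field
$g(\xi, \theta) = g_b + (g_a - g_b)\xi + g_{mi} M(\xi,\theta)$ (base and
apex inflation plus an infarct-footprint bulge), a global axial stretch
$\lambda_z$, and piecewise-linear twist about the long axis (one knot
per slice). The radius of every wall point follows from pointwise
volume conservation,
$r^2 = g^2 R_{in}^2 + (R^2 - R_{in}^2)/\lambda_z$, which gives
$\det \mathbf F = 1$ identically for *all* parameter values — the
$|J - 1| \le 10^{-3}$ requirement is met by construction, not by
penalty.

**Equilibrium.** States minimize total potential energy: strain energy,
plus an active fiber potential whose Cauchy fiber stress is exactly
$T_a$, minus cavity-pressure work $pV$. The active tension–length
dependence is folded into the potential
($\lambda \,\partial W_{act}/\partial\lambda = K(1+\beta_0(\lambda-1))$,
clamped to zero below the stretch where the length factor vanishes), so
the inner minimization sees the full Frank–Starling feedback; only the
weak dependence of $z$ and $Q$ on the stretch *history* is left to an
outer damped fixed-point loop (damping 0.75 with back-off, tolerance
$10^{-6}$, at most 50 iterations — the undamped map has an oscillatory
dominant eigenvalue). Minimization is Nelder–Mead descent (robust
through the exponentially stiff far field) followed by a bounded
quasi-Newton polish; warm starts shorten the descent inside iterative
loops. The solver is fully deterministic.

**Outputs.** End-diastolic state (volume, 24 diastolic strains;
reference = unloaded), end-systolic state (ESV, 24 systolic strains;
reference = end-diastole, as segmental circumferential stretch of the
mid-wall arc minus one), per-point $\lambda_f$, $T_a$, $\sigma_f$
(passive fiber projection + active tension) and $C$, and the twist
profile. Biomarkers are quadrature-weighted wall means over functional
myocardium ($M < 0.5$): $T_a$, $\sigma_f$, their SBP-normalized ratios
(kPa/mmHg) and $C^s$. Wall means were chosen because the reporting
convention behind the published group values is not stated; medians and
peaks were the alternatives.

With cohort-average healthy inputs (EDP 8 mmHg, SBP 144.6 mmHg,
$T_{req} = 157$ kPa) the model produces an ejection fraction near 0.57,
systolic circumferential strains near −0.2, normalized active tension
near 0.41 kPa/mmHg and $C^s \approx 0.37$ — in the physiological range
of the published cohort without any fitting, which is the realism check
we apply to the default constants. The known gap: the reported fiber
stress $\sigma_f$ omits the incompressibility reaction pressure (the
reduced model has no Lagrange-multiplier pressure field), so
$\sigma_f^{norm}$ runs closer to $T_a^{norm}$ than in a full-field
model.

**Infarct.** A contiguous transmural elliptical patch in
circumferential/longitudinal arc-length coordinates, with the 10 mm
linear transition band. Its extent is calibrated by bisection so the
$M = 1$ core occupies a requested wall-volume fraction (default 39%).
The default placement is apical (patch center at 0.75 of the
base-to-apex coordinate, longitudinal-to-circumferential aspect 2) —
typical of a large LAD-territory STEMI — which leaves 12 of the 24
basal-half strain segments remote, consistent with the reported
13 ± 3 remote segments. Segments are classed remote / transition /
infarct by mean $M$ (thresholds 0.05 and 0.5).

# Inverse problems

The mismatch objective is a weighted sum of squares over the 24
segmental strains and the cavity volume; the weights normalize a
typical strain mismatch (0.05) and volume mismatch (10 ml) to order
one. The relative weighting is an explicit design choice (the source
convention is unstated); both constants are exposed as arguments. In MI
mode the strain terms are restricted to remote segments, because the
infarct is modelled with fixed properties (50-fold stiffening, zero
contractility) and is not estimated.

* **Passive fit** (diastole): a three-step scheme over two
  interpretable scale factors on an initial parameter set — global
  stiffness scale against EDV, then a myofiber-direction scale on
  $(a_f, b_f)$ against diastolic strains, then a joint Nelder–Mead
  polish. The eight coefficients are not individually identifiable from
  volume + strain (a known property of this estimation problem); the
  recovery target is therefore the *fiber-direction stiffness* (fiber
  stress at 10% fiber stretch), which is recovered to well under 5% in
  the self-consistency tests.
* **Contractility fit** (systole): a bounded one-dimensional
  golden-section/parabolic minimization of the objective over
  $T_{req} \in [0, 400]$ kPa, absolute tolerance 0.1 kPa, matching ESV
  and systolic strains (remote-only for MI). Noise-free
  self-consistency recovers the generating contractility to well within
  1 kPa; the objective trace is returned so the
  objective-vs-contractility curve can be inspected.

Both fits are deterministic and seed-free. Each phase uses the
measurement set of that phase: diastolic strains + EDV for the passive
fit, systolic strains + ESV for the contractility fit.

# Synthetic cohort generator

No public individual-level data exist for the study cohort, so the
generator *is* the data source, in two modes.

**Calibrated mode** draws per-group feature vectors from truncated
multivariate normals whose marginal means/SDs are the published group
statistics: SBP 144.6 ± 31.2 (healthy) / 118.6 ± 16.4 (MI) mmHg, EDV
127 ± 21 / 145.5 ± 28 ml, ESV 55 ± 14 / 83 ± 21 ml, $T_{req}$
157 ± 25 / 156 ± 27 kPa, $T_a^{norm}$ 0.45 ± 0.06 / 0.55 ± 0.07
kPa/mmHg, $\sigma_f^{norm}$ 0.35 ± 0.05 / 0.47 ± 0.09 kPa/mmHg, $C^s$
0.42 ± 0.04 / 0.44 ± 0.13, GLS −21.4 ± 4.1 / −11.5 ± 3.9 %, segmental
circumferential strain −0.18 ± 0.02 / −0.16 ± 0.01 (treated as a
strain fraction, not a percent). Ejection fraction and $\sigma_f$ are
derived, not drawn ($EF = (EDV - ESV)/EDV$ lands on the published
43% / 57% automatically). $T_a$ group means are taken as
$T_a^{norm} \times SBP$ (65.07 / 65.23 kPa) because raw means are not
printed; their SDs (13 / 15 kPa, ≈20% CV) are an assumption.

The inter-feature correlation matrix is a documented modelling
assumption (the source's correlation analysis is not public): a weak
0.1 background plus structured entries — contractility drives tension
(0.4), tension correlates with its SBP-ratio (0.7), the two ratios
inter-correlate and anti-correlate with SBP (−0.4), volumes co-vary
(0.6), and $corr(T_{req}, C^s) = -0.3$ within group. The last value is
forced by feasibility: the six-month outcome correlations (−0.79 with
$T_{req}$, +0.70 with $C^s$) are jointly attainable only if
$corr(T_{req}, C^s) \le -0.115$. The default matrix is verified
positive definite; user edits that break positive semidefiniteness are
repaired by nearest-PSD projection with a warning. Sampling is
rejection-truncated at ±4 SD and physical bounds, with
$EDV - ESV \ge 10$ ml enforced jointly.

**Pipeline mode** builds each subject through the forward model at its
ground truth (group parameters, drawn $T_{req}$ and SBP, EDP fixed at
8 mmHg healthy / 16 mmHg MI, MI infarct size drawn around 39 ± 6%),
reads EDV/ESV/strains back as "measurements" (optional Gaussian
observation noise; zero noise reproduces the model output exactly), and
re-estimates contractility through the inverse problem. MI
remote-segment counts are drawn from N(13, 3) clipped to [6, 24] in the
cohort table; the forward model's own geometry yields 12.

**Outcomes.** Six-month LVEF change is a linear combination of
standardized $T_{req}$ (negative loading) and $C^s$ (positive loading)
plus Gaussian noise, with loadings solved in closed form so the
*population* correlations equal −0.79 and +0.70 exactly
(standardization uses the configured population moments, not sample
moments); six-month GLS is correlated 0.73 with baseline GLS the same
way. Outcome means (ΔLVEF +4 ± 8 percentage points, GLS6 −14 ± 4%) are
realism choices for a reperfused STEMI cohort. Infeasible correlation
triples are rejected with the offending entries named.

What the generator deliberately does **not** emulate: imaging and
registration noise spectra, non-Gaussian tails, regional calcium
heterogeneity, partial contractility in the border zone. Tests passing
on this generator therefore validate the *machinery* (estimation,
evaluation, ranking) under the published group statistics — they are
not evidence about real CMR data.

# Classification study

Eight methods: univariate logistic regression (the predictor choice is
treated as its tuned parameter; each single feature also contributes
its own operating point to the ROC ensemble), multivariate logistic
regression, k-nearest neighbours (k ∈ {1, 3, 5, 7}; low k is expected
to win on narrow decision boundaries), linear discriminant analysis,
L1-regularized logistic regression (20-point log-spaced penalty grid;
ties resolve to the sparser model), boosted entropy-split decision
trees, random forest, and a Gaussian-process classifier with automatic
relevance determination (GP-ARD).

* **Nested LOOCV.** The outer loop provides out-of-sample predictions;
  for grid-tuned methods an inner LOOCV on each outer training set
  selects the hyperparameter, so held-out data never influence tuning
  (a mutation test asserts that a subject's prediction is invariant to
  its own label). The Bayesian GP-ARD instead maximizes the Laplace
  marginal likelihood on the outer training set. Feature
  standardization uses training-fold statistics only; trees and
  forests see raw features. The decision threshold is 0.5 on the
  predicted MI probability. MI hearts are the positive class.
* **Boosted entropy trees** stand in for the proprietary-adjacent C5.0
  algorithm: AdaBoost.M1 over `rpart` trees with information-gain
  splitting (depth ≤ 3, 10 rounds), importance = fraction of rounds in
  which a feature appears in any split.
* **GP-ARD** is implemented in-package: squared-exponential kernel with
  one length scale per feature, logistic likelihood, Laplace
  approximation (GPML-style Newton mode finding), hyperparameters by
  Nelder–Mead on the marginal likelihood with warm starts across outer
  folds; importance = inverted, normalized length scales.
* **Random forest** uses 200 trees, default square-root feature
  subsampling, seeded per fold; importance = permutation mean decrease
  in accuracy. Lasso importance = |mean standardized coefficient|
  across outer folds.
* **ROC convex hull.** The upper convex hull of all
  (1 − specificity, sensitivity) points, anchored at (0,0) and (1,1);
  AUROC by trapezoidal integration over the hull vertices. With no
  informative points this degenerates to the chance diagonal
  (AUROC 0.5).
* **Rank fusion.** Per method, features are ranked 0…p−1 ascending by
  importance (stable ties) and ranks are summed across the four
  methods that define importance. On default calibrated cohorts the
  two ratio features $C^s$ and $T_a^{norm}$ attain the top mean
  accumulated ranks.

A small bias worth knowing: cross-validated predictions under a label
permutation null have a pessimistic $O(1/n)$ bias, so the
permutation-null AUROC sits slightly below 0.5 at moderate n (≈0.49 at
n = 1000) and approaches 0.5 from below as n grows.

# Association analysis

Pearson correlations with Fisher-z 95% confidence intervals and
two-sided p-values (the z-based test is the package's choice; the
t-based test is the common alternative), significance at 0.05, no
multiple-testing adjustment (by design, recorded in the table
attribute). Group comparisons use the pooled-variance Student's t-test
by default with the Welch variant behind a flag (the source convention
names Student's t-test without specifying the variance treatment).

# Problem sizes and determinism

All stochastic components run from explicit integer seeds; equal
configuration + seed reproduces outputs byte-identically. Default
problem sizes, chosen to keep the full study at desk scale: solver grid
576 points (the test suite uses a 216-point coarse grid, the smallest
that populates all 24 strain regions; volumes agree with a
doubled-resolution solve to <1%); calibrated-generator calibration
checks at n = 10⁴–10⁵; permutation null with 200 permutations at
n = 1000; ensemble hull AUROC averaged over 50 replicate cohorts of
27 + 11 (Monte-Carlo standard error ≈ 0.007); the test suite uses
smaller replicate counts of the same experiments.

# Known limitations

* The equilibrium solver is a reduced-order stand-in: no blood flow,
  valves, atria or inertial dynamics; two time points only
  (end-diastole, end-systole); axisymmetric-plus-bulge kinematics
  cannot represent localized wall-motion abnormalities beyond the
  infarct footprint DOF.
* $\sigma_f$ omits the incompressibility reaction pressure (above).
* The eight passive coefficients are reported as fitted scales of a
  cohort-average set, not as individually identified constants.
* The generator's correlation structure beyond the documented entries
  is an assumption; conclusions that depend on it (notably the exact
  ensemble AUROC level) should be read conditionally on it.
* $C^s$ reflects an "apparent" myofilament kinetics under one shared
  calcium transient; regional calcium biology is not modelled.
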