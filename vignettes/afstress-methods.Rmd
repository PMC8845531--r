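---
title: "Stress-testing virtual left atria: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing virtual left atria: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`afstress` implements a desk-scale virtual-cohort pipeline for studying how
acute simulated response to pulmonary vein isolation (PVI), combined with
imaging and patient-history covariates, predicts one-year atrial
fibrillation (AF) recurrence.  Each virtual patient is a triangulated
left-atrial (LA) surface with a fibrosis field; eleven model-variant
"stress tests" probe the uncertain components of the substrate (fibrosis
type, fiber map, lesion size, initiation protocol, refractory period); the
resulting simulation metrics join imaging areas and history covariates in a
patient signature; and cross-validated classifiers compare three nested
feature sets (history; imaging + history; simulation + imaging + history).
This vignette explains the models, the tunable parameters, and the design
decisions that were genuinely open.

## The electrophysiological model

Tissue is a monodomain reaction–diffusion system on a triangulated surface:

$$\partial_t v \;=\; \nabla\!\cdot\!\big(\mathbf D\,\nabla v\big) \;+\;
  I_{\mathrm{ion}}(v, h) \;+\; I_{\mathrm{stim}},$$

with anisotropic diffusion
$\mathbf D = d_t\,(\mathbf I - \mathbf n\mathbf n^{\!\top}) +
 (d_\ell - d_t)\,\mathbf f\mathbf f^{\!\top}$ along the per-triangle fiber
direction $\mathbf f$.  Space is discretised with linear (P1) finite
elements and a lumped mass matrix; time by explicit operator splitting.
The step size honours both the reaction scale and the Gershgorin stability
bound of the explicit diffusion operator and is reduced automatically.

The cell model is a two-variable phenomenological atrial model (a modified
Mitchell–Schaeffer form) on a normalized potential $v\in[0,1]$ with one
recovery gate $h$; transmembrane potential is reported as
$V_m = V_{\mathrm{rest}} + A\,v$ with $V_{\mathrm{rest}} = -81$ mV,
$A = 110$ mV.  Detailed human atrial ionic models are far more expensive
and are not required for the phenomenology this pipeline extracts (rotors,
dominant frequency, refractoriness); the cell model sits behind a small
parameter object (`cell_model_params()`) so a detailed model can replace
it.  Default constants (`tau_in` 0.3, `tau_out` 6, `tau_open` 120,
`tau_close` 100 ms, gate threshold 0.13) give an action potential duration
near 160 ms and reentrant rates around 5 Hz, in the range reported for
remodeled human atria.  Two per-vertex scalings — `apd_scale` (multiplies
`tau_close`) and `excitability_scale` (multiplies the inward-current rate)
— implement ionic remodeling and the effective-refractory-period (ERP)
battery variants.

**Conduction-velocity calibration.**  Diffusion coefficients are never set
directly: `calibrate_cv()` bisects the longitudinal coefficient until a
planar wave on a flat calibration sheet *at the same mesh resolution and
time step* reaches the target velocity (default 0.5 mm/ms, velocity
anisotropy ratio 2).  Calibrating at the operating discretisation absorbs
the coarse-mesh and explicit-Euler biases, which is why the package can run
2 mm meshes and a 0.1 ms step at desk scale: the achieved CV stays within
5% of target even though the raw scheme is first-order in both.  The
convergence properties (halving dt changes CV by < 1% in the converged
regime; CV $\propto\sqrt{d_\ell}$ within 5% over a 4× range) are enforced
by tests.

**Structural fibrosis.**  Interstitial fibrosis is modelled as zero-flux
edges: the stiffness coupling of a decoupled vertex pair is removed with
diagonal compensation, so current simply cannot cross that edge.  Each
interior edge whose mean endpoint image-intensity ratio (IIR) exceeds 1.22
is decoupled independently with probability rising linearly from 0 at IIR
1.22 to 0.5 at IIR 1.6.  A post-check re-couples a spanning subset if the
selection would fragment the tissue.  One caveat found during testing: at
decoupling densities near 1 the patch disconnects, the repair re-routes
rather than thins the couplings, and the "delay grows with density"
property saturates (with ~1% non-monotone wiggle); the property is therefore
asserted in the sub-saturation regime.

**Conductivity and ionic remodeling.**  Enhanced tissue also conducts more
slowly and repolarises earlier: the default rule maps IIR to a
conductivity scaling of 1 at or below 1.22 (threshold inclusive on the
healthy side — a deliberate choice, the threshold itself defines
"fibrotic" strictly above), falling linearly to a floor of 0.3 at IIR 1.6;
`apd_scale` drops to 0.85 at fibrotic vertices.  The four fibrosis-type
battery variants compose these ingredients: *combination* (decoupling +
conductivity + ionic), *conduction_only* (conductivity + ionic),
*interstitial* (decoupling only), *none*.  The composition of the second
variant is not fixed by the protocol description we follow; defining it as
the complement of interstitial within the combination is the natural
reading and is recorded as a design decision.

## AF initiation and ablation

AF is initiated by the phase-distribution method: each vertex receives the
chirality-weighted sum of `atan2` angles about every seed (computed in the
seed's tangent frame), and the wrapped phase indexes a limit cycle recorded
from a paced single cell (cycle length 1000/6 ms, a 6 Hz target rate).  The
constructed state contains one phase singularity per seed at $t=0$; tests
verify count, location (within 2 mm) and charge on a flat sheet, including
charge inversion under mirrored chirality.  Map `map_A` places four seeds
at fixed anatomical-landmark analogues (posterior wall ×2, anterior wall,
appendage base); `map_B`/`map_C` rotate the placements ±35° about the long
axis.  Seed counts and placements are design choices — the protocol we
mirror states only that the initiation maps differ.

PVI is a wide-area circumferential band: all triangles whose centroid
geodesic distance (Dijkstra on the edge graph; bias below one edge length
at the operating resolutions) to the nearest PV junction loop lies in
$[d, d+w]$, with $d = 5$ mm baseline and $d = 10$ mm for the size variant,
band width $w = \max(5, 2.5h)$ mm.  The lesion constructor *proves*
isolation: it fails unless every PV antrum is graph-disconnected from the
body after removal.  A test-only API injects a gap; note that restoring a
single triangle cannot bridge a band two or more elements thick (its
vertices still couple only within one band row), so the gap is centred on
one triangle with a radius defaulting to the band width, guaranteeing a
transmural conducting channel.

## Metrics

*Phase* is the angle of the per-vertex Hilbert-transform analytic signal of
mean-subtracted $V_m$ — chosen over activation-time phase for being
parameter-free; the method tag is recorded.  *Phase singularities* are
vertices whose one-ring winding number (pairwise differences wrapped to
$(-\pi,\pi]$, traversed counterclockwise about the outward normal) is ±1.
Because a singular point interior to a triangle lies inside the one-ring
polygons of all three of its vertices, raw winding flags a small adjacent
cluster per rotor; detections are deduplicated by merging edge-connected
clusters of equal charge (the raw mode is kept and tested against a
brute-force oracle).  PS statistics over the analysis window (the final
10 s of a 15 s pre-ablation epoch in the `paper` profile; final 3 s of 4 s
in `desk`) are: time-averaged count, total area of triangles visited by
any PS, and that area restricted to PV antra.

*Dominant frequency* (DF) uses per-vertex Welch spectra (~1 s Hann
segments, 50% overlap, zero-padded to ≤ 0.25 Hz bins) in the 1–20 Hz band;
each vertex reports its spectral peak, vertices with < 1 mV peak-to-peak
excursion count as quiescent (0 Hz), and the scalar DF is the 90th
percentile of per-vertex DFs over non-ablated body vertices — a robust
"atrial rate" that ignores isolated PV remnants and small quiet patches.
Whether the source protocol aggregates per-vertex or uses a global signal
is unstated; the percentile rule is our choice and is shift-invariant by
construction.  A simulation is *sustained AF* when DF ≥ 4.7 Hz (threshold
inclusive); acute ablation success is the negation.

*Imaging metrics* are triangle-area sums (cm²): total, PV-antral, fibrotic
(mean vertex IIR > 1.22) and PV-fibrotic; the ordinal visual score bins
the fibrotic fraction at 10/20/35%.

## The stress battery

`enumerate_setups()` yields exactly 11 setups: (1) all-baseline
(combination fibrosis, `fiber_A`, 5 mm lesion, `map_A`, baseline ERP);
(2–4) the other fibrosis types; (5–6) fiber variants; (7) the 10 mm
lesion; (8–9) initiation-map variants; (10–11) ERP short/long
(`apd_scale` 0.8/1.2).  The upstream enums define only two fiber maps and
two initiation maps, which cannot fill two variant slots each; `fiber_C`
(−60°) and `map_C` (−35°) complete the grid.  Pre-ablation epochs are
simulated and analysed for setups 1–4; every setup then applies its lesion
to its pre-ablation end state and simulates the 2 s post-ablation epoch
for DF.  Pre-ablation states are cached and shared across setups whose
varied field does not alter pre-ablation dynamics — only lesion size
qualifies, so setup 7 reuses setup 1's state; fiber, ERP and initiation
variants re-run initiation, because the post-ablation outcome is
conditioned on the pre-ablation state.  A cache-audit test enforces this
policy.

## The synthetic cohort

The generator emulates the *statistical structure* the analysis needs, not
human anatomy: geometry is an icosphere deformed to jittered ellipsoid
radii (42/35/29 mm ± 6%, smooth low-order bumps) with four PV ostia and a
mitral orifice cut out, giving 115–175 cm² total area (the observed range
across seeds is ~130–150 cm² at defaults, matching the ~152 ± 30 cm²
scale of imaged LA cohorts).  Fibrosis is a graph-smoothed Gaussian field
rank-mapped onto an IIR scale so the fraction above 1.22 equals the target
burden exactly up to ties; burdens follow Beta(1.6, 6) (mean 0.21,
emulating ~32 cm² of 152 cm²).  History covariates mirror the roles of a
typical ablation-cohort table (age ~ N(61, 10), 70% male, hypertension
40%, diabetes 12%, LA dilation from area) without claiming its joint
distribution.  AF types default to 43/41/16% (paroxysmal / persistent /
long-standing), with an exact-quota mode reproducing 43/41/16 patients at
n = 100.  Recurrence is Bernoulli with logit
$\mathrm{qlogis}(\text{base rate}) + \beta_b(\text{burden} - 0.21) +
\beta_a(\text{area}-150)/30 + \beta_{\mathrm{af}}$; all-zero coefficients
make labels independent of every feature, and a regression-recovery test
confirms the planted coefficient is recovered within 2 SE at n = 1000.
Recurrence times are truncated-normal 189 ± 95 days in (90, 455] —
post-blanking, within one-year follow-up.  All randomness descends from
one master seed through tagged child seeds; cohorts are byte-identical
given the seed, and geometry is built lazily so statistical tests at
n = 1000+ cost nothing.

What a green end-to-end test does *not* establish: real LA shape
statistics, image segmentation error, fiber-map fidelity, or any clinical
effect size — labels are planted, so the pipeline test is about signal
*transport* (substrate → physics → metrics → classifier), not discovery.

## Outcome classification

Within each training fold only: columns are standardized, PCA (optional)
keeps the smallest component count reaching 95% explained variance, and
the classifier is fitted; test folds are transformed with training-fold
parameters (leak-freedom is asserted via transform checksums).  Folds are
stratified with a fixed seed.  The four classifiers are KNN (k = 5), an
SVM, a random forest (100 trees, √p features per split, depth ≤ 10) and
logistic regression, each with and without PCA on identical folds; the
selection rule is largest mean ROC AUC, ties broken by accuracy then the
fixed order.  AUC is the trapezoidal empirical ROC area and equals the
pair-counting U statistic (tested exhaustively for n ≤ 50, ties counted
half).  Recall/precision refer to the recurrence-positive class at the 0.5
score threshold.  Two environment-driven substitutions: no SVM or tree
package exists in the supported dependency set, so the SVM is a
least-squares SVM (kernel ridge on ±1 labels, RBF kernel with the
median-distance heuristic, fixed ridge 0.1) and the random forest is
bagged CART (Gini, random feature subsets) implemented here.  No
hyperparameter tuning loop exists anywhere, matching the protocol we
mirror.

## Numerical and testing choices worth knowing

- **Desk profile.**  `battery_config("desk")` uses 4 s pre / 2 s
  post-ablation epochs, ~2 mm meshes (≈2 350 vertices) and dt = 0.1 ms so
  a 20-patient, 3-setup pipeline runs in ~10 minutes on one CPU;
  `"paper"` restores the 15 s pre-ablation epoch.  Epoch lengths,
  profile, and seeds are recorded in each signature's provenance.
- **End-to-end acceptance world.**  The planted-signal pipeline check uses
  n = 20, balanced prevalence, and a near-separable burden effect
  (log-odds 80 per unit burden, ≈12 per burden SD).  At n = 20 even an
  oracle classifier's cross-validated AUC is noisy; a design-phase power
  analysis over 60 cohort seeds showed this world yields selected
  AUC ≥ 0.8 in 60/60 draws (min 0.89), so a failure indicates a pipeline
  defect rather than sampling noise.  The permutation null averages a
  fixed reference classifier (logistic regression) over 20 label
  permutations.
- **Cross-validation at small n.**  Ten folds cannot all contain both
  classes when a class has fewer than ten members; the acceptance test
  uses `min(10, n_pos, n_neg)` folds.  `fit_evaluate()` errors rather
  than silently skipping single-class folds.
- **ERP protocol.**  8 S1 beats at 600 ms (test fixtures shorten both),
  binary search on a 5 ms grid, capture = a new probe activation not
  present in a stimulus-free control continuation; ERP = longest
  non-capturing interval + 2.5 ms.
- **Degenerate inputs.**  Burden 0/1 saturate the IIR map below/above
  1.22; zero-burden interstitial substrates equal healthy ones; empty
  lesions are identity; a full-mesh lesion suppresses all activity;
  constant-Vm vertices are phase-undefined and excluded from PS detection;
  a quiescent movie has DF 0 by convention.

## Known limitations

Geometry is topologically faithful but anatomically crude; fibers are
rule-based, not DT-MRI; the cell model is phenomenological; lesion gaps
and recovery, additional ablation lines, biatrial geometry, and
electrogram-based features are out of scope.  Printed clinical effect
sizes (classifier AUCs of the source study, area statistics of its
cohort) are not reproducible here and are not claimed: they require the
real patient outcomes and cluster-scale simulation.
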