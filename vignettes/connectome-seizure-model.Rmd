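---
title: "Modelling seizure onset and virtual resection on structural connectomes"
author: "ictalnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure onset and virtual resection on structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ictalnet` simulates whole-brain seizure initiation as noise-driven escape
from a resting state in a network of bistable oscillators. Each of 82
atlas regions (34 Desikan-Killiany cortical + 7 subcortical structures per
hemisphere) carries a complex state $z_i$ obeying

$$\mathrm{d}z_i = \Big[ f(z_i) + \beta \sum_{j \ne i} M_{ji}\,
\big(z_j(t - \tau_{ij}) - z_i\big) \Big]\,\mathrm{d}t
+ \alpha\,\mathrm{d}w_i,$$

$$f(z) = (\lambda_i - 1 + \mathrm{i}\omega)\,z + 2 z |z|^2 - z |z|^4 .$$

For $0 < \lambda_i < 1$ the radial dynamics are bistable: a stable fixed
point at $0$ (background), an unstable limit cycle at
$r_u = \sqrt{1 - \sqrt{\lambda_i}}$, and a stable high-amplitude cycle at
$r_s = \sqrt{1 + \sqrt{\lambda_i}}$ (the seizure-like state). A region has
*escaped* at the first time $|z_i| > 1$; a run stops once three distinct
regions have escaped (evidence that activity is spreading), or at the
censoring horizon `max_time`. Escape times are the model's proxy for
seizure propensity: shorter means more seizure-prone.

Three subject-specific ingredients enter:

* **Coupling** $M = \log S / \max \log S$ from the streamline-count matrix
  $S$; entries with $S \le 1$ are set to 0 (a zero count is no edge, and a
  single streamline is below tractography noise).
* **Delays** $\tau_{ij}$ = mean fibre length / 7 m/s, binned to integer
  multiples of the solver step (a fixed-step solver can realize only such
  delays).
* **Excitability** $\lambda_i = -D_i/\psi + 0.5$, where $D_i$ measures how
  far the subject's regional surface area sits below/above the control
  distribution. Atrophy (negative $D$) raises $\lambda$, shrinking the
  basin of the background state.

Default parameters: $\beta = 0.01$, $\alpha = 0.05$, $\omega = 15$,
$\psi = 15$, conduction speed 7 m/s, escape threshold 1, three-escape
stopping rule, horizon 200 time units.

## The solver, and why `dt` is a model parameter here

The equations are integrated with a fixed-step Euler–Maruyama scheme, with
complex noise increments $\alpha(\xi_1 + \mathrm{i}\xi_2)\sqrt{\Delta t}$,
$\xi$ standard normal per node per step.

This solver choice has a quantitative consequence that shapes the whole
operating regime. The explicit Euler update of a pure rotation,
$z \mapsto z(1 + \mathrm{i}\omega\,\Delta t)$, multiplies amplitude by
$|1 + \mathrm{i}\omega\,\Delta t| > 1$ each step — a radial dilation at
rate $\omega^2 \Delta t/2$ per time unit. For the node dynamics this acts
as a uniform excitability boost: the discrete-time bifurcation to
monostability sits not at $\lambda = 1$ but at

$$\lambda^\* \;=\; 1 - \tfrac{1}{2}\omega^2 \Delta t .$$

Two facts follow.

1. **The printed noise level only works with this dilation.** With the
   rotation integrated exactly, escape at $\lambda \approx 0.5$ and
   $\alpha = 0.05$ is a Kramers problem with exponent
   $2\Delta V/\alpha^2 \approx 28$ — mean escape times of order $10^6$
   time units. No cohort experiment is possible there. With
   $\omega = 15$ and any practical step, the dilation moves the system
   into the weakly metastable regime where escapes occur within tens of
   time units, which is the regime the model's behaviour (onset around
   $t \approx 14$, patient/control contrast) clearly belongs to.
2. **Escape rates are therefore sensitive to `dt`.** Halving the step
   raises $\lambda^\*$ and slows all escapes; the suite tests this
   *direction* rather than pretending step-size invariance. The default
   `dt = 0.0025` puts $\lambda^\* \approx 0.72$, chosen so that the
   background state stays metastable for every excitability a control
   region can attain (about $\lambda \le 0.70$ under the deviation-score
   clip), while strongly atrophic patient regions approach criticality.
   The noiseless bistability radii are exact for the radial normal form
   (verified at $\omega = 0$, where the Euler fixed radius solves the
   radial equation exactly) but are dilated by the rotation at
   $\omega = 15$ — a documented, deliberate trade-off.

## Deviation scores: pooled parametric by default, rank on request

`surface_area_deviation()` offers two readings of "how many standard
deviations from the control distribution":

* `method = "pooled"` (default): a z score of log surface area against the
  per-region control means, using one residual standard deviation pooled
  across all 82 regions. Regional areas vary multiplicatively between
  subjects with similar relative spread everywhere, so log areas are
  approximately homoscedastic and pooling is variance-stabilizing — the
  same small-sample logic as pooled-variance moderated statistics in
  expression analysis. With 10 controls a per-region SD estimate has 8-9
  degrees of freedom and $t_8$ tails would routinely fabricate extreme
  scores; the pooled estimate has hundreds.
* `method = "rank"`: the nonparametric placement score
  $D = \Phi^{-1}\!\big[(\#\text{below} + 0.5\,\#\text{ties} + 0.5)/(n+1)\big]$,
  with leave-one-out referencing for controls. Robust and
  assumption-free, but it saturates at $\pm\Phi^{-1}(0.5/(n+1))$ — about
  $\pm 1.69$ for ten references — so in small cohorts genuine deep atrophy
  and an ordinary sampling extreme receive identical scores. Prefer it
  when the reference cohort is large (tens of controls).

Scores are clipped to $\pm 6$, keeping $\lambda = -D/\psi + 0.5$ within
$[0.1, 0.9]$ at $\psi = 15$ (clipping is reported when it occurs), and
controls are always scored against the remaining controls
(leave-one-out). The bound is deliberately wide: sclerotic mesial
temporal structures genuinely sit 4–8 control standard deviations below
the reference, and a tighter clip would hand them the same excitability
as an ordinary sampling extreme, erasing precisely the pathology the
model is built around.

## The synthetic cohort: what it emulates, and what it does not

No subject data ship with the package; `generate_cohort()` draws cohorts
with the statistical structure the analysis assumes:

* **Geometry.** Deterministic, hemisphere-mirrored coordinates: cortical
  regions on a half-ellipsoid lattice, subcortical structures in a deep
  central shell, and hand-placed positions for the mesial temporal
  cluster (temporal pole, entorhinal, parahippocampal, amygdala,
  hippocampus) whose mutual adjacency matters to the disease model.
* **Edges.** Regions within a 30 mm contact radius connect with
  probability 0.95 (abutting structures essentially always share a
  bundle); beyond it, probability decays exponentially (scale 50 mm) and
  is additionally scaled by $(A_i A_j)^{1/2}$ relative to the median
  canonical area — streamline endpoint counts track region size, which
  keeps small subcortical structures out of the global hub tail. Bilateral
  thalamus and insula receive a 1.5× hub boost.
* **Counts and lengths.** Log-normal streamline counts whose log-mean
  decays with distance beyond the contact radius (scale 25 mm) with the
  same size scaling; fibre lengths are tortuosity-scaled (1.3×) Euclidean
  distances with 5% noise, so mean length is a stable delay proxy.
* **Areas.** Log-normal around fixed canonical per-region values
  (realistic Desikan-scale magnitudes: temporal pole ≈500 mm², superior
  frontal ≈7300 mm²) with 10% total coefficient of variation, of which
  75% of the log-variance is a shared per-subject brain-size factor and
  the rest independent regional variation — mirroring the strong global
  component of real anatomical variability. The pooled deviation score
  removes the shared factor allometrically (robust per-subject centring),
  so chance extremes are bounded by the much tighter *residual* spread
  while focal atrophy, defined in total control-SD units, stands out
  clearly — the statistical backbone of the patient/control contrast.
* **Patients.** A control draw whose left temporal pole, amygdala,
  hippocampus, parahippocampal gyrus, putamen and thalamus lose
  `atrophy_effect_sd` (default 2) control standard deviations of surface
  area — the mesial-temporal atrophy pattern of left TLE with
  hippocampal sclerosis.

The size-scaled connectivity deserves a remark, because it is what makes
the mechanism work rather than a cosmetic choice. The diffusive coupling
contributes a damping term $-\beta s_i z_i$ ($s_i$ = node strength): a
region's escape rate depends on its *margin*
$\lambda^\* - \lambda_i + \beta s_i$. Without size scaling, the
subcortical cluster — central, hence densely connected under pure
distance decay — would be the most damped part of the network, and its
atrophy-driven excitability would be cancelled by coupling, leaving
patient and control escape profiles indistinguishable at realistic effect
sizes. With it, the atrophic cluster is weakly damped but internally
strongly coupled, so in patients the first escape recruits its
neighbours (the three-escape criterion rewards exactly this spreading),
while a control's chance extremes are scattered, strongly damped cortical
regions whose second and third escapes must happen independently.

What a green cohort experiment does **not** establish: the generator has
no global brain-size factor, no age/sex structure, no measurement noise in
the counts beyond the log-normal draw, bidirectional edges only, and its
"anatomy" is a lattice, not a brain. Results transfer to real connectomes
only to the extent that those simplifications are harmless.

## Virtual surgery

Three plans of exactly three regions each, mirroring in-silico surgical
conditions: `plan_random()` (a random seed node plus its two
strongest-coupled neighbours among those above the mean nonzero weight —
"nearest" is read in coupling weight, since the qualifying criterion is a
weight threshold), `plan_clinical()` (ipsilateral hippocampus, amygdala,
parahippocampal gyrus — the amygdalohippocampectomy), and
`plan_patient_specific()` (the three nodes most frequently among the
first three escapers of the unresected baseline; ties broken by smaller
mean escape time, then lower index). `apply_resection()` zeroes the
nodes' rows and columns and removes them from escape detection; escaped
survivors keep driving their neighbours, resected nodes drive nothing.

Improvement is assessed per patient as the percentage change in
third-escape time, pre vs post, paired by noise seed across iterations,
with a paired t test; *success* requires $p < 0.05$ **and** a positive
mean improvement. Strategy-level comparisons use Kruskal–Wallis followed
by Bonferroni-corrected pairwise Mann–Whitney tests only when the omnibus
is significant.

## Numerical and statistical conventions

* Censored runs (horizon reached before the third escape) contribute
  `max_time` to subject means — conservative, keeps all iterations
  comparable; the censored fraction is reported alongside.
* The Mann–Whitney implementation reports the U/z/p triple; p is exact
  (null U distribution) for tie-free samples up to $n = 50$, otherwise a
  tie-corrected, continuity-corrected normal approximation. Positive z
  means the first sample is larger; group comparisons pass patients
  first, so positive z = higher in patients.
* Weighted clustering uses the geometric-mean-of-triangle-weights
  (Onnela) form with weights normalized by the matrix maximum;
  eigenvector centrality is the principal eigenvector normalized to unit
  maximum, computed on the largest component with zeros elsewhere.
* Noise streams come from a package-local xoshiro256++ generator with
  Box–Muller shaping — bit-reproducible across platforms for a given
  seed, independent of R's RNG (which drives cohort sampling). One
  experiment is controlled by exactly two seeds: the cohort seed and the
  simulation base seed, echoed into every report.
* The pipeline applies common random numbers: every subject is simulated
  under the same block of noise seeds, so between-subject comparisons
  reflect model differences rather than noise-draw luck. Under the null
  of identical subject models this yields exact ties (conservative), and
  pre/post surgery runs reuse the block, keeping improvement paired by
  seed.
* The null calibration of the success criterion (independent pre/post
  replicate blocks of the same model) lands at the 5% type-I level for
  the significance test; the success flag's additional sign requirement
  halves that in expectation.

## Known limitations

* Escape-time scales are solver-coupled (see above); comparisons are
  meaningful within a fixed `dt`, and `dt` is reported with every run.
* The oscillation frequency calibration (`omega = 15` vs a nominal 3 Hz
  seizure rhythm) is left to the user via `time_unit_seconds`, which only
  affects the fibre-length-to-delay conversion; all reported times are in
  model time units.
* With ten controls the rank deviation score saturates; the pooled score
  is the default for exactly this reason, and cohorts of that size remain
  at the edge of what the deviation scoring can resolve.
* Patient-specific plans take the baseline simulations as input, so plan
  quality inherits baseline Monte Carlo error at small iteration counts.

## A minimal session

```{r example}
library(ictalnet)

config <- run_config(
  cohort = cohort_spec(n_patients = 10, n_controls = 10, seed = 1),
  n_iterations = 50,
  strategies = c("random", "clinical", "patient_specific"),
  base_seed = 100101,
  output_dir = "reports"
)
val <- run_validation(config)
val$group_comparison          # patient-vs-control escape-time tests
surg <- run_surgery(config, val)
surg$success_rates            # per-strategy % of patients improved
```
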