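---
title: "Network diffusion modelling and the Pathology Progression Rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network diffusion modelling and the Pathology Progression Rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprnet)
```

## The model

pprnet implements the Network Diffusion Model (NDM) of trans-network
pathology spread. Pathology is a nonnegative vector `x` over brain regions
(arbitrary units), and spreads along the structural connectome as linear
heat-like diffusion,

$$x(t) = e^{-\beta H t}\, x_0,$$

where `H` is a graph Laplacian of the connectivity matrix and `β` (1/year)
is the diffusivity. The model is linear, time-invariant, and — under the
unnormalized Laplacian — mass-conserving: total pathology is constant while
its spatial pattern relaxes toward the Laplacian's null mode. Measurable
regional atrophy is assumed proportional to *accumulated* pathology,
$\Phi(t) = \int_0^t x(\tau)\,d\tau$, so atrophy never decreases even where
pathology does (hypertrophy and compensatory volume gains are outside the
model). The proportionality constant between accumulated pathology and the
atrophy statistic is absorbed into the scale of `x`, so atrophy units are
arbitrary; `β` is the only physically interpreted parameter.

Both operators are evaluated spectrally from a single cached
eigendecomposition `H = U Λ Uᵀ` computed when the Laplacian is built; no
generic matrix exponential is ever formed. This makes `ndm_evolve`,
`ndm_accumulate`, `modified_laplacian` and `predicted_slope` mutually
consistent by construction, which the test suite exploits: the identity
$\beta \tilde H(\beta t)\,\Phi(t) = x(t)$ holds to ~1e-14 across random
connectomes.

## The baseline-rate operator

Because atrophy integrates pathology, the atrophy pattern at a baseline scan
and its instantaneous rate of change are related by a fixed linear operator:

$$\left.\frac{d\Phi}{dt}\right|_{t_\mathrm{base}}
  = \beta\,\tilde H(\beta t_\mathrm{base})\,\Phi_\mathrm{base},
\qquad
\tilde H(s) = U\,\mathrm{diag}\!\left(\frac{1}{s},\;
  \frac{\lambda_i e^{-\lambda_i s}}{1 - e^{-\lambda_i s}}\right) U^\top,$$

with the `1/s` entry on the Laplacian's zero mode. `t_base` is the unknown
time from pathology onset to the baseline exam. Numerically the nonzero-mode
diagonal is computed as `λ / expm1(λ s)`, which is stable for `λs` down to
1e-12 (where it approaches `1/s`) and underflows cleanly to 0 for
`λs ≳ 745` instead of producing `NaN`. The operator requires exactly one
zero mode; disconnected graphs are accepted for construction but refused by
the fitting operators, since the zero-mode term presumes a single null
direction. An eigenvalue counts as zero when it is below `1e-8` times the
largest eigenvalue.

## Estimating the PPR

Per subject, three steps are run exactly once (no iteration; an opt-in
`iterate` flag exists but is off by default):

1. **Slopes.** Each region's longitudinal atrophy is regressed on time with
   an intercept (shared QR solve of the `[1, t]` design). Negative slopes
   are set to 0 and counted — cortical "thickening" is treated as
   measurement noise in a neurodegenerative cohort. Slopes below 1e-12 in
   magnitude are snapped to 0 so solver noise on flat trajectories cannot
   masquerade as progression; a subject with all-zero slopes is returned as
   a flagged non-progressor with `beta_hat = 0`.
2. **Onset time.** With `β` pinned at a reference `β₀ = 0.05`/yr, a grid of
   candidate `t_base` values is scanned for the maximum Pearson correlation
   between `β₀ H̃(β₀ t) Φ_base` and the observed slopes. Since `H̃` depends
   on `β` and `t` only through their product and correlation is
   scale-invariant, the identified quantity is `β₀ · t̂` (an estimate of the
   true `β·t_base`); `t̂` itself is a nuisance and is only recovered if
   `β₀` happens to equal `β`. Ties and flat correlation curves resolve to
   the smallest grid point; fits at either grid boundary are flagged.
3. **Diffusivity.** `β̂ = ⟨v, slopes⟩ / ⟨v, v⟩` with
   `v = H̃(β₀ t̂) Φ_base` — the pseudoinverse of the one-column system —
   clipped at 0, since negative diffusivity is meaningless under the model.

The baseline vector is the *observed* atrophy at the first visit, not the
fitted intercept: the rate relation is stated in terms of the actual
baseline pattern, and using the intercept would smuggle slope information
into both sides of the correlation.

**Grid choice.** The default grid spans 0.25–50 years in steps of 0.25,
i.e. `β₀t ∈ [0.0125, 2.5]`. The product `β·t_base` must fall inside
`β₀ · [t_min, t_max]` for the search to succeed, so studies expecting fast
progressors with long prodromes should widen `tgrid_max` (the validation
protocols here use up to 260 years with step 0.01 — at `β₀ = 0.05`/yr that
resolves `βt` to 5e-4); boundary fits are flagged rather than silently
returned. On model-consistent data the estimator then recovers `β` to
machine precision and `β₀t̂` within one grid step of `β·t_base`.

**Finite-visit bias.** The rate relation is exact for *instantaneous*
derivatives, but empirical slopes from visits spread over 2–6 years estimate
the time-averaged derivative of a concave trajectory. This biases `β̂`
upward by roughly 10–30% for `βt` around 1–2.5 — an inherent property of
the published estimator on realistic visit schedules, not of this
implementation. The test suite pins this down: closed-loop recovery from
analytic slopes is exact to 1e-3 (machine precision in practice), recovery
from annual-visit OLS slopes is tested to stay within a 35% band while
preserving subject ordering. Rank-based downstream analyses (Kruskal–Wallis
across diagnoses, Spearman agreement) are insensitive to this
monotone bias.

**Outliers.** Fitted rates are fenced per diagnostic group at
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`, with quartiles by linear interpolation of
order statistics at index `(n−1)p` (the `quantile` type-7 convention; the
convention matters for small groups and is fixed here for reproducibility).
Groups smaller than 4 are left unflagged with a warning.

## Cohort analyses

CSF profiles are six-dimensional — raw Aβ, tau, pTau (pg/ml) plus the three
ratios, each z-scored against the control cohort (sample mean, n−1 sd);
subjects missing any raw biomarker are dropped and counted rather than
imputed. Clustering is agglomerative with Ward linkage on Euclidean distance
(the standard companion to a variance-ratio criterion; average and complete
linkage are available), cut at each candidate `k` in 2–10, and `k` is chosen
by the Calinski–Harabasz index
$CH(k) = \frac{B/(k-1)}{W/(n-k)}$ computed directly from the cut labels,
ties to the smaller `k`. Degenerate geometry (total scatter numerically
zero) short-circuits to the smallest candidate instead of dividing by a
vanishing `W`. Group contrasts use Kruskal–Wallis, Wilcoxon rank-sum
(normal approximation, so calibration holds under ties), and chi-square
without continuity correction; p-values are reported uncorrected by design,
with Benjamini–Hochberg available to callers via `p.adjust`. Region
selection ranks per-region pooled-variance t-statistics (cases vs controls)
and returns the `k` most negative, ties in label order; the baseline
regression is ordinary least squares of `β̂` (or any progression measure,
e.g. the global atrophy rate) on the 10 selected regional volumes plus 3
CSF biomarkers, refusing rank-deficient designs by naming the collinear
columns.

## The synthetic generator

The generator exists so every stage is testable without subject data, and
its defaults are the package's fixed study conditions:

* **Connectome** — a random spanning tree plus random extra edges up to the
  edge budget implied by 85% target sparsity, log-normal weights
  (heavy-tailed like streamline counts), symmetric, connected by
  construction, normalized to unit total weight. 86 regions with standard
  cortical/subcortical labels so anatomical seeding works by name.
* **Subjects** — pathology seeded in bilateral entorhinal cortex and
  hippocampus (the canonical early-disease sites), forward-simulated with
  per-group log-normal diffusivities (medians 0.05/0.10/0.15 per year for
  EMCI/LMCI/AD-like groups, sdlog 0.3 — chosen to give ordered, separable
  groups at desk scale), onset-to-baseline times uniform on 5–20 years,
  annual visits over 3 years, and Gaussian observation noise at 5% of the
  signal RMS applied to observed atrophy (where measurement error arises),
  floored at 0.
* **CSF** — each subject is assigned one of three clusters; raw
  (Aβ, tau, pTau) triples are drawn around cluster centroids
  (190, 72, 35) / (160, 100, 47) / (130, 135, 60) pg/ml with within-cluster
  sd (10, 8, 4), against controls at (198, 68, 33); ratios are derived from
  the raws so the six-dimensional profile stays internally consistent. The
  third cluster carries the Alzheimer-type signature (low Aβ, high
  tau/pTau) by construction. Magnitudes follow published cohort ranges;
  the within-cluster spread is deliberately tighter than raw diagnostic
  groups so that planted structure is recoverable.
* **Covariates** — APOE4 allele-count probabilities, MMSE and FAQ all track
  the subject's diffusivity rank, giving the expected group contrasts.

What it does **not** emulate: registration/segmentation error structure,
spatially correlated measurement noise, site and scanner effects, missing
visits, age confounding, or any departure of real disease from the diffusion
model itself. Passing recovery tests on this generator therefore validates
the *estimator* (inverse matches forward model under noise), not the model's
biological fidelity.

## Validation scale and determinism

The shipped validation runs at desk scale, chosen to keep the full suite
under a minute of compute: 100 random connectomes for the operator oracle, a
5×5 `(β, t_base)` grid for noiseless recovery, 200 subjects × 4 noise levels
for noisy recovery, 20 cohort seeds for cluster recovery, and 1000
permutation replicates for test calibration. Every stochastic step takes an
explicit seed; the CLI stamps outputs with the tool version, a config hash
(excluding path-valued keys) and the seed, and contains no timestamps, so a
rerun with the same config and seed is byte-identical — asserted end-to-end
in the acceptance tests.

## Known limitations

* `t_base` is not separately identifiable from `β` — only their product is
  estimated; reporting `t̂` as an onset age would be a misreading.
* The finite-visit slope bias above; longer follow-up or visit-midpoint
  corrections would reduce it but are not part of the published estimator.
* The diffusion model is linear: aggregation kinetics, selective regional
  vulnerability and directed transport are out of scope.
* Complete-case handling throughout; no imputation of CSF biomarkers.
* Clustering quality degrades gracefully but silently as cluster overlap
  grows; the CH curve should always be inspected, not just `k_selected`.
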