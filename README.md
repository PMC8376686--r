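# pprnet

Network diffusion modelling of neurodegenerative pathology spread, and
estimation of a per-subject **Pathology Progression Rate (PPR)** from
longitudinal regional brain atrophy.

## The problem and the model

In Alzheimer's disease and related disorders, misfolded protein pathology is
thought to propagate trans-neuronally along white-matter connections. The
**Network Diffusion Model (NDM)** formalizes this as heat-like diffusion on
the structural connectome: with `H` a graph Laplacian of the region-by-region
connectivity matrix `C` (canonically 86 Desikan-Killiany regions), the
regional pathology pattern evolves as

    x(t) = exp(-β H t) · x₀

where `β` (1/year) is the diffusivity — the speed at which pathology spreads
through the network. Measured MRI atrophy is modelled as accumulated
pathology, `Φ(t) = ∫₀ᵗ x(τ) dτ`. Under this model the atrophy pattern at a
baseline scan and its instantaneous rate of change are linked exactly by a
modified Laplacian `H̃`:

    dΦ/dt |_base = β · H̃(β t_base) · Φ_base,
    H̃(s) = U diag( 1/s [zero mode],  λᵢ e^{-λᵢ s} / (1 - e^{-λᵢ s}) ) Uᵀ

with `H = U Λ Uᵀ` and `t_base` the (unobserved) years from pathology onset to
the baseline scan. The package estimates each subject's `β` — the PPR — in
three steps: (1) per-region OLS slopes of longitudinal atrophy, negatives
clipped to 0; (2) a grid search for `t_base` maximizing the Pearson
correlation between `β₀·H̃(β₀t)·Φ_base` and the observed slopes at a reference
`β₀ = 0.05`/yr (identifying the product `β·t_base`); (3) scalar least squares
for `β̂`. Cohort tools cover Tukey-fence outlier flagging per diagnostic
group, CSF biomarker z-scoring against controls, Ward hierarchical clustering
with Calinski–Harabasz model selection, non-parametric group comparisons, and
baseline multivariate regression. A deterministic synthetic-cohort generator
provides connectomes, NDM-driven longitudinal atrophy with known ground
truth, and 3-cluster CSF profiles, so the whole pipeline is testable without
any data download.

Intended users: researchers modelling progression on connectomes who want a
reproducible, tested reference implementation of the diffusivity estimator
and its surrounding cohort statistics.

## Worked example

```r
library(pprnet)

conn <- synth_connectome(n_regions = 86, target_sparsity = 0.85, seed = 11)
conn
#> Connectome: 86 regions
#>   sparsity (off-diagonal zero fraction): 0.8501
#>   total weight: 1

L <- build_laplacian(conn, kind = "normalized")

# one synthetic patient: true beta = 0.12/yr, onset 10 yr before baseline,
# annual scans for 3 years, 2% observation noise
sub <- synth_subject(L, beta = 0.12, t_base = 10, visits = c(0, 1, 2, 3),
                     noise_sd = 0.02, seed = 11)
fit <- fit_ppr(sub$trajectory, L, grid = tbase_grid(0.25, 150, 0.25))
fit
#> PPR fit for subject S1
#>   beta_hat: 0.12259 per year
#>   tbase_hat: 26.25 years (nuisance; beta0 * tbase_hat identifies beta * t_base)
#>   peak correlation: 0.9823
```

`beta_hat` recovers the planted 0.12/yr within ~2%; `peak_correlation` is the
Pearson match between the model-predicted and observed slope patterns at the
optimum. `tbase_hat` is a nuisance: only `beta0 * tbase_hat ≈ beta * t_base`
is identified (0.05 × 26.25 ≈ 1.31 vs 0.12 × 10 + the few observed years),
so it should not be read as an onset-time estimate.

```r
# cohort level: 3-cluster CSF structure recovered by variance-ratio selection
co <- synth_cohort(cohort_spec(seed = 11))
zs <- zscore_biomarkers(co$csf, co$csf_controls)
hierarchical_cluster(zs$z)
#> Hierarchical clustering (ward.D2): selected k = 3
#>   cluster sizes: 47 / 36 / 37
#>   CH curve:
#>      2      3      4      5      6      7      8      9     10
#> 219.10 335.43 289.50 246.69 227.44 212.62 199.62 192.84 186.40
```

The Calinski–Harabasz curve peaks at k = 3, matching the generator's planted
cluster count; cluster 3 carries the Alzheimer-type signature (low CSF Aβ,
raised tau/pTau relative to controls).

## Command line

```sh
Rscript inst/cli/pprnet.R simulate --seed 3 --out run1 --n-per-group 20
Rscript inst/cli/pprnet.R fit --out run1 --connectome run1/connectome.csv \
    --atrophy run1/atrophy_long.csv --tgrid 0.25:150:0.5
Rscript inst/cli/pprnet.R cluster-report --out run1
```

All outputs are delimited text with provenance headers (tool version, config
hash, seed); reruns with the same seed are byte-identical.

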