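# thermotree

Tropical insects live close to their thermal limits. Along elevation
gradients, the critical thermal maximum (CTmax) of whole insect communities
tracks local temperature only partially, its evolution is phylogenetically
constrained, and temperatures well below CTmax already cause heat coma when
exposure accumulates over hours. `thermotree` packages the statistics
behind this kind of study for ecophysiologists and comparative biologists:
it takes ramping-assay tables, community phylogenies and microclimate
series, and returns community summaries, comparative-model fits and
climate-projection fractions — with a synthetic-data module that generates
every input with known ground truth so each estimator is covered by
parameter-recovery tests.

## Models at the core

**Trait evolution.** Tip CTmax is multivariate normal with mean Xβ and a
tree-structured covariance: Brownian motion (C_ij = σ²·t_shared),
stationary Ornstein–Uhlenbeck with pull α towards an optimum θ
(C_ij = σ²/(2α)·e^(−α·d_ij)), or independent tips (star). Fits are by
maximum likelihood with σ² profiled out; models are compared by AIC, the
optimum θ is the GLS mean under the OU covariance, and variance is
partitioned by likelihood-based partial r² (1 − exp(−(2/n)·ΔlogL)).
Phylogenetic signal comes as Pagel's λ (scalar ML, likelihood-ratio test),
Blomberg's K (variance ratio over its Brownian expectation, permutation
test), a Moran's-I correlogram over patristic-distance classes, and
BM ancestral states (node-wise GLS means). Supertrees are assembled by
grafting family subtrees onto an ultrametric backbone, bladj-style even
age interpolation between calibrated nodes, and tip-height equalization.

**Thermal death time.** Static tolerance is the log-linear landscape
t_coma(T) = t_ref·10^((T_L − T)/z); z is fitted as −1/slope of
log₁₀(time) on temperature. Dynamic (ramping) limits convert to T_L by
solving the injury-accumulation integral of a linear ramp
(z/(r·ln10·t_ref))·[10^((CTmax_dyn−T_L)/z) − 10^((T_start−T_L)/z)] = 1.
A measurement is *critical* when coma is predicted within 8 h, i.e. above
T_L − z·log₁₀(480/t_ref); fractions are over all retained values, nights
included. Scenario series are the current series plus the bio5 anomaly.

## Worked example

```r
library(thermotree)

# a 150-OTU community tree and a trait under stationary OU around 42.2 degC
tr  <- simulate_tree(150, seed = 11, n_families = 12)
y   <- simulate_trait_ou(tr, list(beta0 = 42.2, beta_elev = 0,
                                  alpha = 3, sigma2 = 6), rep(0, 150), seed = 11)
opt <- fit_ou_optimum(tr, y)
sig <- pagel_lambda(tr, y)
K   <- blomberg_k(tr, y, n_perm = 999, seed = 1)

# thermal sensitivity from a noiseless knockdown curve, and an 8-h threshold
kd   <- simulate_static_knockdowns(list(T_L = 46, z = 2.16, t_ref = 1), 38:46)
zfit <- fit_z(kd)
sens <- community_sensitivity(c(40, 40.5, 41, 41, 41.5, 42, 42, 42.5, 43, 44),
                              ramp_rate = 0.5, z = 3)
classify_critical(data.frame(value = c(30, 34, 36.5, 38, 39.5)), sens$median)
```

Output:

```
theta = 41.98 degC, alpha = 3.39, AIC = 317.9
lambda = 1.00 (p = 2.3e-15), K = 0.29 (p = 0.001)
z-hat = 2.16, T_L = 46.00 degC
median landscape: T_L = 43.00 degC, 8-h critical temperature = 34.95 degC
critical fraction of toy series: 0.6
```

The OU optimum recovers its generative 42.2 degC within sampling error; a
Brownian trait on a 150-tip tree shows full λ and K below 1 (its usual
behaviour on imbalanced trees); the TDT line built with z = 2.16 returns
exactly that sensitivity; and three of the five toy temperatures lie above
the 34.95 degC critical temperature of the median community landscape.

## The analysis workflow

Numbered drivers under `analysis/` run the full synthetic study and write
tidy tables under `results/`:

1. `01_simulate.R` — generate the study (tree, assays, plots, microclimate,
   knockdowns, protein Tm, `truth.json`).
2. `02_assay_stats.R` — plot quantiles, elevational/MAT trends (OLS and
   k = 5 spline), heat-shock effects by band, observer ANOVA.
3. `03_phylo.R` — ancestral states, correlogram, λ and K, BM/OU/star PGLS
   with AIC ranking, OU optimum, variance partitioning.
4. `04_tdt.R` — z fit, lowland community sensitivity levels,
   critical-temperature fractions for current and SSP scenarios.
5. `05_protein_tm.R` — heat-sensitive Tm statistics, taxonomic variance
   tests, family-level Tm~CTmax regressions.

`run_pipeline()` performs the same sequence programmatically from one
configuration.

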