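---
title: "Methods: thermal limits, phylogenetic constraint, and heat-coma projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal limits, phylogenetic constraint, and heat-coma projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotree)
```

# Scope

`thermotree` reimplements, as a tested pipeline, the statistical core of a
community-level study of insect heat tolerance along tropical elevation
gradients: ramping-assay summaries, phylogenetic comparative models of
CTmax, and a thermal-death-time (TDT) engine that converts assay limits
into heat-coma times and critical-temperature fractions under present and
anomaly-shifted climates. Because the original field, satellite and genomic
data are external, a synthetic-data module generates every input with known
ground truth; all statistical claims the package makes about itself are
parameter-recovery claims computed by its own test suite and acceptance
script.

# Ramping assays and their discretization

An individual's critical thermal maximum (CTmax) is the temperature at
which it loses coordinated mobility while temperature ramps up in 1 degC
steps held for 2 min (rate 0.5 degC/min) from a 28 degC start; CTmin
mirrors this downward. The generator treats the true threshold as latent
and records the first grid temperature at which the insect would be seen
immobile: ceiling-to-grid for CTmax, floor for CTmin. The protocol itself
does not state the discretization convention; the 2-min check interval
implies the observer can only catch the threshold at the next grid point,
which is what the ceiling rule encodes. Consequently recorded minus true
CTmax lies in [0, 1) degC, a bias that cancels in group differences (the
heat-shock effect) and in slopes, but adds ~0.5 degC to intercepts.

Community summaries use one fixed quantile rule everywhere (linear
interpolation between order statistics, R's type 7, `ct_quantile()`); the
choice is arbitrary but frozen for reproducibility, and shared by the
protein-Tm module. Elevational trends are fitted either by ordinary least
squares or by a penalized regression spline with basis dimension k = 5
(`mgcv`, smoothness by GCV); k = 5 deliberately limits the trend to gentle
saturation shapes. Heat-shock (plasticity) effects are shocked-minus-control
group means for CTmax and control-minus-shocked for CTmin, so a positive
effect always means increased tolerance; elevation bands are half-open
[0, 600), [600, 1200), [1200, Inf) metres.

# Trait evolution on the community tree

The comparative engine treats tip CTmax as multivariate normal with mean
`X beta` and a covariance determined by the tree:

* Brownian motion (BM): `C_ij = sigma2 * (shared root-to-tip path length)`.
* Stationary Ornstein-Uhlenbeck (OU): pull of strength `alpha` towards an
  optimum; `C_ij = sigma2/(2 alpha) * exp(-alpha * d_ij)` with `d_ij` the
  patristic distance, the root drawn from the stationary distribution.
* Star: independent tips (ordinary regression), the `alpha -> Inf` limit.

The residual scale is profiled out of the likelihood; `alpha` is profiled
on the log scale by a deterministic 25-point coarse grid over
`[1e-3, 1e3]/depth` followed by bounded refinement (tolerance 1e-8). An
estimate at the grid boundary is flagged, not hidden: it means the data
prefer an effectively independent (or effectively Brownian) structure and
the OU parameters are not separately identified. A fixed-root OU variant
(`ou_root = "fixed"`) is available because published PGLS implementations
differ in this choice; the stationary form is the default and is the form
the generator simulates, so recovery tests close the loop. With an
intercept-only mean the OU fit yields the evolutionary optimum `theta` as
the GLS mean under the OU covariance.

Model support is compared by AIC, counting coefficients + sigma2 (+ alpha
for OU); ties are broken alphabetically so output is deterministic.
Variance partitioning uses the likelihood-based partial r2,
`1 - exp(-(2/n)(logL_full - logL_reduced))`: predictors are dropped one at
a time keeping the covariance, and the phylogeny component replaces the
covariance by the star model keeping all predictors. This definition is
well-defined under correlated errors, reduces to the classical partial r2
for independent observations (tested), and was chosen because the
partitioning tool used in the original analysis does not document its
internals.

Phylogenetic signal statistics: Pagel's lambda scales the off-diagonal
covariance and is estimated by bounded scalar ML with a likelihood-ratio
test against lambda = 0; Blomberg's K is the observed variance ratio over
its Brownian expectation, with a one-tailed tip-permutation test.
Permutation p-values use (b+1)/(m+1) smoothing and record their seed. The
correlogram bins pairwise 1/distance weights into equal-frequency classes;
on ultrametric trees a large mass of tip pairs crosses the root at the
identical maximal distance, so tied class breaks are collapsed rather than
fabricating empty bins. Ancestral states are ML states under BM, computed
node by node as the GLS mean under the covariance induced by re-rooting at
that node; the root state therefore equals `(1'C^-1 y)/(1'C^-1 1)` exactly,
which is the dense-matrix oracle the tests assert at 1e-8.

## Supertree assembly

Family subtrees (with their own relative branch lengths) replace the
matching tips of an ultrametric family backbone; a single-OTU family
becomes one pendant branch, by default half the family's backbone terminal
branch since a degree-2 attachment point would be vacuous. Node ages are
then calibrated bladj-style: fixed ages (the root at minimum) are honoured
and every unconstrained node age is interpolated evenly, by node count,
between its nearest constrained ancestor and a constrained descendant.
The descendant is taken along the *longest* chain of unconstrained nodes:
on a binary tree the upper nodes of a long uncalibrated chain always have
some one-step path to a tip, and interpolating against that short side
branch would compress the whole chain into the top of the age range instead
of spreading it evenly. Finally, terminal branches are extended so all tip
heights equal the maximum depth; the result looks ultrametric but carries
relative, not absolute, time.

# The thermal-death-time model

Static heat tolerance is a log-linear landscape: time to heat coma at
constant temperature T is

`t_coma(T) = t_ref * 10^((T_L - T)/z)`

with `z` the thermal sensitivity (degC that divides knockdown time by ten,
typically 1-5 for insects; the pipeline default is the conservative z = 3)
and `T_L` the temperature causing coma at the reference time `t_ref`. The
reference time is set to 1 min; the source framework leaves it
unspecified, and every downstream quantity is expressed through the closed
form so `t_ref` remains an explicit knob. `z` is estimated from static
knockdown tables by least squares of log10(time) on temperature
(`z = -1/slope`).

A ramping assay measures a *dynamic* limit. Under memoryless,
non-recoverable injury accumulation (injury rate `1/t_coma(T)`), a linear
ramp at rate r starting at `T_start` reaches coma at `ct_dyn` when

`(z / (r ln10 t_ref)) * (10^((ct_dyn - T_L)/z) - 10^((T_start - T_L)/z)) = 1`.

`dynamic_to_static()` solves this for `T_L` by bracketed root finding
(default), or drops the start term for the closed form
`T_L = ct_dyn - z log10(r t_ref ln10 / z)`; the two agree within 0.05 degC
whenever the start is at least 3z below the dynamic limit. The forward ramp
simulator (`ramp_to_coma()`, step 5e-4 min quadrature) is kept in the
package as the independent oracle: conversion and simulation round-trip
within 0.01 degC across z in [1, 5] and rates in [0.06, 1] degC/min.

A temperature measurement is *critical* when the predicted coma time is at
or below 8 h (480 min; the boundary counts as critical), equivalently when
it exceeds `T_L - z log10(480/t_ref)`. Fractions are always over all
retained measurements, night values included. Community sensitivity levels
convert the lowland 10%/25%/50% CTmax quantiles into three static
landscapes applied gradient-wide — a conservative stance that assumes
upslope communities could at best reach lowland tolerance. Climate
scenarios shift a series by the bio5 anomaly (future minus current mean
daily maximum of the warmest month); surface series get the same
air-derived shift (surfaces are expected to warm at least as fast, so the
projected fractions are lower bounds), with a multiplier exposed for
sensitivity analysis. Series pass a quality filter first (keep only
best-quality flags, `0b00` by default).

# The synthetic study and what it does (not) show

The generator emulates: a pure-birth ultrametric phylogeny rescaled to
depth 1 with monophyletic families cut at a fixed lineage count; CTmax
evolving branchwise under stationary OU around `beta0 + beta_elev * elev`;
assay discretization as above with individual scatter (sd 1 degC — the
study does not report within-species variance, so it is an explicit free
parameter); 15-min microclimate as lapse-shifted diurnal + weak annual
sinusoids with stationary AR(1) noise (sd 1.5 degC, coefficient 0.7);
TDT knockdown times with log10-normal noise; and a hierarchical-normal
protein-Tm table. All streams derive from one root seed via named
substreams, so adding a generator leaves the others' draws untouched, and
identical configurations are byte-identical.

Default trait parameters are `beta0 = 42.2` degC (the community optimum),
`beta_elev = -0.0022` degC/m (the Neotropical 0.41 degC per degC of mean
annual temperature times a 0.0054 degC/m lapse), `alpha = 0.3`,
`sigma2 = 10`. The pull strength deserves a note: the assay layer adds
individual scatter that is independent across tips, and once
`alpha * depth` rises much above 1 the OU tip covariance itself decays so
fast that the fitted pull runs to the boundary and the model collapses onto
the star fit. `alpha = 0.3` keeps the fitted covariance interior and
reproduces the qualitative structure the analysis is about: OU preferred
over BM and star by AIC, intermediate lambda, K well below 1, and
explained variance split between phylogeny and elevation. The
parameter-recovery suites use their own, steeper conditions
(`alpha = 3, sigma2 = 6` on 300-tip trees for the optimum; a
lambda-transformed BM draw at 0.76 on 500-tip trees for the signal
estimate), where the corresponding estimator is well identified.

What passing tests do *not* show: real microclimate is not a two-sinusoid
AR(1) process (no weather fronts, no canopy heterogeneity); real elevation
is phylogenetically structured whereas the generator assigns plots to OTUs
independently; the protein-Tm generator has no phylogeny beyond the
order/family hierarchy; and the headline percentages of critical future
temperatures in the original study depend on its deposited logger and
satellite series, which desk-scale synthetic data cannot and do not
reproduce — the TDT engine is instead validated through closed-form
identities, hand-countable fractions and monotonicity under anomaly
shifts.

# Numerical choices and degenerate inputs

* Covariance solves go through Cholesky factorizations; non-positive
  definite matrices raise a classed error rather than silently
  regularizing.
* lambda is maximized with `optimize` on [0, 1] (tol 1e-8) with explicit
  endpoint evaluation, since interior search can miss a boundary optimum.
* A constant trait short-circuits the OU optimum fit (`theta` = the
  constant, `sigma2` = 0); a constant predictor is a degenerate-design
  error; a single observer, a single temperature, an empty series and an
  all-dropped QC filter each produce a classed error or warning named in
  the tests.
* Problem sizes in the default suites (300-500 tips, 50-200 replicates,
  30-day microclimate) were chosen so each estimator's Monte-Carlo error
  is several times smaller than the tolerance being asserted.

# Known limitations

Mixed-effects assay models and Bayesian comparative methods are out of
scope. The protein variance tests aggregate to species means before the
nested fixed-effects ANOVA — a conservative approximation to a mixed model
with random protein identity, so its F statistics are not comparable in
magnitude to protein-level analyses. The OU fixed-root variant is provided
but untested against an external reference. Tree inference from sequences,
OTU clustering and Tm prediction are upstream of this package and are
assumed done.
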