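---
title: "Spatial capture-recapture density estimation with scrdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial capture-recapture density estimation with scrdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Camera-trap surveys of individually identifiable carnivores produce sparse
binary encounter histories: which identified individual was photographed at
which site during which capture occasion. Converting those histories into a
population density is delicate because detectability falls off with the
distance between a trap and an animal's home range, and because the area
effectively sampled by a trap array is not the area of the array itself.
`scrdens` implements the two standard answers on a common data model:

* **spatial capture-recapture (SCR)**: a latent activity center per
  individual, an explicit detection-versus-distance function, and a density
  defined over a discretized state-space — the recommended approach;
* **nonspatial closed-population estimators (M0, Mh)** whose abundance is
  divided by an *effective trapping area* (ETA) built from observed
  movement distances — retained for comparability with the older
  literature.

## Data model

A session is a `trap_array` (sites with planar coordinates in meters and a
site × occasion activity mask — a pair of cameras photographing the two
flanks of a passing animal is one detector) together with an
`encounter_data` array `y[i, j, k]` of binary detections. Occasions
aggregate `L = 5` successive trap nights by default; a deployment of `D`
days yields `ceiling(D / L)` occasions, and a trailing occasion shorter than
`L` keeps its true activity pattern rather than being dropped, so no
detection is ever discarded. (Published survey tables from staggered
multi-site deployments sometimes print more occasions than `ceiling(D / L)`
of the *average* deployment length would give; per-site start-date staggering
explains this, and the ceiling rule is the faithful per-session choice.)
Repeated photographs of one individual at one site within an occasion
collapse to a single detection, which dissociates trapping events from
photograph counts and avoids pseudo-replication. Coordinates must be planar
meters — geographic longitude/latitude input is rejected rather than
converted, because every distance in the model is Euclidean.

## The SCR model

Detection is half-normal: an individual centered at `s` is detected at a
trap `j` at distance `d_j(s)` in one occasion with probability
`p_j(s) = p0 exp(-d_j(s)^2 / (2 sigma^2))`. The two parameters have direct
interpretations: `p0` is the per-occasion detection probability of a trap
sitting exactly on the activity center, `sigma` (meters) sets how quickly
detection decays with distance and scales with home-range size.

Activity centers follow a homogeneous Poisson point process of intensity `D`
(individuals per m²) over the state-space `S`: the rectangle of trap
locations buffered by 15 km on each side and discretized into 1.5-km pixels
(area `a` = 2.25 km²). The defaults mirror the survey design this package
models: a 15-km buffer is at least twice any plausible lynx `sigma`, and the
likelihood is insensitive to buffering beyond `2 sigma` (a post-fit check
warns if the buffer is narrower than `2 * sigma_hat`). The full rectangle is
used — no habitat mask — matching a homogeneous-density model.

With pixels `g`, per-session minus log-likelihood:

```
-log L = - sum_i log( sum_g D a P(y_i | s_g) ) + sum_g D a pdot(s_g) + log(n!)
```

where `P(y_i | s)` multiplies Bernoulli terms over active site-occasions and
`pdot(s) = 1 - prod_{j,k active} (1 - p_j(s))`. Because detection is
constant across occasions, each individual enters only through its per-site
occasion-detection counts, which keeps evaluation at `O(G x J)` per
individual. Everything is computed in log space with log-sum-exp, so the
likelihood is finite for any valid input.

Multi-session fits share `(logit p0, log sigma)` within user-defined sharing
groups while density stays per-session — the device used to stabilize
estimates when one study area detects only a handful of individuals.

### Why the Poisson form

The number of activity centers is modelled as Poisson rather than fixed
(binomial) `N`. The two differ negligibly at these sample sizes, the Poisson
form is smooth in all parameters, and it admits a closed-form profile for
density: given the detection parameters the per-session MLE is
`D = n / (a sum_g pdot(s_g))`. The optimizer therefore only searches the
detection scale, and the abundance identity below holds exactly at the
optimum. A fixed-`N` simulation mode exists in the generator for recovery
experiments.

### Estimation and uncertainty

Optimization is quasi-Newton (BFGS) on unconstrained `(logit p0, log sigma)`
with density profiled out, multi-started (3 starts by default) from a
method-of-moments initializer: `sigma0 = MMDM / 2`, `p0 = 0.1`,
`D0 = n / A(S)`; the extra starts sit at fixed offsets from the initializer
so fits are reproducible without touching the RNG. If no individual moved
between sites, `sigma0` falls back on the median nearest-neighbor trap
spacing. The variance matrix is the inverse of a central-difference Hessian
of the *joint* likelihood at the optimum; non-convergence is flagged, a
singular information matrix yields missing SEs with a warning, and the final
gradient norm is reported. Abundance is expected abundance
`N = D * A(S)` with the delta-method SE `N * SE(log D)`; realized-abundance
summaries can be derived from the density surface if wanted, but expected
abundance is the default report.

### Density surfaces

`density_surface()` returns, per pixel, the posterior expected number of
activity centers: each detected individual's posterior membership
probability plus the expected undetected centers `D a (1 - pdot(s))`. At the
MLE the pixel values sum exactly to `N` (the profile identity), which the
tests assert at `1e-6` relative tolerance. Two limits are useful intuition
and are also tested: as `p0 -> 0` the surface flattens to `D a` everywhere
(no information), and an individual detected many times at one site with
small `sigma` concentrates its posterior in the pixel containing that site.
Pixel-level plots should still be read cautiously — the surface mixes
posterior mass of observed individuals with a flat expectation for
unobserved ones.

## Nonspatial track

`capture_frequencies()` reduces a session to `f[c]`, the number of
individuals detected in exactly `c` occasions (detection at any site counts
once). `fit_m0()` maximizes the constant-`p` closed-population likelihood
with `N` continuous (`p` profiled analytically; `N` reported both continuous
and rounded; all-singleton data give an unbounded, flagged estimate).
`fit_mh_chao()` is Chao's lower-bound estimator
`N = n + f1^2 / (2 f2)` (bias-corrected `n + f1(f1-1)/(2(f2+1))` when
`f2 = 0`) with Chao's variance. The heterogeneity estimator behind published
Mh rows of comparable studies is typically not stated; Chao's bound is the
defensible default, and numerical equality with any particular published Mh
row is not guaranteed. A directional fact worth remembering (and tested
here by simulation): fitting M0 to heterogeneous-detection data
underestimates abundance, so M0 densities are conservative.

Conversion to density uses the effective trapping area: the convex hull of
the trap coordinates dilated by a buffer `w` equal to the MMDM (or half of
it), where the MMDM averages, over individuals detected at more than one
site, the maximum pairwise distance between their capture sites. For a
convex hull the dilated area is exactly `A + P w + pi w^2` (point: `pi w^2`;
collinear sites: `2 L w + pi w^2`). "Trapping area" is taken as the convex
hull — the dominant convention in the camera-trap literature; a
union-of-discs alternative (`method = "disc_union"`, fine-grid quadrature,
approximate) is available for sensitivity analysis. Density is
`100 N / ETA(km2)` per 100 km², with ETA treated as fixed in the SE — the
convention of the comparison literature, which understates uncertainty but
keeps SEs interpretable as abundance SEs rescaled.

One published-table caveat found while validating the arithmetic: in the
survey tables this package is benchmarked against, one M0/MMDM density cell
(printed 0.31 from abundance 4 over 1,991 km², which gives 0.20) is
internally inconsistent; the package's checks use the consistent cells only.

## The synthetic-data generator

`make_checkerboard_traps()` reproduces the systematic design of lynx camera
surveys: square cells of 2.7 km side, one site at the center of every second
cell, so any plausible home range contains a site.  `simulate_scr()` draws
`N ~ Poisson(D * A(S))` (or fixed `N`) centers — a pixel chosen uniformly,
then a uniform within-pixel jitter, matching the estimator's discretization
without lattice artifacts — and Bernoulli detections from the half-normal
model on active site-occasions. Individuals with all-zero histories are
kept in the truth record but omitted from the encounter data, exactly as a
real survey would never see them. `assign_sex()` adds iid F/M/U labels
(sex is known for only a minority of individuals in the motivating surveys);
camera failure can be emulated with a per-site-occasion dropout probability
(default 0). Default generating values are the study conditions the package
targets: `p0 = plogis(-2.34)`, `sigma = exp(8.80)` m, 13 occasions, and
`E[N] = 30` over the buffered state-space.

What the generator does *not* emulate — and what passing recovery tests
therefore do not demonstrate about field data: behavioral responses to
traps, transient individuals passing through during the mating season,
sex-specific movement scales, temporal variation in effort quality, and
habitat heterogeneity in density. Recovery results validate the estimator
under its own assumptions, nothing more.

## Numerical choices and edge cases

* Optimizer gradient tolerance: BFGS with `reltol = 1e-12` on the profiled
  likelihood; the reported gradient norm at the optimum is typically below
  `1e-3` on the standardized scale.
* Detection probabilities are clamped at `1 - 1e-12` before `log(1 - p)` so
  degenerate inputs (e.g. `p0 = 1` at distance 0) stay finite.
* Occasion collapsing is `ceiling`-based and idempotent; a site-occasion is
  active if any of its days was active.
* Ties in the M0 profile likelihood cannot occur (strict concavity past the
  boundary); the boundary case "every individual seen exactly once" is
  detected and flagged rather than returning a spuriously large number.
* Degenerate trap geometries (single site, collinear sites) use the exact
  disc/stadium ETA forms rather than the polygon formula.
* State-space grids always cover the buffered bounding box (`ceiling` on the
  pixel count), so the grid can overshoot the box by less than one pixel per
  axis; the overshoot is part of `A(S)` and is consistent between fitting and
  reporting.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on synthetic data
generated in code. The calibration experiments use a 91-site checkerboard
(13 x 14 cells of 2.7 km), 13 occasions, E[N] = 30 with 25 replicates for
the headline recovery experiment, and 100 replicates for the bias/coverage
study at the same design; likelihood-equivalence oracles enumerate instances
up to 4 pixels x 3 sites x 3 occasions x 3 individuals. These sizes were
chosen so that a full run is comfortable on a laptop while Monte-Carlo
standard errors stay small enough for 3-SE calibration checks to have
teeth.

## Known limitations

* Homogeneous density only — no density covariates or habitat masks.
* Euclidean distances only; least-cost-path (connectivity-aware) SCR is out
  of scope.
* No behavioral (trap-happy/shy) or temporal detection effects; no
  sex-specific `sigma` (the data model carries sex labels so the extension
  is natural, but surveys with mostly unknown sex rarely support it).
* Maximum likelihood only — no Bayesian/MCMC fitting.
* Expected-versus-realized abundance: the package reports expected
  abundance; with very high per-individual detection rates realized-N
  uncertainty would be smaller than the reported SE.
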