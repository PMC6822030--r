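# scrdens

Maximum-likelihood **spatial capture–recapture (SCR)** density estimation for
camera-trap surveys of individually identifiable, wide-ranging animals
(large carnivores such as the Eurasian lynx are the motivating case). The
package also implements the classical nonspatial workflow — closed-population
abundance estimators converted to density through an effective trapping
area — so the two approaches can be compared on the same data, plus a
synthetic-data generator that reproduces the statistical structure of such
surveys for testing and calibration.

## The model

A survey session consists of `J` camera sites with planar coordinates (m), a
binary site × occasion activity mask, and binary detections `y[i,j,k]` of
individual `i` at site `j` in occasion `k` (an occasion aggregates 5
successive trap nights by default; repeated photographs within an occasion
count once). Each individual carries a latent activity center `s`, and
detections are Bernoulli with the half-normal detection function

    p_j(s) = p0 * exp(-d_j(s)^2 / (2 sigma^2))

where `p0` is the detection probability for a trap placed exactly at the
activity center and `sigma` (m) is the spatial scale of movement. Activity
centers follow a homogeneous Poisson point process with intensity `D` over a
discretized state-space `S` (pixel side 1.5 km, traps buffered by 15 km by
default). Marginalizing centers over the pixels `g` with area `a` gives the
session likelihood

    -log L = - sum_i log( sum_g D a P(y_i | s_g) ) + sum_g D a pdot(s_g) + log(n!)

with `pdot(s)` the probability of at least one detection. Several sessions
can share `(p0, sigma)` within sharing groups while each keeps its own
density, which stabilizes estimation when some sessions detect few
individuals. Estimates are by quasi-Newton maximization (density profiled
out analytically), standard errors from the inverse observed information,
and abundance is reported as expected abundance over the state-space,
`N = D * A(S)`, with delta-method SEs.

The nonspatial track drops the spatial information, fits M0 (common
detection probability) and Chao's lower-bound Mh (heterogeneous detection),
and divides abundance by the effective trapping area: the convex hull of the
traps dilated by the mean maximum distance moved (MMDM) or half of it
(HMMDM), `ETA = A + P*w + pi*w^2`.

## Worked example

Simulate a lynx-scale survey — a checkerboard of 91 sites in 2.7-km cells,
13 occasions, `p0 = plogis(-2.34)`, `sigma = exp(8.80)` m, 30 expected
individuals in the buffered state-space — and fit both tracks:

```r
library(scrdens)
traps <- make_checkerboard_traps(13, 14, cell = 2700, n_occasions = 13)
ss    <- build_state_space(traps, buffer = 15000, resolution = 1500)
sim   <- simulate_scr(traps, ss, p0 = plogis(-2.34), sigma = exp(8.80),
                      density = 30 / (ss$n_pixels * ss$pixel_area),
                      session_id = "survey1", seed = 2026)
fit <- fit_scr(list(traps = sim$traps, encounters = sim$encounters),
               statespaces = ss)
summary(fit)
#> Detection / movement (per sharing group):
#>  group p0_logit se_p0_logit log_sigma se_log_sigma      p0 sigma_m
#>      1   -2.491     0.09212      8.86       0.0414 0.07646    7045
#>
#> Abundance / density (per session):
#>  session group  n detections area_km2  N  se_N D_per_100km2   se_D
#>  survey1     1 29        294     4158 36 6.752       0.8659 0.1624
#>
#> log-likelihood -1415.6890; gradient norm 3.73e-04; converged: TRUE
```

The fitted detection scale (`log sigma` 8.86 ± 0.04 against a generating
value of 8.80) and baseline detection (`logit p0` −2.49 ± 0.09 against
−2.34) recover the truth within sampling error; the simulated truth held
`N = 32` activity centers against the estimate 36.0 (SE 6.8). The density
surface sums back to the abundance estimate, and the nonspatial track runs
off the same encounter data:

```r
sum(density_surface(fit)$density)   # 36.0047, equals N-hat
fr <- capture_frequencies(sim$encounters)
fit_m0(fr)
#> M0: N-hat = 29.00 (SE 0.92), p-hat = 0.4934 (SE 0.0302), n = 29, K = 13
fit_mh_chao(fr)
#> Mh (Chao lower bound): N-hat = 31.67 (SE 3.49), n = 29, f1 = 4, f2 = 3
eta <- eta_from_mmdm(sim$encounters, sim$traps)
nonspatial_density(fit_m0(fr)$N, fit_m0(fr)$se_N, eta)$density
#> 0.54  (lynx per 100 km2; SCR gave 0.87)
```

`run_pipeline()` (or `inst/scripts/scrdens-pipeline.R` from a shell) chains
reading, fitting, the nonspatial estimators and report writing for a YAML
run configuration, writing a per-session summary CSV, density rasters
(ESRI ASCII + CSV) and a JSON run log.

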