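---
title: "From archival light to migratory reaction norms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From archival light to migratory reaction norms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wheatrack)
```

wheatrack implements the full analysis chain used in light-level geolocation
studies of small migratory songbirds: from the raw light record of an
archival tag to daily positions, a stopover/travel schedule, environmental
annotation, and mixed-effects "reaction-norm" models of daily departure
probability and travel speed. Because real geolocator deployments cannot be
redistributed, the package carries a synthetic-world generator whose outputs
have known truth; every stage of the pipeline is tested by recovery of that
truth.

## The measurement model

An archival tag records ambient light every few minutes. At a fixed
threshold (1.35 in device units) the light curve crosses upward at dawn
(a sunrise event) and downward at dusk (a sunset event). Clock times of
those crossings determine position: longitude from the observed solar noon
(midpoint of sunrise and sunset, against 12:00 UTC corrected by the
equation of time) and latitude from day length given the solar declination,
both evaluated at a calibrated solar zenith angle $z_0$ (the sun's angle
from vertical at which the threshold is crossed; around 96.8 degrees for
this kind of tag and habitat).

Shading of the sensor (vegetation, weather, the bird's own plumage) can
only *delay* the apparent sunrise and *advance* the apparent sunset. The
twilight error in minutes is therefore one-sided and is modelled
log-normal, $\log d \sim N(\mu, \sigma^2)$ with defaults $\mu = 2.2$,
$\sigma = 1.0$ (median delay 9 minutes, 95th percentile about 47).

Solar geometry uses the Meeus-series ephemeris (declination, equation of
time; accuracy about 0.01 degrees over 1950--2050). An algorithmically
distinct almanac (Michalsky's) ships alongside as a cross-check oracle; the
two agree within 0.01 degrees, far below the 1-sigma calibration
uncertainty of any tag. Both are geometric: atmospheric refraction is
absorbed into the calibrated zenith angle, as is standard for the threshold
method.

### Calibrating the zenith angle and the twilight model

At the deployment site the true position is known, so every recorded
twilight yields an error sample. The one-sidedness is essential: if the
zenith angle were chosen so that the *median* predicted twilight matches
the observations, the error sample would be centred at zero and could not
estimate the log-normal shading parameters. Instead `calibrate_zenith()`
anchors the *smallest* observed error: $z_0$ is solved so that the minimum
error equals the expected minimum of $n$ draws from the fitted log-normal
(iterated twice to debias), which reduces exactly to the geometric zenith
in the noise-free limit and keeps the error sample strictly positive so
that log-moments estimate $(\mu, \sigma)$. Errors are floored at 0.1 min
before taking logs (the log-normal density is undefined at zero). A
degenerate, noise-free error sample is detected and flagged rather than
fitted. Calibration requires a site and season where the zenith range is
astronomically attainable; at 65 degrees north the sun stays above
$z = 96.8$ all night until mid-August, and the feasible range is computed
from the data and reported when violated.

### Editing twilights

Following standard practice, twilight events deviating more than 30
minutes from their surrounding events are repaired before any position is
estimated. For each event, the five nearest same-type neighbours define a
robust local trend (repeated-median slope over a doubled context window,
median intercept) in time-of-day space; detrending prevents false flags
during fast longitudinal travel, and the robust slope prevents an outlier
block at the edge of the near window from masquerading as drift. An event
deviating more than the limit from *stable* neighbours (detrended spread
at most the limit) is moved onto the trend and flagged `adjusted`; with
unstable neighbours it is flagged `discarded`. The operation is idempotent
and events at the series ends are left untouched. Under the default
shading model this rule discards roughly 10--15% of twilights — more than
the ~2% reported for field data, because the fitted log-normal has a much
heavier tail than realized shading at an open site; see "What the
generator does and does not emulate".

## Bayesian track refinement

The state is one position per twilight pair (the midday position), the
simplest state space that supports daily locations, inter-day speeds, and
latitude uncertainties. The unnormalized log-posterior of a track
$x_{1:K}$ is

$$\sum_k \log f_{\mathrm{LN}}(e^{rise}_k) + \log f_{\mathrm{LN}}(e^{set}_k)
  + \sum_k \log f_{\Gamma}(v_k) + \sum_k \log w(x_k)$$

with $e^{rise}_k$ the observed-minus-predicted sunrise delay (minutes,
positive or the density is zero), $e^{set}_k$ the predicted-minus-observed
sunset advance, $v_k$ the great-circle speed (km/h) between consecutive
states over the actual elapsed time (about 24 h between midday states),
and $w$ a land/sea mask weight. The movement prior is gamma with shape 0.7
and rate 0.05 (scale 20 km/h, mean 14 km/h): shape below 1 puts the mode
at zero, encoding high probability of staying put and monotonically
decreasing probability of higher speeds, consistent with an airspeed of
roughly 50 km/h on flight nights. (The rate parameterization is the only
reading of "shape 0.7, scale 0.05" under which the prior covers realistic
speeds at all; it is exposed as a configurable rate.) The mask defaults to
land:sea weights of 4:1 — only the ratio matters, and the posterior is
invariant to common rescaling.

Sampling is Metropolis-within-Gibbs with Gaussian proposals, adapted
per-state toward 20--40% acceptance during burn-in and frozen afterwards.
States interact only with their neighbours through the movement prior, so
odd and even days are updated as alternating vectorized half-sweeps (a
valid checkerboard Gibbs scan). Defaults: 2 chains, 5,000 burn-in sweeps,
15,000 kept, thinned by 5; the recovery tests use shorter chains (2,000 /
6,000--8,000) after checking split-chain R-hat below 1.02. Initial
positions come from the threshold method evaluated at a slightly smaller
zenith angle, which makes both twilight errors strictly positive; equinox
gaps are interpolated, and any remaining non-finite state is jittered
locally (the documented re-initialization path).

The sampler was validated against a brute-force evaluation of the same
unnormalized posterior on a fine latitude-longitude lattice for small
problems: marginal means and SDs agree within Monte-Carlo error. A single
twilight pair under the default shading model carries a posterior SD of
roughly 3 degrees of latitude — the information floor that pooling across
stopover days (via the movement prior's spike at zero speed) then reduces.

## Segmenting the schedule

Stopovers and travel days are separated by a changepoint analysis of the
twilight series. A flight night shifts the next day's sunrise *and* sunset
coherently (longitude moves both; latitude moves day length), while
shading noise hits single events. The detector assigns each event the
squared studentized difference from its same-type predecessor, mapped
through its chi-square null distribution: series are first detrended with
a running median (the seasonal drift rate depends on latitude), and the
scale is a local running MAD (twilight noise is heteroscedastic — it
inflates around the equinoxes). A continuous log-scale version of the
probability backs the thresholding rule, because the probability itself
saturates at 1 in double precision for strong changepoints.

Two windowed designs were evaluated first and rejected on synthetic truth:
a plain two-segment mean comparison fires on the smooth seasonal drift
inside perfectly stationary periods (the F statistic is scale-free), and
adding a shared within-window trend goes blind when flights recur every
2--3 days, because every multi-event window then straddles several
changepoints. The minimal-window studentized difference is the only member
of the family that degrades gracefully across both regimes.

Events above the 0.75 quantile of all scores mark movement days; runs of
quiet days form stationary periods, consecutive periods whose mean
positions lie within 200 km merge (iterated to a fixed point, means
duration-weighted), and only then is the 2-day minimum applied — merging
first lets a single falsely marked day inside a stopover be healed rather
than deleting a sub-2-day fragment. Season endpoints follow the
longitude/distance rules of the study design: autumn onset is the start of
the travel run preceding the first stationary site more than 2 degrees of
longitude from the breeding area in the travel direction (or the last day
of the following run if no such site exists); autumn termination is the
first day of the wintering period, generalized as the longest stationary
period away from the breeding area; spring onset uses a 200-km radius
around the wintering ground, and spring termination falls back to the last
estimable location, flagged truncated, when polar daylight ends the track.

Phenology metrics follow directly: total migration distance is the sum of
great-circle legs between consecutive daily positions inside the window
(Earth radius 6371 km throughout), total speed of migration is distance
over duration (an exact identity, tested as such), travel speed is the
overnight displacement into each travel day, and stopover days per
1,000 km divides the stopover count by distance.

### What schedule recovery can and cannot achieve

Under light shading (log-normal(0.5, 0.5); delays of a couple of minutes)
the segmentation recovers about three quarters of multi-day stationary
periods with boundaries within one day, where the residual misses are the
0.75-quantile rule itself (a top-quartile of events cannot cover every
travel day when travel events approach a quarter of all events) and
equinox degeneracy. Under the full fitted twilight model treated as the
true noise process, single flight nights are not identifiable in
principle: the coherent twilight shift of a median flight (about 16
minutes) is the same size as the difference of two independent shading
delays (median about 13 minutes), and the best attainable
single-day classification accuracy measured on the truth tables is about
0.59. Recovery rates at both noise levels are computed, not assumed, in
the test suite, and periods are compared against truth that has been
passed through the same 200-km merge rule — the operational definition
treats sites within 200 km as one site, so sub-200-km overnight hops are
below the method's resolution by definition.

## Environmental annotation

Weather fields live on a regular 2.5-degree, 6-hourly grid (reanalysis
structure): surface air temperature, surface pressure, surface wind,
precipitation rate, and u/v wind at 1000/925/850/700 mbar. Queries are
bilinear in space and linear in time; the four pressure levels are matched
exactly, never interpolated across; queries outside the hull are errors
naming the axis. Precipitation is summed over the seven hourly samples
from 3 h before to 3 h after local sunset ("local sunset" being the
detected sunset event — the quantity the tag itself observes).

Flow assistance toward a preferred direction uses the airspeed
formulation

$$fa = y\cos\theta + \sqrt{z^2 - (y\sin\theta)^2} - z,$$

with $y$ the wind speed, $z$ the airspeed (13 m/s default) and $\theta$
the angle between the direction the wind blows toward
($\mathrm{atan2}(u, v)$, degrees from north) and the initial great-circle
bearing to the goal. When the crosswind exceeds the airspeed the value is
missing, not an error; the best (maximum) of the four pressure levels is
used, missing only if all four are. For travel-speed models the flow is
instead the mean of hourly evaluations along the great-circle path flown
that night, with winds interpolated in space and time.

The bird-day table has one row per day of the migration window: stopover
rows (at their period's mean position) carry the binary departure response
— 1 exactly on the last evening of a stopover — and travel rows (at the
day's own position) carry the realized travel speed, the overnight
displacement into that day. Remaining migration distance is the
great-circle distance to the seasonal destination. Rows with missing flow
assistance are flagged and dropped listwise by the model fits, with the
count reported.

## The statistical layer

Numeric covariates are z-transformed (scalings stored for
back-transformation) and screened for collinearity by iteratively dropping
the largest variance-inflation factor until all fall below 2
($VIF_i = 1/(1 - R_i^2)$, ties dropping the later-listed predictor).
Departure probability is a mixed-effects logistic regression with a
random intercept for deployment year, fitted by maximum likelihood with
adaptive Gauss-Hermite quadrature (15 nodes; exactly one scalar grouping
factor makes this accurate to far below the reporting precision, and the
test suite checks the fitted likelihood against brute-force numerical
integration to 1e-6). Travel speed is a weighted linear mixed model (REML)
on log10 speed with weights equal to the inverse latitude SD of each
day's position. Total speed of migration across bird-seasons is modelled
on the log10 scale against log10 total stopover duration, and against
log10 mean travel speed plus season, with individual as the random factor.
The travel-speed response is log10-transformed: the headline intercept
(about 2.45, i.e. 280 km/night) is only interpretable on that scale, which
resolves the ambiguity in the study design's wording about which variable
the log transform applies to.

Credible intervals come from simulating the joint posterior under
improper flat priors, $p(\beta) \propto 1$ and
$p(\sigma) \propto 1/\sigma$: for gaussian fits $\sigma^2$ is drawn from
its scaled inverse-chi-square distribution and coefficients from a
multivariate normal scaled by the drawn $\sigma$; for binomial fits
coefficients are drawn from the asymptotic normal on the link scale
(no MCMC). The estimate is the median of 2,000 draws, the 95% CrI its
2.5/97.5% quantiles, and an effect is significant when the interval
excludes zero. Overdispersion is summarized by the Pearson scale
parameter; variance-partition (marginal/conditional) R-squared uses
$\pi^2/3$ as the latent-scale residual variance for the logit family.
Effect displays summarize the two interacting covariates into five
quantile categories each, fix everything else at its mean, and suppress
cells outside the jointly observed covariate envelope instead of
extrapolating.

## The synthetic world

The generator provides ground truth at three layers, all bit-reproducible
under a seed.

**Weather.** Deterministic structure — a latitudinal temperature gradient
(-0.45 degC per degree latitude from 25 degC at 10 degrees north), a
seasonal cosine (amplitude 12 degC peaking at day 190), a small diel cycle
in local hour, level-dependent mean zonal flow (2/4/6/10 m/s) — plus
AR(1)-in-time (coefficient 0.8), spatially smoothed Gaussian anomalies,
the cheapest field with nonzero autocorrelation in both axes so that
interpolation is genuinely exercised. Precipitation is Bernoulli-gamma on
a smoothed latent field. With all noise SDs at zero the fields reduce to
the deterministic terms exactly, which several tests exploit. A synthetic
land mask (thresholded smooth blobs, 70% land) feeds the spatial prior.

**Behaviour.** Each evening the bird z-scores its sunset covariates
against fixed reference scalings and departs with probability
$\mathrm{logit}^{-1}(\beta x)$; on flight nights it covers
$10^{\gamma x + \epsilon}$ km ($\epsilon \sim N(0, 0.3)$, capped at 10
flight hours times 50 km/h ground speed) along the great circle toward its
destination. The coefficient defaults are the fitted autumn
departure-probability and travel-speed models of the study system
(intercepts -0.25 and 2.45; temperature, pressure, wind, precipitation,
flow-assistance and remaining-distance terms with their interactions), so
the generator is the truth-generator for exactly the model structure the
statistical layer estimates. The reference scalings and the weather
parameters were chosen once so that simulated seasons reproduce the
observed schedule structure — roughly 70% stopover days, ~280-km flight
nights, about 10 multi-day stopovers per season, arrival within the
season — and were then frozen.

**Light.** Light is a logistic function of solar zenith angle calibrated
so the threshold is crossed exactly at the configured zenith (96.8
degrees), making the threshold method exactly invertible in the noise-free
limit; the 5-minute cadence bounds discretization error at 2.5 minutes.
Per-twilight shading delays warp the time at which the zenith is
evaluated — the morning limb later, the evening limb earlier — so apparent
sunrise is never earlier than true sunrise, apparent sunset never later,
and the apparent day shortens by exactly the sum of the two delays.
Midnight-sun days are emitted saturated and flagged.

**Default scenario.** A meridional autumn migration from Eagle Summit
(65.6 N, 145.4 W) to a wintering site at (12 N, 95 W), about 6,600 km,
August through mid-November. The literal study route (Alaska to eastern
Africa) cannot be reproduced by a great-circle-following agent — that
great circle crosses the polar cap, where August has no twilights — so the
default emulates the route's *structure* (a long meridional descent) and a
second scenario used by the track-recovery tests emulates its first,
zonal, high-latitude leg (Eagle Summit eastward to 55 N, 70 W at 55--65
degrees north, where day length is most informative per degree of
latitude).

**What passing tests do and do not show.** The generator draws shading
delays independently per twilight from the fitted log-normal — the
"fitted model as true noise process" convention. Real shading is lighter
most days and strongly autocorrelated (a bird in the same shaded roost for
a week), which makes real twilight series *easier* to segment and real
tracks somewhat smoother than the synthetic ones; the recovery rates
reported here are therefore conservative in that respect. Conversely the
synthetic world has no clouds, no orography, no tag clock drift, no
device-specific light response, and its weather anomalies are far smoother
than frontal systems; covariate effects estimated from it say nothing
about how well reanalysis data represent the conditions a real bird
experienced.

## Numerical choices and degenerate inputs

* All times are UTC POSIXct internally; serialized ISO-8601. Coordinates
  decimal degrees, longitude in (-180, 180], great circles on a 6371-km
  sphere.
* Threshold crossings are linearly interpolated between samples; the
  threshold-method position is iterated (latitude root-bracketing on the
  day-length equation, longitude correction at -4 min/degree) so the
  midpoint bias from declination drift over long high-latitude days
  cancels; near-equinox day lengths with no root, or only artefactual
  polar roots, return a missing latitude with a diagnostic while longitude
  is still reported.
* Constant-light series (polar day or night) yield an empty twilight set
  with a diagnostic, not an exception.
* Posterior simulation refuses non-positive-definite coefficient
  covariances; model fits fall back to fixed-intercept versions with a
  warning when the grouping factor has fewer than 2 levels; singular
  random effects are retained and reported as SD ~ 0 with a flag.
* Problem sizes in the test-suite recovery studies — 40-day tracks with
  2,000/8,000-sweep chains, 100-replicate coverage studies at a few
  hundred rows each, 500-twilight calibrations, 20-track schedule
  studies — were chosen as the smallest sizes at which the Monte-Carlo
  error of each check sits well below its tolerance.

## Known limitations

* One state per day: sub-daily movement and nocturnal exploratory flights
  are invisible by construction.
* The changepoint detector resolves movement only down to the coherent
  twilight shift it produces; under heavy shading single flight nights
  are unidentifiable (quantified above), and the 0.75-quantile rule caps
  the fraction of days that can ever be marked as travel.
* Calibration assumes the deployment site is known exactly and the tag
  clock is true; clock drift would alias into longitude.
* The statistical layer fits exactly one random intercept; crossed or
  nested random effects, model selection, and spatial autocorrelation
  corrections are out of scope.
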