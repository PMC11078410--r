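---
title: "Adaptive multi-vehicle mapping of patchy phytoplankton blooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multi-vehicle mapping of patchy phytoplankton blooms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomfleet)
```

## The problem

Phytoplankton blooms are patchy in all three spatial dimensions and evolve in
time. A fleet of autonomous underwater vehicles (AUVs) can map chlorophyll-a
fluorescence (CF) adaptively: each vehicle carries a statistical model of the
field, steers toward regions of high predicted concentration and high
uncertainty while avoiding its fleet-mates, and exchanges data with the rest
of the fleet through a shore-side operator hub over a satellite link whose
messages are limited to 340 bytes. `bloomfleet` implements the full pipeline:
the shared spatial grid, the on-board model, the waypoint planner, the wire
codec and hub, a mission simulator with a synthetic bloom field, and the
geostatistical checks used to validate the model's assumptions.

## The on-board model

CF in bloom conditions is heavy-tailed and strictly positive; its logarithm
is approximately Gaussian. The model is therefore a *log-Gaussian process*:
measurements $y$ are log-transformed and centred,
$z = \ln y - m_{GP}$ with $m_{GP} = \overline{\ln y}$, and a Gaussian
process is fitted to $z$ over the four coordinates $s = (x, y, z_{depth},
\tau)$. The kernel is an anisotropic squared exponential,

$$k(s, s') = \sigma_c^2 \exp\!\Big(-\tfrac12 \sum_d \big((s_d - s'_d)/M_d\big)^2\Big),$$

with per-axis de-correlation lengths $M = (M_x, M_y, M_z, M_\tau)$. Note the
lag is *divided* by the length scale, so the covariance falls to
$\sigma_c^2 e^{-1/2}$ at one de-correlation length — the property that gives
the parameter its name. Predictions use the standard GP equations with a
nugget $\sigma_n^2$ added to the training diagonal only; the reported
predictive variance is that of the latent field. Because prediction time
$\tau_{now}$ enters every kernel evaluation, the system is rebuilt and
solved in full at each planning step rather than ingesting data
incrementally.

Log-space moments are mapped back to the fluorescence scale with the
log-normal moment identities

$$\hat y = e^{\bar f_* + \mathrm{cov}(f_*)/2}, \qquad
  \Sigma_y^2 = \hat y^2\,(e^{\mathrm{cov}(f_*)} - 1),$$

which make the predictive variance grow with the predicted mean — the
property that lets a variance-seeking planner double as a maxima-seeker.

Defaults follow the field-trial operator inputs: $M = (600, 600, 3)$ m and
$M_\tau = 10^4$ s, $\sigma_c = 1.6$, $\sigma_n = 0.7$. The pair
$(\sigma_c, \sigma_n)$ is interpreted as *standard deviations* and squared
where variances are required; the accompanying text calls 0.7 a nugget
standard deviation, and an `as_variance` switch covers the other reading.

Two choices here were genuinely open:

* **$m_{GP}$ is recomputed from the current training set at every
  evaluation**, consistent with full re-evaluation per iteration. Under
  maxima-seeking sampling the training set over-represents high values, so
  $m_{GP}$ drifts upward late in long missions and unvisited cells revert
  to a biased prior. This is a real property of the method, visible in the
  simulator's RMSE curves; pinning $m_{GP}$ to the pilot-survey value would
  trade it for staleness.
* **Zero readings are clipped** to a configurable floor (default
  0.01 µg/L) before the log; real fluorometers emit zeros. Negative
  readings are rejected as errors.

## Grid segmentation and data exchange

Raw measurements arrive at high rate; for both computational feasibility and
bandwidth they are segmented into a shared $n_x \times n_y \times n_z$ grid.
A cell receiving new measurements takes the *mean of the new batch only* —
any previous value is discarded, on the argument that temporal decay makes
stale data irrelevant next to fresh data from the same place. Untouched
cells keep their data. The cell timestamp is the mean time of the
contributing batch (the convention had to be fixed; the mean is the least
surprising choice for an averaged value). The linear cell index runs
x-fastest (`id = ix + n_x (iy + n_y iz)`, 0-based); since every agent shares
the grid, the ordering is part of the wire protocol.

Messages carry a 10-byte header (message ID, vehicle ID, two IEEE singles
for the surface position) followed by fixed-width cell records of
$n_d = 3 + n_c$ bytes: one quantized byte per channel, a 16-bit cell
number, and one time byte. With 20 bytes of driver overhead inside the
340-byte satellite limit, up to $\lfloor 320 / n_d \rfloor$ records fit
(80 for a single channel). Value bytes quantize $\ln v$ linearly over a
configured range (default 0.01–100 µg/L) — a log grid spends its 256 codes
where a log-normal field lives; time bytes count minutes from the mission
epoch, saturating at 255. All multi-byte fields are big-endian. The
operator hub keeps the newest record per (vehicle, cell), tracks what each
vehicle has already received, and replies with the newest not-yet-delivered
records from the rest of the fleet plus everyone's last surface positions
(the position message is small and not compressed). One caveat is
documented rather than fixed: record times travel at one-minute resolution,
so two vehicles sampling the same cell within the same minute can resolve
the tie differently until one of them produces a newer record.

## The planner

Each vehicle starts with a *pilot survey*: fleet member $n_v$ of $N_v$
crosses the volume at $x_v = V_x (2 n_v + 1) / (2 N_v)$ from $y = 0$ to
$y = V_y$, undulating between the surface and the bottom of the volume
(default two full cycles per crossing — the cadence is not specified by the
method, and two cycles samples every depth layer twice per transect).

Afterwards the vehicle is myopic: from its position it generates
$3 n_\theta$ candidate waypoints on a circle of radius $r$ at three depth
layers $\pm z_d$ (defaults: $n_\theta = 8$, $r$ = one horizontal cell
extent, $z_d$ = one vertical cell extent), screens out candidates outside
the volume, and picks the candidate maximising

$$U = k_\mu \hat y + k_\sigma \Sigma_y^2 - \sum_{k \ne v} (k_l / d_k)^2,$$

where $d_k$ is the *horizontal* distance to vehicle $k$'s last known
position. The separation term is the only reading of the published
expression that is unitless, decays with distance, and makes $k_l$ (300 m
by default) a characteristic standoff radius where the penalty equals one.
A candidate exactly on top of another vehicle scores $-\infty$. Exact ties
break to the lowest candidate index, making the planner deterministic.
Stale fleet positions are used as-is — they are what the hub last reported.

Whether $\hat y$ and $\Sigma_y^2$ are evaluated at the candidate's exact 3D
point or at its grid cell center was genuinely open; this package evaluates
at the **cell center**. The planner's currency is grid cells — cells are
what gets sampled, averaged and exchanged — and the alternative is
demonstrably pathological here: candidates step vertically in whole cell
heights, so a vehicle that has surfaced generates candidates lying exactly
on cell *boundary* planes forever, and with $M_z = 3$ m against 10 m cells
those planes are 1.7 vertical length scales from every (cell-center)
training point. Exact-point evaluation therefore reports near-prior
variance on the boundary planes no matter how well their cells are
sampled, and variance-seeking fleets end up camped on them (most visibly
at the surface). Cell-center evaluation ties the utility to the state of
the cell the candidate would actually sample.

## The simulator and its stated world

The synthetic field is built in log space as the sum of a smooth vertical
profile with a subsurface maximum (a Gaussian bump centred at 30 m depth
with 12 m width — the dominant structure of a stratified spring bloom) and
a horizontal stationary Gaussian random field with squared-exponential
covariance (correlation length 300 m on the reduced volume), drawn with
random Fourier features so it is evaluable anywhere. The two terms are
standardized over the grid-cell centers and mixed 50/50 in variance, then
scaled so the log field has exactly mean 0 and standard deviation 1.6 at
the cell centers (the process scale used throughout). The field is the
exponential of this surface: positive, log-normally distributed, patchy.
Sensor readings multiply the true value by $e^\varepsilon$,
$\varepsilon \sim N(0, \sigma_n^2)$ — the nugget of the on-board model.

What the generator does *not* emulate: fine-scale vertical heterogeneity
(the vertical structure is a deterministic profile, so the marginal log
distribution is a profile-plus-Gaussian mixture rather than exactly
normal), advection or temporal evolution (the truth field is static, as in
the reference simulation study; a drift mode exists but nothing depends on
it), navigation error, or sensor quenching near the surface. A green
simulation test therefore establishes that the *method* converges on a
world obeying its own assumptions — not that it would on any real bloom.

The reduced default experiment uses a 1000 × 1000 × 50 m volume with a
10 × 10 × 5 grid, 10 s ticks, 1.2 m/s vehicles, 600 s exchange periods and
a 3600 s mission, sized so a four-vehicle mission runs in seconds on one
CPU. Surfacing is instantaneous: the vehicle teleports to the surface,
exchanges, and resumes — so the kinematic bound (per-tick displacement at
most speed × tick) holds horizontally everywhere and in 3D away from
exchange events.

**RMSE scale and mission length.** The headline convergence statement is
that with four vehicles the model error converges to the nugget standard
deviation 0.7 — a *log-space* quantity. RMSE is therefore computed between
log-space predictive means and log truth at all cell centers (the
fluorescence-scale RMSE is computed and exported alongside, but has the
units of µg/L and no natural 0.7 floor). Because $M_\tau = 10^4$ s makes
the model deliberately forget, the RMSE curve on a static field dips to a
plateau (roughly 2000–5000 s for multi-vehicle fleets at this scale) and
then drifts upward once the data age approaches $M_\tau$ and the biased
$m_{GP}$ dominates unvisited cells. The default mission length (3600 s)
measures the plateau; running several times longer would measure the
forgetting regime instead, which is a statement about mission scheduling,
not about model quality. The single-vehicle configuration converges more
slowly (consistent with the reference study's single-vehicle convergence at
three times this volume scale) and has typically not reached its own
plateau by 3600 s, which is precisely why the fleet comparison favours
more vehicles, most strongly from one to two.

## Geostatistical validation

`empirical_variogram()` computes the classical semivariance over horizontal
lag bins (100 m bins to 2000 m by default, mirroring the field analysis;
time is ignored because missions are short). `fit_spherical()` fits
$\gamma(h) = c_0 + c\,(1.5 h/a - 0.5 (h/a)^3)$ (capped beyond the range
$a$) by least squares weighted with per-bin pair counts, optimizing on the
log scale for positivity with a quasi-Newton polish; a fit whose partial
sill is negligible flags the range as unidentifiable (pure nugget). One
honest limitation: when the underlying field has squared-exponential
structure, pair-count weighting lets the heavy mid-lag bins dominate and
the fitted nugget is not a reliable estimate of the noise floor — the
short-lag empirical semivariance of dense along-track data is, and that is
what the test suite checks against $\sigma_n^2$. Full parameter recovery
(within 25% over seeds) is demonstrated where the generating covariance is
itself spherical.

`best_fit()` fits log-normal, gamma, beta, Burr XII and normal candidates
by maximum likelihood and scores them by AIC and by the SSE between each
fitted density and a 50-bin density-normalized histogram. The fitted
density is *bin-averaged through its CDF* rather than evaluated at bin
midpoints: midpoint evaluation systematically mis-scores sharply peaked
long-tailed densities and can invert close rankings. The beta candidate is
fitted on values rescaled into (0,1) by the sample maximum with the
Jacobian folded into its likelihood, so AICs remain comparable; the Burr
density and CDF are implemented in-package (no installed package provides
them). On bloom-like data log-normal decisively beats gamma, beta and
normal; the three-parameter Burr family overlaps the log-normal shape and
can tie on SSE (in the reference field data it won on AIC), so the
pipeline checks require log-normal to be in the top two and strictly ahead
of the other three.

## A short tour

```{r tour, eval = FALSE}
config <- default_mission_config()        # reduced-scale stated world
field <- config_truth_field(config, seed = 1)
mission <- run_mission(4, field, config, seed = 2)
terminal_rmse(mission)                    # log-space and fluorescence RMSE
curve <- rmse_curve(mission)              # per vehicle + fleet average

# operator-style profile query at the center of the volume
cells <- grid_cells(segment_measurements(mission$measurements[, -1],
                                         grid_state(config$volume)))
train <- lgp_training(cells[, c("x", "y", "z", "time")], cells$chan1,
                      config$hyperparams)
profile <- gp_predict(train, data.frame(x = 500, y = 500,
                                        z = c(5, 15, 25, 35, 45)),
                      tau_now = 3600, config$hyperparams)
```

## Numerical choices and limitations

* GP solves use a Cholesky factorization; predictive variances are clipped
  into $[0, \sigma_c^2]$ against roundoff. Duplicate (location, time)
  training rows are merged by averaging before the solve.
* The geodetic conversion is a flat-earth tangent projection about the
  volume origin; over the few-kilometer operational areas the error is far
  below a cell extent. The volume frame is right-handed with x rotated
  $\theta$ counter-clockwise from east and depth positive down; the
  orientation convention is documented rather than inferred — with
  $\theta = -45°$ a point due east of the origin lands at equal positive
  x and y.
* Grid cells are half-open except the last cell per axis, so the far faces
  of the volume map to valid cells.
* Hyperparameter estimation is out of scope by design: values come from the
  operator configuration, and the variogram tools exist to sanity-check
  them, not to refit them automatically.
* The planner is single-step myopic; with strong variance weights and a
  dominant hotspot all vehicles can converge on the same patch late in a
  mission, which is part of why long-horizon RMSE drifts (see above).
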