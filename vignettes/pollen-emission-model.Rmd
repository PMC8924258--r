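---
title: "The pollen emission model: equations, calibration and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pollen emission model: equations, calibration and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollensim)
```

## The model

`pollensim` simulates the daily emission flux of wind-dispersed pollen for
individual taxa on a regular grid. The flux (grains m⁻² d⁻¹) at a cell on
day *t* is a product of independent factors:

$$E_{\mathrm{pol}}(t) = A \cdot \mathrm{pf}_{\mathrm{annual}} \cdot
\gamma_{\mathrm{phen}}(t) \cdot \gamma_{\mathrm{precip}}(t) \cdot
\gamma_{\mathrm{CO_2}}$$

* **A** — the taxon's vegetated land-cover fraction (m² m⁻²) at the cell.
* **γ_phen** — a Gaussian in day of year,
  $\gamma_{\mathrm{phen}}(t) = e^{-(t-\mu)^2 / 2\sigma^2}$, with mean
  $\mu = (\mathrm{sDOY}+\mathrm{eDOY})/2$ and width
  $\sigma = (\mathrm{eDOY}-\mathrm{sDOY})/a$. The season start and end days
  are linear in the previous-year annual average temperature (PYAAT):
  $\mathrm{sDOY} = m_{\mathrm{sDOY}} \cdot \mathrm{PYAAT} + b_{\mathrm{sDOY}}$,
  and likewise for eDOY. PYAAT is the sole climatic predictor: pollen grains
  form from photosynthates accumulated the year before flowering. With the
  default width divisor $a = 3$, the weight at both season boundaries is
  $e^{-a^2/8} = e^{-1.125} \approx 0.3247$ of the peak, for any season.
* **pf_annual** — a daily amplitude carrying the annual production. The
  annual production scale is
  $S = \exp(m_{\mathrm{prod}} \cdot \mathrm{PYAAT} + b_{\mathrm{prod}}) /
  P_{\mathrm{norm}} \times P_{\mathrm{annual}}$, where $P_{\mathrm{annual}}$
  (grains m⁻² yr⁻¹) is the literature annual production and
  $P_{\mathrm{norm}}$ is the predicted count at a reference historical
  temperature, so that $S = P_{\mathrm{annual}}$ exactly at the reference
  climate.
* **γ_precip** — a wet-day switch: days whose precipitation strictly exceeds
  5 mm d⁻¹ emit nothing (scavenging and suppressed release); equality at the
  threshold keeps the day.
* **γ_CO₂** — 1 normally; 2 in the doubled-production sensitivity mode
  representing CO₂ fertilization at end-of-century concentrations.

### From annual production to a daily amplitude

The production scale $S$ has annual units while the emission flux is daily.
We define the amplitude by normalizing with the in-year sum of the seasonal
weights,

$$\mathrm{pf}_{\mathrm{annual}} = S \Big/ \sum_{t=1}^{365}
\gamma_{\mathrm{phen}}(t),$$

so that in the absence of precipitation the annual emission sum per cell is
exactly $A \cdot S \cdot \gamma_{\mathrm{CO_2}}$, independent of the season's
placement or width. This makes a structural statement exact: phenology
shifts redistribute pollen within the year — flattening the curve when the
season lengthens, sharpening it when the season contracts — but do not
change the integrated annual total. That invariant is asserted to relative
1e−9 in the test suite. Because the normalizing sum runs over the 365 days
actually simulated, seasons whose Gaussian tails extend past the year edges
are clipped *and* remain conservative: the clipped tail mass is
redistributed into the year rather than lost.

### Numerical choices

* **Full-year Gaussian, no truncation.** γ_phen is evaluated on all 365
  days; sDOY/eDOY only set μ and σ. Truncating outside the season window
  would discard ~7 % of the mass (at a = 3) and break the boundary identity
  above; the un-truncated Gaussian is the stated form of the model.
* **Strict threshold.** "Exceeds 5 mm d⁻¹" is read strictly: γ_precip = 0
  iff pr > 5.0. On continuous synthetic precipitation the equality case has
  measure zero, so the reading is inconsequential in practice but fixed for
  reproducibility.
* **Real-valued dates.** sDOY/eDOY are kept as reals throughout the
  analysis; rounding to whole days would quantize away the small shifts that
  distinguish nearby warming scenarios.
* **365-day no-leap calendar** everywhere, matching climate-model
  convention and avoiding leap-year branching. DOY ∈ {1, …, 365}.
* **Degenerate seasons are masked, not fatal.** A cell-year where the
  regressions give eDOY ≤ sDOY is set to `NA`, counted, and reported via a
  message; a continental run is not aborted by a few failing cells. The
  Morris screen inherits this policy: design rows whose output is missing
  drop the affected elementary effects rather than imputing them.
* **Temperature is Kelvin throughout**, including the regression slopes
  (d K⁻¹), so warming offsets are applied without unit conversion.

## The synthetic data generator

Real applications of the model drive it with downscaled climate-model daily
fields, survey-based land cover and multi-decade station pollen counts. The
generator replaces these with transparent statistical stand-ins so every
downstream stage is testable:

* **Climate** — daily temperature is a linear latitudinal gradient
  (−0.45 K per degree north of the domain mid-latitude around a 285 K mean),
  a sinusoidal seasonal cycle (±12 K, peaking mid-July), the scenario
  warming offset, a per-member offset, an interannual offset (sd 0.3 K) and
  daily white noise (sd 2 K). Precipitation is an independent two-state
  process: wet days with probability 0.3 and gamma-distributed intensities
  (shape 0.7, mean 4 mm d⁻¹), so a realistic minority of days crosses the
  5 mm threshold; the wet-day probability is configurable so the switch can
  be exercised both rarely and frequently. All noise is seeded from the
  user's seed and the member index only — two scenarios differing only in
  their warming offset share identical noise, which makes scenario
  differences exactly additive and lets tests assert, e.g., that a +4.5 K
  offset shifts season starts exactly 2.25 times as far as +2 K.
* **Ensembles** — members sit on a deterministic offset ladder spanning
  ±`member_spread` K with member-specific noise streams, so ensemble
  min/max/sd are reproducible.
* **Land cover** — per-taxon fractions are bilinear upsamplings of a coarse
  uniform random surface, giving smooth patches (so regional averages are
  non-degenerate) with per-taxon values capped at 0.9/n_taxa, hence cell
  sums ≤ 0.9 by construction. The spatial covariance of real vegetation maps
  is not known to the model and the smoothness scale here is a free choice,
  fixed in the config defaults.
* **Taxon parameters** — 15 phenotypes covering the 13 prevalent
  wind-pollinated North American taxa, with *Ulmus* split into spring and
  late-flowering phenotypes and Poaceae into C3/C4 grasses. The slope
  structure encodes the three observed warming-response regimes: 11 spring
  taxa with sDOY more temperature-sensitive than eDOY (earlier, longer
  seasons), *Betula* with exactly equal slopes (uniform earlier shift,
  duration unchanged — exact by construction, not approximately), and three
  short-day taxa (*Ambrosia*, C4 Poaceae, late *Ulmus*) with positive slopes
  and eDOY more sensitive (later, longer seasons). Ten of fifteen
  production slopes are positive (production increases with warming), five
  negative (*Acer*, *Betula*, *Fraxinus*, *Populus*, Pinaceae). The *Alnus*
  row uses a Pacific-Northwest reference temperature for P_norm, mirroring
  its restricted range. Magnitudes (seasons of 60–90 days between DOY 40 and
  300, productions of 10⁵–10⁶ grains m⁻² yr⁻¹, |m_prod| of 0.03–0.12 K⁻¹)
  are chosen to be representative of aerobiological survey values.
* **Pseudo-observations** — station-level (sDOY, eDOY, annual count) tuples
  are the generating lines plus Gaussian noise (defaults: 5 d on dates,
  0.3 natural-log units on counts), with station PYAAT taken from the
  synthetic climate at the station cell. Zero noise puts observations
  exactly on the truth, which is what makes exact parameter recovery a
  meaningful calibration test.

What the generator does **not** emulate: spatially correlated storm
systems, orography, coastlines and land masks, drought–production coupling,
observation gaps and station relocation biases, or the inter-model
structural spread of a real climate ensemble (members differ only by offset
and noise). Passing tests therefore demonstrate the correctness of the
machinery and its invariants, not skill against real pollen counts.

## Calibration

Per taxon, station-years are pooled (no station effects — the observation
network is treated as sampling one regional relationship) and three
ordinary-least-squares regressions are fitted: sDOY on PYAAT, eDOY on
PYAAT, and ln(annual count) on PYAAT. Natural log is used for production,
consistent with the exponential in the production scale. Confidence
intervals and the two-sided slope test come from classical OLS theory
(t-based); resampling intervals would also be defensible but the classical
choice matches the plain-regression formulation and is exactly testable:
with date noise of 5 d at n = 50, the 95 % slope interval covers the truth
in 93–97 % of 200 replicates. P_norm is computed from the fitted production
line at the reference temperature (domain historical mean; PNW mean for the
*Alnus* analog), which makes the production scale cancel to exactly
P_annual at the reference climate. P_annual and the width divisor *a* are
not identifiable from count observations and are carried from the
literature table.

## Projection diagnostics

Season metrics are computed per year from each year's PYAAT and then
averaged over the 20-year period (the period mean of yearly dates, not the
dates of the period-mean temperature — equivalent under linear phenology,
but the former generalizes). The maximum daily emission E_pol,max is the
maximum of the day-of-year climatology (the period-average emission curve),
not the mean of per-year maxima: the former is the quantity shown by
period-average time series and is less sensitive to single wet days. Both
alternatives are one argument away in the code.

Warming-response categories compare historical and future season metrics:
Category 1 (Δs < 0, Δe < 0, duration increase beyond tolerance), Category 2
(both earlier, |Δduration| within tolerance), Category 3 (Δs > 0, Δe > 0,
longer). The tolerance defaults to 2 days at region scale — wide enough
that realistic noise does not promote the exact-Betula case into Category
1, narrow enough to separate genuine asymmetric shifts; it is an explicit
argument.

Regional aggregation uses five fixed boxes (NE, SE, MT, CA, PNW) tiling
25–48° N × 70–125° W without overlap (CA/PNW split at 40° N), with
cosine-latitude area weighting by default (equal weighting available);
whether observational practice area-weights such averages is ambiguous, so
the choice is explicit and configurable. Ensemble statistics are evenly
weighted across members. Taxon fields aggregate to four plant functional
types (DBL: the nine deciduous genera; ENL: Cupressaceae + Pinaceae; GRA:
C3 + C4 Poaceae; RAG: *Ambrosia*) by daily summation, which conserves the
total by construction. The overlap diagnostic integrates
$\sum_t \min(c_i(t), c_j(t))$ over pairs of intra-PFT climatology curves to
label phenological convergence (overlap grows under warming) or divergence.

## Morris sensitivity screen

Nine parameters are screened per taxon: P_annual, the four phenology
coefficients, the two production coefficients, P_norm and *a*. Ranges for
regression coefficients are their 95 % CIs; P_annual takes literature
bounds; P_norm's bounds are the extremes of exp(m·T_ref + b) over the four
(m_prod, b_prod) CI corners; *a* spans 3 ± 0.2. The design uses p random
one-at-a-time trajectories on a 4-level unit-hypercube grid with step
Δ = levels/(2(levels−1)) = 2/3 (the standard Morris grid; the trajectory
count is the only setting the screen's size formula fixes — N = p(k+1),
so p = 100 gives exactly 1000 runs at k = 9). Elementary effects are
computed on unit-scaled coordinates (so μ* is comparable across parameters
with different physical units) with the signed step in the denominator, so
a linear response yields the same effect regardless of move direction; μ*
is the mean absolute effect, σ the sample (n−1) standard deviation, and
ranks are descending by μ* (ties: larger σ, then parameter order). Each
screened model run simulates a single year and reports the domain-average
E_pol,max.

A structural consequence worth knowing: because regression intercepts are
referenced to PYAAT = 0 K, their 95 % CIs are wide at any realistic sample
size, and because Morris perturbs (m_prod, b_prod, P_norm) independently,
the production exponent can swing by several natural-log units across the
design. The production-related parameters (P_annual, P_norm, m_prod,
b_prod) therefore dominate the μ* ranking on the default synthetic
configuration — production magnitude parameters on top, phenology
parameters below — and degenerate-season rows induced by wide phenology
intercept ranges are dropped from the effect statistics rather than
imputed.

## Problem sizes

The package's own test and example runs use desk-scale settings chosen for
interactive turnaround: 6×8 to 20×30 cell grids, 2–20-year spans, 2–3
ensemble members, 5 stations, and Morris screens of 4–30 trajectories
(the size formula and oracle tests cover p = 100 designs directly). All
sizes are plain arguments; nothing in the implementation is specific to
these values.

## Known limitations

* No atmospheric transport, dispersion or deposition — the output is an
  emission flux at the surface, not an airborne concentration; exposure
  interpretation requires coupling to a transport model.
* No meteorological drivers beyond temperature and precipitation (no wind,
  humidity or boundary-layer effects), and no drought limitation of
  production.
* Phenology is linear in PYAAT by construction; chill-hour or degree-day
  formulations are out of scope.
* The CO₂ response is a single global doubling switch, not a
  concentration–response curve.
* Synthetic precipitation is spatially independent; regional wet-day
  statistics are controlled only through the occurrence probability and
  intensity distribution.
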