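---
title: "Scoring and forecasting the marginal value of citizen-science checklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and forecasting the marginal value of citizen-science checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Semi-structured citizen-science bird records (eBird-style "checklists" — a
complete list of the species an observer identified at given coordinates and
time, with effort fields) are the largest source of data for estimating
species population trends, but observers sample where and when they please.
The result is heavy redundancy at famous "hotspots" and long gaps elsewhere.
Not every checklist teaches a trend model the same amount: a list from a
cell unvisited for three years can move a trend estimate far more than the
thousandth list from the same park in the same month.

`samplingvalue` makes that intuition quantitative and then predictive:

1. **Score the past.** Fit one presence/absence trend model per species and
   measure, for every checklist and species, how much the *trend
   coefficient* would change if that checklist were deleted (dfBeta). A
   checklist's *marginal value* is the sum of those absolute changes across
   species.
2. **Explain the scores.** Regress (log) marginal value on dynamic
   covariates describing each grid cell's *sampling history* at the moment
   the checklist happened.
3. **Forecast.** Use the fitted regression to predict, for every cell and
   every day, the expected marginal value of a hypothetical checklist —
   a daily map of where sampling would be most informative.

## The trend model

For each species $s$ with enough observations, presence/absence $y_{cs}$ on
checklist $c$ is modelled as a binomial GLM (logit link) fitted by IRLS:

$$\operatorname{logit} P(y_{cs}=1) = \alpha_s + \beta_s\,\mathrm{day}_c
  + \gamma_{s,\mathrm{county}(c)} + \log L_c ,$$

where $\mathrm{day}_c$ counts integer days since a configurable origin,
county is a categorical spatial term (reference level = first sorted
county), and $\log L_c$ — the log of the checklist's *list length* (number
of species reported) — enters as an offset. List length is the standard
proxy for observer effort in complete-checklist data; the offset lives on
the linear-predictor scale because that is the only dimensionally coherent
place for it (a configuration switch fits list length as a free covariate
instead). Zeros are inferred by zero-filling, which is valid only for
complete checklists — the reader refuses incomplete ones.

Checklists first pass the usual quality filters (each strict, in this
attribution order): complete lists only; diurnal start times (default
[05:00, 20:00), configurable — a solar-elevation computation would add a
dependency for marginal benefit); duration strictly between 5 and
240 minutes; travelling distance < 5 km *or* survey area < 500 ha
(stationary lists pass); and more than four species, short lists usually
being targeted searches. "More than four" is read strictly (a
four-species list is removed). Checklists lacking a duration are removed
by the duration rule; checklists lacking a start time are removed while
the diurnal rule is active. Species enter the modelled set with more than
50 observations, optionally intersected with an allow-list (e.g.
terrestrial species); without an allow-list the taxonomy rule is skipped
with a logged note.

Fits that fail IRLS convergence, sit on the boundary, or show numerical
separation are flagged and excluded downstream (transparent and logged;
penalised fits would change the influence calculus silently). Degenerate
responses (a species present on every checklist or none) are flagged
without fitting.

## The influence calculus

The change in one coefficient from deleting observation $i$ is approximated
by the standard one-step formula on the weighted design at convergence:

$$\mathrm{dfBeta}_i \;=\; \hat\beta - \hat\beta_{(i)} \;=\;
  \frac{(X'WX)^{-1} x_i\, w_i r_i}{1 - h_i},$$

with $W$ the IRLS weights, $r_i$ the working residual and $h_i$ the hat
diagonal. For a Gaussian linear model this *equals* the exact leave-one-out
refit difference (a theorem — the test suite asserts it to $10^{-10}$ on a
five-point dataset); for the logistic fits it is the usual one-step
approximation, which the suite shows correlates with exact refits at
$r > 0.99$ per species. The sign convention is "full-data minus deleted":
positive means removing the checklist would lower the coefficient.

Design notes:

- **Raw, not standardized.** The default dfBeta is the raw coefficient
  change; a `standardized = TRUE` option divides by the coefficient SE.
  Raw values are what the formula above defines unambiguously, and the
  summed-absolute-value statistic uses them.
- **Absences count.** Under zero-filling a non-detection is an observation
  in every species' model, so failing to see a species produces a dfBeta
  automatically — often a large one for a declining species.
- **Pathology containment.** Entries with $h_i \approx 1$ are non-finite in
  the one-step form; they are flagged and contribute zero to the marginal
  sum, so one pathological species cannot poison a checklist's value.
- Cook's distance is deliberately not offered: trend detection cares about
  one coefficient, not the whole parameter vector.

The per-checklist **marginal value** is
$v_c = \sum_s |\mathrm{dfBeta}_{cs}|$ over converged species. It shrinks
roughly as checklists accumulate (each observation matters less once a
trend is well determined), a property the tests assert on replicate means.

## Sampling-history covariates

The region is tiled with square cells ("sites") at several grains — the
grain parameter is the cell **side** in km (default 5, 10, 25, 50). The
reported statistics this package is modelled on are only consistent with
side lengths, not areas; an area reading would make the finest "5 km²"
cells ~2.2 km across, incompatible with nearest-neighbour distances of up
to ~20 km at that grain. Points are assigned to cells with the half-open
convention $[x_0, x_1) \times [y_0, y_1)$, so boundary points are
deterministic. All distances are centroid-to-centroid Euclidean on a
projected plane (an equirectangular local projection is built in; synthetic
worlds are natively planar).

For every cell and day $d$, seven parameters are computed **causally** —
from checklists strictly before $d$, never after (a property test appends
future checklists and asserts bit-identical history):

1. ever sampled;
2. distance to the nearest sampled cell (0 for a sampled cell);
3. median sampling interval: median gap between consecutive distinct
   sampled days, floored at 1 when fewer than two sampled days exist (keeps
   the covariate finite; dates are integer days, so real gaps are ≥ 1);
4. the nearest *other* sampled cell's median interval;
5. days since the last sample (≥ 1 by causality);
6. sampling duration: last minus first sampled day (0 for one-day history);
7. number of unique sampled days (several same-day lists count once).

The neighbour fields (`neighbor_dist_km` and its interval) always exclude
the focal cell. This matters: on a value-model training row the focal cell
is by definition being sampled that day, so an including-focal distance is
identically zero and an including-focal neighbour interval is identically
the cell's own — neither could ever act as a covariate. The
including-focal convention survives in `dist_nearest_sampled`, which is
what the unsampled-site semantics need.

## The value model

Training rows are the evaluation year's checklists (default: the final year
of the record — the analysis needs a year for which both the marginal
values and the prior history are known). The response is
$\log v_c$; the covariates are the cell-day parameters (3)–(7) above,
log-transformed and then standardized **with training means and SDs**,
which are stored on the fit and reused verbatim at prediction time.
Standardized coefficients are therefore directly comparable effect sizes.
Fields with a meaningful zero (distances, sampling duration) use
`log1p`; strictly positive fields use `log`. Sampling duration is always
excluded from the model — it tracks the median sampling interval — and the
collinearity screen reports (but does not drop) any other pair with
$|r| > 0.7$.

Two structural degeneracies are handled explicitly rather than fatally,
because they are facts about well-sampled regions, not data errors: once
every cell has been visited, a distance-type covariate can be constant on
the training rows, and a neighbour interval can alias the cell's own.
Constant or aliased covariates are dropped with a warning and recorded on
the fit; the fit aborts only when no informative covariate remains.

Checklists in never-before-sampled cells lack within-cell history, so they
are excluded from the five-covariate model and analysed separately: a
regression of log value on a binary never-sampled indicator, reported per
grain with no multiplicity correction (each grain is its own analysis).
When an evaluation year contains no unsampled-cell checklists — routine at
coarse grains — the test is reported infeasible rather than silently
skipped.

**Daily maps.** For each day, sampled cells get model predictions from
their current parameters; never-sampled cells are imputed with the mean of
the sampled cells' predictions (so imputation is exactly
mean-preserving, which the tests assert); cells hosting several checklists
that day have one of the per-checklist expectations selected uniformly at
random under a supplied seed — the same seed reproduces the map
bit-for-bit. Maps stay on the log scale, the modelling scale; exponentiate
for display.

## The synthetic world

Real eBird extracts are a licensed download, so validation runs on a
simulator whose truth is known. It emulates: complete checklists with
species drawn from logistic occupancy models (linear day trend with
per-species slopes $\sim N(0, 5\times10^{-4})$ per day, i.e. up to roughly
±1 logit over a four-year record; county effects over contiguous Voronoi
county blocks, SD 0.5); hotspot-biased effort (Pareto cell weights,
exponent 1.2 — the top decile of cells draws the majority of checklists);
multi-year uniform date coverage; and realistic effort fields (log-normal
durations around 60 min, exponential travelling distances, normal start
times with naturally nocturnal tails, a few percent incomplete lists).

Effort and list length deserve care. Each checklist draws a *target* list
length $L \sim 5 + \mathrm{Poisson}(10)$; modelled species are detected
with the effort term $\log(L/15)$ in their logit; unmodelled "background"
species (an 80-species pool, mirroring the many real species that never
enter a trend analysis) pad the list up to $L$. Realized list length then
equals $L$ (the clamp at zero background binds with negligible
probability), so the fitted GLM with a $\log(\text{list length})$ offset is
the *exact* conditional model of the data — which is what makes the
parameter-recovery and CI-calibration checks meaningful tests of the
estimator rather than of an accidental misspecification. An `effort_sd`
knob (default 0) adds unexplained observer heterogeneity on top for
robustness studies, deliberately breaking that exactness.

The default world is a 120 km square — matching the regional extent at
which 5–50 km grains are all meaningful (a smaller world collapses to a
single cell at the coarsest grain, where the five-covariate model cannot
exist) — with 3 counties, 20 modelled species, 4 years and 6,000
checklists: large enough for stable GLMs, small enough that the full
pipeline closes in well under a minute.

What the simulator does **not** emulate: weekend and road-proximity biases,
observer skill heterogeneity, detection probabilities varying over the
annual cycle, and taxonomic reporting quirks. Passing tests therefore
validate the estimator and pipeline mechanics, not the behavioural realism
of citizen scientists; effect *magnitudes* on real data will differ.

## Problem sizes used in validation

The test suite fixes its own seeds and sizes: CI calibration uses 200
replicates of a reduced world (1,500 checklists, 10 species), pooling
~2,000 intervals; coverage must land in [0.90, 0.99] and the pooled bias
within 2 Monte-Carlo SEs. The exact-refit dfBeta oracle runs on a
200-checklist, 5-species world (every omission refitted). The null
calibration of the unsampled-site test uses 500 replicates. Causality is
property-tested over 500 random histories. The end-to-end run covers all
four grains of the default world, 365 daily maps each.

## Known limitations

- One trend model family (binomial GLM with list-length offset); the
  leverage framework accepts any model that yields hat values and working
  residuals, but no occupancy/detection variants are provided.
- No spatial autocorrelation terms; counties are the only spatial effect.
- Group (shared) checklists are treated as independent events.
- One-step dfBeta is an approximation for non-Gaussian fits; at extreme
  leverage it deviates from exact refits (entries with $h_i \approx 1$ are
  excluded rather than refitted).
- The median-interval floor of 1 day for single-day histories is a
  modelling convenience; the covariate is not defined there.

## A minimal run

```{r example}
library(samplingvalue)

cfg <- pipeline_config(seed = 1, out_dir = "svrun")
manifest <- run_all(cfg)

# standardized effect sizes at the 5 km grain
readr::read_csv(file.path("svrun", "value_model_grain5.csv"))
# per-grain unsampled-site tests (infeasible where every site was sampled)
readr::read_csv(file.path("svrun", "unsampled_effects.csv"))
# one expected-value map per evaluation day
readr::read_csv(file.path("svrun", "expected_value_maps_grain5.csv"))
```
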