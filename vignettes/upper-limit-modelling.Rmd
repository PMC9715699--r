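---
title: "Modelling upper distribution limits of fish on stream networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling upper distribution limits of fish on stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`streamlimits` predicts the uppermost point of fish occurrence on a
dendritic stream network in two stages: a reach-level presence model,
then network stopping rules that collapse the per-reach probability
field into one discrete upper-limit point per flow path. This vignette
is the package's own account of the science: the model and its
assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, and the numerical decisions taken where the
design was genuinely open.

## The data model

A `StreamNetwork` is a directed tree of short reaches (5–7 m in the
intended use, anything in 0.5–50 m accepted) oriented downstream toward
a single outlet. Each reach carries a length, a representative
(midpoint) elevation, an incremental drainage area, and free-form
category and block labels. Key conventions:

* **Orientation.** `from_node` is the upstream end; a confluence is a
  node receiving two or more reaches. Exactly one reach leaves every
  node, so braided or looped channels are out of scope.
* **Positions.** A network point is `(reach, offset)` with the offset
  in metres from the reach's *downstream* end. Distance to the outlet
  is the sum of fully downstream reach lengths plus the offset — the
  quantity the MAE statistic is defined on.
* **Elevation monotonicity.** Elevations should not increase
  downstream. Violations beyond 0.01 m per reach (sensor-noise scale)
  warn and are flattened by carrying the running downstream minimum;
  all slope computations use the flattened profile, which prevents
  spurious negative slopes.
* **Along-path elevation.** The continuous profile is piecewise linear
  through reach-midpoint samples and linearly extended beyond the first
  and last midpoints (the local gradient is assumed to continue to the
  reach ends). Slope windows that would extend past the top of a path
  are undefined rather than truncated.

## Covariates

Four hydro-topographic covariates drive the default presence model, in
the field's standard units:

| covariate | units | definition |
|---|---|---|
| `upstream_length_km` | km | summed channel length strictly above the reach's upstream node |
| `log_drainage_area` | log10 km² | flow-accumulated drainage area (incremental areas summed downstream) |
| `downstream_slope_pct` | % | drop from the reach midpoint to the point 1000 m downstream along the flow path, divided by the window |
| `elev_norm` | — | reach elevation divided by the median reach elevation of its spatial block |

Decisions taken where the conventions were open: upstream channel
length *excludes* the reach's own length (an inclusive variant sits
behind `inclusive = TRUE`); the area transform is log base 10 and
errors on non-positive areas; elevation normalization divides by the
block median (a subtraction variant sits behind `method = "subtract"`);
the 1000 m slope window is anchored at the reach *midpoint* because the
reach-level covariate needs a representative position. Reaches whose
midpoint lies less than 1000 m above the outlet have no full window and
are **undefined**: undefined cells mark a reach "no prediction" for
every downstream stage (they are never silently imputed into the
model). `downstreamSlope(..., shrink_at_outlet = TRUE)` exists for
truth construction and exploratory use, evaluating the slope over the
available distance instead.

The patch-scale operator `patchMean()` implements flow-conditioned
averaging: the incremental-area-weighted (or length-weighted) mean of a
local variable over the reach and everything upstream of it, the graph
analogue of a flow-conditioned parameter grid.

## Stage 1: presence labels and sub-models

Observed upper-limit points come in two kinds — uppermost fish
occurrence (`O`) and nearest upstream habitat barrier (`H`) — and are
handled identically but fitted separately. `propagateLabels()` marks
every reach from an observation down to the outlet as `trout` and every
reach strictly upstream *on the surveyed path* as `no_trout`; unsampled
tributaries stay unlabelled, because the data say nothing about them.
When the surveyed path is not recorded, the larger-drainage branch is
followed at each fork, which is the channel a field crew ascends by
default. Two observations of one kind that imply both labels on one
reach are contradictory data and raise an error rather than being
resolved silently.

`balanceClasses()` undersamples the majority class within every block
so that the fitted decision boundary sits at probability 0.5 — the
assumption the stopping rules' default cut point relies on. Blocks with
a single class are dropped with a warning; the subsample is seeded.

The default sub-model is unpenalized logistic regression through
`stats::glm` (IRLS); an L2 (ridge) variant via glmnet sits behind
`penalty = "L2"` for separation-prone data. Non-convergence and
(quasi-)complete separation are detected and recorded in the model
metadata — complete separation is expected when training on noiseless
synthetic labels and is not an error. The random-forest alternative
(`fitRandomForest()`, ranger delegate, probability forests) tunes
`mtry` and `min.node.size` over a small grid by an inner 3-fold
cross-validation on MCC, is fully seeded, and satisfies the same
prediction contract: `predictProbability()` returns a probability for
every reach whose covariates are all defined and `NA` ("no
prediction") elsewhere. Greedy-forward variable selection
(`selectVariables()`) adds the candidate that maximizes mean
cross-validated MCC and stops when the improvement falls below 0.005 —
a deliberately simple, documented stand-in for unpublished
feature-filtering pipelines.

## Stage 2: stopping rules

Walking each headwater-to-outlet path upstream over the probability
field:

* **SR2** stops at the most-downstream transition from ≥ cut to < cut.
  On a monotone non-increasing path this is the unique threshold
  crossing. We read "the lowest point having probability ≥ 50 %" as
  this first-crossing benchmark rule.
* **SR3** stops below the first run of at least `persistence_run`
  (default 3) consecutive sub-cut reaches, so a short dip in
  probability does not end the distribution. A run truncated by the
  top of the path still stops: with window 1 and a persistence run
  equal to the remaining path length, SR1 reduces exactly to SR2 on
  monotone paths, which pins this choice down.
* **SR1** is SR3 applied after a centred rolling mean
  (`smooth_window`, default 5, odd; the window shrinks at path ends so
  output length equals input length).
* **SLOPE20** ignores probabilities: the limit is the most-downstream
  reach boundary whose upstream 20 m channel window has average slope
  ≥ 20 %. Slopes are evaluated on the flattened, midpoint-sampled
  profile, so a physical ramp must slightly exceed the threshold to
  register at a misaligned sampling grid — an inherent property of
  reach-discretized hydrography.

Ties exactly at the cut count as presence (the balanced training
centres the boundary at 50 %, so the boundary value itself is
fish-side). Per-path stops are reconciled at confluences by taking the
union of the per-path fish-bearing prefixes, which is closed under
"downstream of" by construction. A limit point then sits on every *cut
edge* — a fishless reach whose downstream neighbour is fish-bearing —
at the upstream node of the last fish-bearing reach. Two fishless
branches above one confluence collapse into a single limit at that
node. When the rule leaves no fish-bearing reach at all there is no
edge and no limit point is emitted (the classification is still
returned). Limit types follow the position: `lateral` when the host
reach meets a larger-drainage channel at its downstream junction (the
limit ends in the tributary within one reach length of the junction),
`confluence_terminal` when the limit sits exactly on a confluence node,
`midstream_terminal` otherwise.

No-prediction reaches take the nearest defined probability downstream
for traversal; reaches with no defined value downstream (the zone
within the slope window of the outlet) inherit the nearest defined
value up the *larger-drainage* branch, so a small fishless tributary
tip cannot poison the mainstem bottom, and any remaining undefined side
branch then inherits the stem value. Such reaches keep the class
`no_prediction` and never host a limit point; limits that would land on
them are relocated to the nearest predicted reach downstream.

## Evaluation

MCC is used throughout (`(TP·TN − FP·FN) / sqrt` of the four marginal
products, 0 by convention when a marginal vanishes — equivalently the
Pearson correlation of the binary vectors). The along-network MAE
pairs observed and predicted limits by headwater path; an observed path
with no predicted limit contributes the distance from the observed
limit to the top of its path (`unpaired = "top"`, the conservative
default) or can be excluded. Because tributary boundaries can fall at
confluences, several limit points may sit on one path's reaches; the
path's own boundary is the most-upstream one, which is how pairing
resolves it. Both the per-split mean and the pooled-pairs MAE are
reported, since either aggregation is defensible.

`makeCVPlan()` assigns whole blocks to folds, balanced to within one
block, independently per repeat. `runNestedCV()` balances the training
blocks per split, fits the sub-model (inner tuning loop for RF only),
scores held-out blocks by MCC, optionally runs a stopping rule for a
per-split MAE, and *asserts* (not assumes) that no reach of a test
block entered the training set. Partial-dependence profiles and
seeded permutation importance provide the model-explanation surface;
for a single-variable logistic model the partial-dependence profile is
analytically the inverse-logit curve, which the tests exploit.

## The synthetic generator

`generateNetwork()` emulates the study conditions the framework is
designed for, not any particular landscape. A mainstem valley carries
one tributary sub-watershed per spatial block (block = mainstem segment
plus its tributary tree), mirroring how a survey region decomposes into
sub-watersheds that each contain their own headwaters — and hence their
own fish boundary. Reach lengths are uniform on 5–7 m. Channel gradient
follows the fluvial slope–area law (gradient proportional to drainage
area to the power −0.45) with lognormal segment- and reach-scale
variability; elevation is the upstream cumulative sum of reach drops,
rescaled to a 300 m relief, so profiles are strictly increasing
upstream by construction. Incremental areas are gamma draws modulated
by an along-channel AR(1) lognormal factor (drainage density varies
along a valley), which also keeps drainage area from being a
deterministic function of channel length. Occupancy truth is the exact
inverse logit of the four core covariates with default coefficients
(3, 1.5, 2, −0.5, −3.5) — probability rising with upstream length and
area, falling with slope and elevation, the slope effect strong in line
with its leading importance for fish limits. The true limit per path is
the most-downstream upstream-crossing of 0.5; note that labels and true
limits depend only on the *direction* of the coefficient vector, not
its scale. `O` observations displace the true limits along-network by
seeded Gaussian noise (30 m default, truncated at path ends and at the
junction where another surveyed path diverges, so observation sets are
always label-consistent); `H` points sit at the first barrier-grade
(≥ 20 % over 20 m) run above `O`, else the path top, and are therefore
never below `O`. Shared-stem duplicate limits are surveyed once.
`simulateRegionalSurvey()` pools 36 small basins whose drainage density
and relief vary lognormally — a survey region rather than a single
watershed — and is the design used for coefficient-recovery studies
(about 20,000 reaches, where each coefficient's sampling error is a few
percent).

What the generator does *not* emulate: raster DEM derivation and its
error structure, climate covariates (only generic autocorrelated
nuisance fields), anthropogenic barriers, braided channels, detection
error in the surveys beyond positional noise, and any real species'
response shape. Passing tests therefore demonstrate the *machinery* —
label propagation, balancing, fitting, stopping rules, spatially
blocked validation — under a known truth; they do not validate
ecological transferability to real landscapes.

## Problem sizes and numerical tolerances

The test suite exercises: exhaustive MCC enumeration over all confusion
tables with at most 20 observations; 100 random networks of up to 500
reaches for stopping-rule/oracle equivalence; a ~20,000-reach regional
survey for coefficient recovery (10 % per-coefficient band, within 3
standard errors); a 3,400-reach, 21-block watershed for the full
predict → SR2 loop (exact recovery at zero noise; MAE within 3× the
30 m observation noise otherwise) and the 5×5 nested spatial CV
(separable labels: mean MCC ≥ 0.95; globally shuffled labels: |mean
MCC| < 0.1). These sizes are the package's chosen demonstration scale:
large enough for stable statistics, small enough to re-run routinely.
Floating-point tolerances are 1e-9 relative for conservation
identities, 1e-6 km for length summaries, and 0.01 m per reach for
elevation monotonicity.

## Known limitations

* Single-outlet trees only; multi-outlet coastal networks must be
  processed per watershed.
* The SR1/SR3 persistence constants of published optimal stopping
  rules are not reproduced; the rules are parameterized
  (`persistence_run`, `smooth_window`) and documented instead.
* Logistic sub-models are unpenalized by default; heavily separated
  training data produce large coefficient norms (flagged in metadata)
  whose predictions remain well-behaved but whose coefficients should
  not be interpreted.
* Model serialization covers the logistic sub-model (coefficients are
  a complete description); random-forest delegates must be refit
  in-session.
* GeoJSON export requires caller-supplied planar geometry; the package
  performs no coordinate-system handling.
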