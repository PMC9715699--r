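#' @import methods
NULL

#' Dendritic stream network of short reaches
#'
#' A validated directed tree of stream reaches oriented toward a single
#' outlet.  Each reach runs from an upstream node (`from_node`) to a
#' downstream node (`to_node`); a confluence is a node that is the `to_node`
#' of two or more reaches.  Reaches carry a representative (midpoint)
#' elevation, an incremental drainage area and a free-form category label
#' (typically land ownership).  Construct with [buildNetwork()]; never fill
#' slots directly.
#'
#' @slot reaches data.frame with columns `reach_id`, `from_node`, `to_node`,
#'   `length_m`, `elev_m`, `elev_flat_m` (elevation flattened to be
#'   non-increasing downstream, used for slope computations),
#'   `incr_area_km2`, `category`, and optionally `block`.
#' @slot outlet character, the `reach_id` of the outlet reach.
#' @slot downstream integer vector: for each reach, the row index of its
#'   unique downstream neighbour (`NA` for the outlet reach).
#' @slot order integer vector of row indices in downstream-first
#'   (outlet-first) topological order.
#' @slot distDown numeric vector: along-network distance (m) from each
#'   reach's downstream end to the outlet's downstream end.
#'
#' @seealso [buildNetwork()], [reaches()], [distanceToOutlet()]
#' @export
setClass("StreamNetwork",
  representation(
    reaches    = "data.frame",
    outlet     = "character",
    downstream = "integer",
    order      = "integer",
    distDown   = "numeric"
  )
)

setValidity("StreamNetwork", function(object) {
  rr <- object@reaches
  msgs <- character()
  need <- c("reach_id", "from_node", "to_node", "length_m", "elev_m",
            "elev_flat_m", "incr_area_km2", "category")
  miss <- setdiff(need, names(rr))
  if (length(miss))
    msgs <- c(msgs, paste("missing reach columns:", paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(rr$reach_id))
      msgs <- c(msgs, "duplicate reach_id")
    if (any(rr$length_m <= 0))
      msgs <- c(msgs, "non-positive reach length")
    if (any(rr$elev_m < 0))
      msgs <- c(msgs, "negative elevation")
    if (any(rr$incr_area_km2 < 0))
      msgs <- c(msgs, "negative incremental drainage area")
    n_nodes <- length(unique(c(rr$from_node, rr$to_node)))
    if (n_nodes != nrow(rr) + 1L)
      msgs <- c(msgs, "not a tree: #nodes must equal #reaches + 1")
    if (sum(is.na(object@downstream)) != 1L)
      msgs <- c(msgs, "network must have exactly one outlet reach")
    if (length(object@order) != nrow(rr) ||
        length(object@distDown) != nrow(rr) ||
        length(object@downstream) != nrow(rr))
      msgs <- c(msgs, "internal index slots out of step with reach table")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted reach-level presence model
#'
#' Maps a covariate table to per-reach presence probabilities.  `"LR"`
#' models store explicit logistic-regression coefficients (intercept first);
#' `"RF"` models store an opaque random-forest delegate in `fit`.
#'
#' @slot algorithm `"LR"` or `"RF"`.
#' @slot variables character, ordered covariate names used by the model.
#' @slot coefficients named numeric: `(Intercept)` then one slope per
#'   variable (length 0 for RF models).
#' @slot fit ANY: the delegate fit object (RF), or the `glm`/`glmnet` fit.
#' @slot metadata list: seed, n, convergence/separation flags, deviance,
#'   standard errors, balancing report, chosen hyperparameters.
#'
#' @seealso [fitLogistic()], [fitRandomForest()], [predictProbability()]
#' @export
setClass("PresenceModel",
  representation(
    algorithm    = "character",
    variables    = "character",
    coefficients = "numeric",
    fit          = "ANY",
    metadata     = "list"
  )
)

setValidity("PresenceModel", function(object) {
  if (!object@algorithm %in% c("LR", "RF"))
    return("algorithm must be 'LR' or 'RF'")
  if (object@algorithm == "LR" &&
      length(object@coefficients) != length(object@variables) + 1L)
    return("LR model needs an intercept plus one coefficient per variable")
  TRUE
})

#' Spatial block cross-validation plan
#'
#' Assigns spatial blocks (e.g. sub-watershed ids) to folds for each of
#' several repeats; every block appears in exactly one fold per repeat and
#' fold sizes are balanced to within one block.
#'
#' @slot repeats integer, number of repeats.
#' @slot folds integer, folds per repeat.
#' @slot assignment data.frame with columns `block`, `repeat_id`, `fold`.
#' @slot seed integer seed the plan was drawn with.
#'
#' @seealso [makeCVPlan()], [runNestedCV()]
#' @export
setClass("CVPlan",
  representation(
    repeats    = "integer",
    folds      = "integer",
    assignment = "data.frame",
    seed       = "integer"
  )
)

setValidity("CVPlan", function(object) {
  a <- object@assignment
  if (!all(c("block", "repeat_id", "fold") %in% names(a)))
    return("assignment needs columns block, repeat_id, fold")
  for (r in seq_len(object@repeats)) {
    ar <- a[a$repeat_id == r, ]
    if (anyDuplicated(ar$block))
      return("a block appears in more than one fold within a repeat")
    sizes <- table(factor(ar$fold, levels = seq_len(object@folds)))
    if (any(sizes == 0))
      return("empty fold")
    if (diff(range(sizes)) > 1)
      return("fold sizes differ by more than one block")
  }
  TRUE
})

#' Stopping-rule configuration
#'
#' Parameters for collapsing per-reach presence probabilities into a single
#' upper-limit point per flow path.  Rules: `"SR1"` smooths probabilities
#' with a centred rolling mean and then applies a persistence-run stop;
#' `"SR2"` stops at the most-downstream crossing from at-or-above to below
#' the cut point; `"SR3"` applies the persistence-run stop to the raw
#' probabilities; `"SLOPE20"` ignores probabilities and places the limit
#' just below the lowest channel run of `run_m` metres with average slope at
#' least `slope_threshold_pct`.
#'
#' @slot rule one of `"SR1"`, `"SR2"`, `"SR3"`, `"SLOPE20"`.
#' @slot cut_point probability threshold in (0, 1); ties at the cut count as
#'   presence.
#' @slot smooth_window odd reach count for the SR1 rolling mean.
#' @slot persistence_run reach count for the SR1/SR3 stop: the limit is
#'   placed below the first (most-downstream) run of at least this many
#'   consecutive sub-cut reaches (a run truncated by the top of the path
#'   also triggers the stop).
#' @slot slope_threshold_pct,run_m slope baseline parameters (percent, m).
#'
#' @seealso [stoppingRuleConfig()], [findUpperLimits()], [applySlope20()]
#' @export
setClass("StoppingRuleConfig",
  representation(
    rule                = "character",
    cut_point           = "numeric",
    smooth_window       = "integer",
    persistence_run     = "integer",
    slope_threshold_pct = "numeric",
    run_m               = "numeric"
  )
)

setValidity("StoppingRuleConfig", function(object) {
  if (!object@rule %in% c("SR1", "SR2", "SR3", "SLOPE20"))
    return("rule must be one of SR1, SR2, SR3, SLOPE20")
  if (object@cut_point <= 0 || object@cut_point >= 1)
    return("cut_point must lie in (0, 1)")
  if (object@smooth_window < 1L || object@smooth_window %% 2L == 0L)
    return("smooth_window must be odd and >= 1")
  if (object@persistence_run < 1L)
    return("persistence_run must be >= 1")
  if (object@run_m <= 0 || object@slope_threshold_pct <= 0)
    return("slope parameters must be positive")
  TRUE
})

#' Synthetic hydrography generator configuration
#'
#' Defaults emulate the study conditions the package is designed for:
#' 5--7 m reaches on a branching tree, a concave longitudinal profile,
#' drainage area accumulating downstream, occupancy generated from a known
#' logistic model of the four core covariates, 63 nuisance covariates with
#' no true effect, 21 spatial blocks, and 30 m along-network observation
#' noise.
#'
#' @slot seed integer master seed.
#' @slot n_headwaters number of headwater tips (leaves) of the tree.
#' @slot mean_segment_reaches mean number of reaches per branch segment
#'   (between confluences); a root-to-leaf path crosses roughly
#'   `log2(n_headwaters) + 1` segments.
#' @slot reach_length_range metres, uniform reach-length range.
#' @slot relief_m elevation relief from the outlet to the highest tip.
#' @slot concavity slope--area exponent: channel gradient scales as
#'   drainage area to the power `-concavity`, giving steep tributary
#'   headwaters and a gentle mainstem.
#' @slot slope_segment_sd,slope_reach_sd SDs of the lognormal gradient
#'   variability at segment (persistent between confluences) and reach
#'   scale; elevation is the upstream cumulative sum of per-reach drops, so
#'   profiles are strictly increasing upstream by construction.
#' @slot area_shape,area_scale_km2 gamma parameters of per-reach incremental
#'   drainage area.
#' @slot area_lognorm_sd SD of a spatially autocorrelated lognormal factor
#'   on incremental areas (valley side-slope contributing area varies along
#'   the channel, so drainage area is not a deterministic function of
#'   channel length).
#' @slot n_nuisance number of spatially autocorrelated nuisance covariates.
#' @slot nuisance_rho per-reach AR(1) autocorrelation of nuisance fields.
#' @slot beta named numeric truth coefficients: intercept then
#'   `upstream_length_km`, `log_drainage_area`, `downstream_slope_pct`,
#'   `elev_norm`.
#' @slot obs_noise_m SD (m) of along-network observation displacement.
#' @slot barrier_slope_pct run-slope threshold that defines a habitat
#'   barrier for H-type observations.
#' @slot n_blocks number of contiguous pseudo-sub-watershed blocks.
#'
#' @seealso [generatorConfig()], [generateNetwork()], [simulateOccupancy()]
#' @export
setClass("GeneratorConfig",
  representation(
    seed                 = "integer",
    n_headwaters         = "integer",
    mean_segment_reaches = "numeric",
    reach_length_range   = "numeric",
    relief_m             = "numeric",
    concavity            = "numeric",
    slope_segment_sd     = "numeric",
    slope_reach_sd       = "numeric",
    area_shape           = "numeric",
    area_scale_km2       = "numeric",
    area_lognorm_sd      = "numeric",
    n_nuisance           = "integer",
    nuisance_rho         = "numeric",
    beta                 = "numeric",
    obs_noise_m          = "numeric",
    barrier_slope_pct    = "numeric",
    n_blocks             = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  if (object@n_headwaters < 1L) return("need at least one headwater")
  if (object@mean_segment_reaches < 1) return("mean_segment_reaches must be >= 1")
  if (length(object@reach_length_range) != 2 ||
      any(object@reach_length_range < 0.5) ||
      any(object@reach_length_range > 50) ||
      diff(object@reach_length_range) < 0)
    return("reach_length_range must be an increasing pair within [0.5, 50] m")
  if (object@obs_noise_m < 0) return("observation noise must be >= 0")
  if (object@n_blocks < 1L) return("need at least one block")
  if (length(object@beta) != 5L)
    return("beta must have 5 elements: intercept + four core covariates")
  TRUE
})

#' @describeIn StreamNetwork-class compact display
#' @param object a `StreamNetwork`
#' @export
setMethod("show", "StreamNetwork", function(object) {
  rr <- object@reaches
  n_leaf <- length(headwaterReaches(object))
  cat("StreamNetwork with", nrow(rr), "reaches /",
      nrow(rr) + 1L, "nodes\n")
  cat("  outlet reach:", object@outlet,
      "| headwaters:", n_leaf,
      "| total length:", sprintf("%.3f km", sum(rr$length_m) / 1000), "\n")
  cat("  elevation range:",
      sprintf("%.1f-%.1f m", min(rr$elev_m), max(rr$elev_m)),
      "| drainage area at outlet:",
      sprintf("%.4f km2", sum(rr$incr_area_km2)), "\n")
  invisible(NULL)
})

#' @describeIn PresenceModel-class compact display
#' @param object a `PresenceModel`
#' @export
setMethod("show", "PresenceModel", function(object) {
  cat("PresenceModel [", object@algorithm, "] on ",
      length(object@variables), " variable(s): ",
      paste(object@variables, collapse = ", "), "\n", sep = "")
  if (object@algorithm == "LR") {
    print(round(object@coefficients, 4))
  }
  if (!is.null(object@metadata$n))
    cat("  trained on n =", object@metadata$n, "\n")
  invisible(NULL)
})

#' @describeIn CVPlan-class compact display
#' @param object a `CVPlan`
#' @export
setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", object@repeats, "repeat(s) x", object@folds,
      "fold(s) over", length(unique(object@assignment$block)),
      "blocks (seed", paste0(object@seed, ")\n"))
  invisible(NULL)
})

#' @describeIn StoppingRuleConfig-class compact display
#' @param object a `StoppingRuleConfig`
#' @export
setMethod("show", "StoppingRuleConfig", function(object) {
  cat("StoppingRuleConfig:", object@rule)
  if (object@rule == "SLOPE20") {
    cat(sprintf(" (slope >= %g%% over %g m)\n",
                object@slope_threshold_pct, object@run_m))
  } else {
    cat(sprintf(" (cut %g", object@cut_point))
    if (object@rule == "SR1")
      cat(sprintf(", window %d", object@smooth_window))
    if (object@rule %in% c("SR1", "SR3"))
      cat(sprintf(", persistence %d", object@persistence_run))
    cat(")\n")
  }
  invisible(NULL)
})
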