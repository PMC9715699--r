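# Stopping rules: collapse per-reach presence probabilities into a single
# upper-limit point per headwater-to-outlet flow path.

#' Construct a stopping-rule configuration
#'
#' @param rule `"SR1"`, `"SR2"`, `"SR3"` or `"SLOPE20"`
#' @param cut_point probability threshold (default 0.5; ties count as
#'   presence)
#' @param smooth_window odd rolling-mean window in reaches (SR1 only,
#'   default 5)
#' @param persistence_run consecutive sub-cut reaches required to stop
#'   (SR1/SR3, default 3)
#' @param slope_threshold_pct,run_m slope-baseline parameters (defaults 20
#'   percent over 20 m)
#' @return a [StoppingRuleConfig-class]
#' @export
stoppingRuleConfig <- function(rule = c("SR2", "SR1", "SR3", "SLOPE20"),
                               cut_point = 0.5, smooth_window = 5,
                               persistence_run = 3,
                               slope_threshold_pct = 20, run_m = 20) {
  rule <- match.arg(rule)
  new("StoppingRuleConfig", rule = rule, cut_point = cut_point,
      smooth_window = as.integer(smooth_window),
      persistence_run = as.integer(persistence_run),
      slope_threshold_pct = slope_threshold_pct, run_m = run_m)
}

#' Centred rolling mean of path probabilities
#'
#' Smooths an ordered (downstream-to-upstream) probability sequence with a
#' centred rolling mean whose window shrinks to the available neighbours at
#' the path ends, so output length equals input length.
#'
#' @param path_probs numeric probabilities along one flow path
#' @param window odd window size (1 = identity)
#' @return numeric of the same length, values in \[0, 1\]
#' @export
smoothProbabilities <- function(path_probs, window) {
  n <- length(path_probs)
  if (n == 0L) stop("empty path")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1")
  if (window == 1L) return(path_probs)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(path_probs))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# per-path stop index: number of trout reaches counted from the bottom of
# the path (k = n means no stop on this path)
.stopIndex <- function(v, cfg) {
  n <- length(v)
  cut <- cfg@cut_point
  sub <- v < cut                      # ties at the cut count as presence
  if (!any(sub)) return(n)
  if (cfg@rule == "SR2") return(which(sub)[1L] - 1L)
  # SR1/SR3: first run of >= persistence_run consecutive sub-cut reaches;
  # a run truncated by the top of the path also stops
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= cfg@persistence_run | ends == n)
  if (!any(ok)) return(n)
  starts[which(ok)[1L]] - 1L
}

# Shared finalization: per-path trout counts -> downstream-closed trout
# set, classification, and deduplicated limit points placed at the
# upstream node of each maximal trout reach.
.finalizeLimits <- function(net, paths, k_per_path, p_defined, cfg) {
  rr <- net@reaches
  n <- nrow(rr)
  trout <- logical(n)
  for (j in seq_along(paths)) {
    k <- k_per_path[[j]]
    if (k > 0L) trout[paths[[j]][seq_len(k)]] <- TRUE
  }
  cls <- ifelse(trout, "trout", "no_trout")
  cls[!p_defined] <- "no_prediction"
  names(cls) <- rr$reach_id

  # a limit sits on every cut edge of the trout set: a non-trout reach
  # whose downstream neighbour is trout.  The limit point is the shared
  # node (the upstream node of the last trout reach); two fishless
  # branches above one confluence collapse into a single limit there.
  hosts <- integer(0)
  cut_child <- integer(0)
  for (b in which(!trout)) {
    d <- net@downstream[b]
    if (is.na(d) || !trout[d]) next
    # never host a limit on a no-prediction reach: relocate downstream
    j <- d
    while (!is.na(j) && !p_defined[j]) j <- net@downstream[j]
    if (is.na(j) || !trout[j]) next
    if (j %in% hosts) next
    hosts <- c(hosts, j)
    cut_child <- c(cut_child, b)
  }
  if (length(hosts)) {
    pts <- networkPoint(rr$reach_id[hosts], rr$length_m[hosts])
    leaf_of <- vapply(cut_child, function(b) .leafAbove(net, b), character(1))
    limits <- data.frame(
      path_id = leaf_of,
      reach_id = rr$reach_id[hosts],
      offset_m = rr$length_m[hosts],
      dist_to_outlet_m = distanceToOutlet(net, pts),
      limit_type = vapply(seq_along(hosts), function(k)
        classifyLimitType(net, pts[k, , drop = FALSE]), character(1)),
      rule = cfg@rule,
      cut_point = if (cfg@rule == "SLOPE20") NA_real_ else cfg@cut_point,
      stringsAsFactors = FALSE)
    limits <- limits[order(limits$dist_to_outlet_m, limits$reach_id), ]
    rownames(limits) <- NULL
  } else {
    limits <- data.frame(path_id = character(0), reach_id = character(0),
                         offset_m = numeric(0), dist_to_outlet_m = numeric(0),
                         limit_type = character(0), rule = character(0),
                         cut_point = numeric(0), stringsAsFactors = FALSE)
  }
  list(limits = limits, classification = cls)
}

# headwater id reachable from a reach following the larger-area branch
.leafAbove <- function(net, i) {
  area <- accumulateDrainageArea(net)
  ups <- .upstreamNeighbors(net)
  cur <- i
  repeat {
    nxt <- ups[[cur]]
    if (is.null(nxt) || !length(nxt)) return(net@reaches$reach_id[cur])
    cur <- nxt[which.max(area[nxt])]
  }
}

#' Find upper-limit points from per-reach probabilities
#'
#' Walks every headwater-to-outlet flow path upstream over the (optionally
#' smoothed) probability field and applies the configured stopping rule:
#' `SR2` stops at the most-downstream transition from at-or-above to below
#' the cut point; `SR1` (on smoothed probabilities) and `SR3` (raw) stop
#' below the first run of at least `persistence_run` consecutive sub-cut
#' reaches, so short dips in probability do not end the distribution.
#' Per-path limits are reconciled at confluences into a downstream-closed
#' trout set; each limit point sits at the upstream node of a maximal
#' trout reach.  No-prediction reaches (`NA`) borrow the nearest defined
#' downstream probability for traversal, keep class `no_prediction`, and
#' never host a limit point.
#'
#' @param net a [StreamNetwork-class]
#' @param probs numeric probabilities named by reach id (NA = no
#'   prediction)
#' @param cfg a [StoppingRuleConfig-class] (rules SR1/SR2/SR3)
#' @return list with `limits` (data.frame: path_id, reach_id, offset_m,
#'   dist_to_outlet_m, limit_type, rule, cut_point) and `classification`
#'   (named character: trout / no_trout / no_prediction per reach)
#' @export
findUpperLimits <- function(net, probs, cfg = stoppingRuleConfig("SR2")) {
  if (cfg@rule == "SLOPE20")
    return(applySlope20(net, cfg))
  rr <- net@reaches
  p <- if (is.null(names(probs))) as.numeric(probs)
       else as.numeric(probs[rr$reach_id])
  if (length(p) != nrow(rr))
    stop("probability field must cover every reach (use reach-id names)")
  if (all(is.na(p)))
    stop("probability field covers zero reaches")
  defined <- !is.na(p)
  filled <- p
  for (i in net@order) {                 # copy from downstream
    d <- net@downstream[i]
    if (is.na(filled[i]) && !is.na(d) && !is.na(filled[d]))
      filled[i] <- filled[d]
  }
  if (anyNA(filled)) {
    # reaches with no defined value downstream (outlet-side gaps) take
    # the nearest defined value up the larger-drainage branch, so small
    # fishless tributary tips cannot poison the mainstem bottom
    need <- is.na(filled)
    area <- unname(accumulateDrainageArea(net))
    writer <- rep(-Inf, length(filled))
    for (i in rev(net@order)) {          # deepest reaches first
      d <- net@downstream[i]
      if (!is.na(d) && need[d] && !is.na(filled[i]) && area[i] > writer[d]) {
        filled[d] <- filled[i]
        writer[d] <- area[i]
      }
    }
    for (i in net@order) {               # undefined side branches inherit
      d <- net@downstream[i]             # the now-defined stem value
      if (is.na(filled[i]) && !is.na(d) && !is.na(filled[d]))
        filled[i] <- filled[d]
    }
  }
  paths <- .leafPathsIdx(net)
  k <- vapply(paths, function(path) {
    v <- filled[path]
    if (cfg@rule == "SR1")
      v <- smoothProbabilities(v, cfg@smooth_window)
    .stopIndex(v, cfg)
  }, integer(1))
  .finalizeLimits(net, paths, k, defined, cfg)
}

#' Slope-threshold baseline limits
#'
#' The regulatory-style baseline that ignores presence probabilities: on
#' each flow path the upper limit is the most-downstream position
#' immediately below the lowest run of `run_m` metres of channel with
#' average slope at least `slope_threshold_pct`.  Paths with no such run
#' get no limit (the whole path is classified trout).
#'
#' @param net a [StreamNetwork-class]
#' @param cfg a [StoppingRuleConfig-class] with `rule = "SLOPE20"`
#' @return as [findUpperLimits()]
#' @export
applySlope20 <- function(net, cfg = stoppingRuleConfig("SLOPE20")) {
  rr <- net@reaches
  paths <- .leafPathsIdx(net)
  k <- vapply(paths, function(path) {
    prof <- .pathProfile(net, path)
    d <- net@distDown[path]                     # run-start candidates
    feas <- d + cfg@run_m <= prof$top + 1e-9
    if (!any(feas)) return(length(path))
    e_lo <- .profileElev(prof, d[feas])
    e_hi <- .profileElev(prof, d[feas] + cfg@run_m)
    slope <- 100 * (e_hi - e_lo) / cfg@run_m
    hit <- which(slope >= cfg@slope_threshold_pct - 1e-9)
    if (!length(hit)) return(length(path))      # whole path trout
    which(feas)[hit[1L]] - 1L                   # reaches below the run
  }, integer(1))
  .finalizeLimits(net, paths, k, rep(TRUE, nrow(rr)), cfg)
}

#' Classify the type of an upper-limit point
#'
#' `lateral` limits end in a tributary just above (within one reach length
#' of) its junction with a larger-drainage channel; `confluence_terminal`
#' limits sit exactly at a confluence node on the combined channel;
#' everything else is `midstream_terminal` (a soft or hard edge within a
#' channel).
#'
#' @param net a [StreamNetwork-class]
#' @param point a single-row [networkPoint()]
#' @return one of `"lateral"`, `"midstream_terminal"`,
#'   `"confluence_terminal"`
#' @export
classifyLimitType <- function(net, point) {
  i <- .checkPoints(net, point)
  rr <- net@reaches
  ups <- .upstreamNeighbors(net)
  at_up_node <- abs(point$offset_m - rr$length_m[i]) < 1e-9
  if (at_up_node && length(ups[[i]]) >= 2L)
    return("confluence_terminal")
  sib <- setdiff(which(rr$to_node == rr$to_node[i]), i)
  if (length(sib)) {
    area <- unname(accumulateDrainageArea(net))
    if (any(area[sib] > area[i]))
      return("lateral")
  }
  "midstream_terminal"
}
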