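# Hydro-topographic covariates per reach.  Undefined values are encoded as
# NA and mean "no prediction" for every downstream modelling stage.

#' Flow-accumulated drainage area
#'
#' Accumulates incremental drainage areas downstream: each reach's drainage
#' area is its own incremental area plus the areas of all reaches upstream
#' of it.  The outlet value equals the sum of all incremental areas exactly.
#'
#' @param net a [StreamNetwork-class]
#' @return named numeric, km2 per reach
#' @export
accumulateDrainageArea <- function(net) {
  rr <- net@reaches
  if (any(rr$incr_area_km2 < 0))
    stop("negative incremental drainage area")
  area <- rr$incr_area_km2
  for (i in rev(net@order)) {       # upstream reaches before downstream
    d <- net@downstream[i]
    if (!is.na(d)) area[d] <- area[d] + area[i]
  }
  names(area) <- rr$reach_id
  area
}

#' Total upstream channel length
#'
#' The summed length of all channel strictly upstream of each reach's
#' upstream node, i.e. the stream length above the reach, in km.
#' Headwater reaches score 0.  With `inclusive = TRUE` the reach's own
#' length is included (length above the reach's downstream node).
#'
#' @param net a [StreamNetwork-class]
#' @param inclusive include the reach's own length (default `FALSE`)
#' @return named numeric, km per reach
#' @export
upstreamChannelLength <- function(net, inclusive = FALSE) {
  rr <- net@reaches
  tot <- rr$length_m                 # subtree totals, self included
  for (i in rev(net@order)) {
    d <- net@downstream[i]
    if (!is.na(d)) tot[d] <- tot[d] + tot[i]
  }
  out <- if (inclusive) tot else tot - rr$length_m
  names(out) <- rr$reach_id
  out / 1000
}

#' Downstream channel slope over a window
#'
#' Percent slope between each reach's midpoint and the point `window_m`
#' metres downstream along its (unique) flow path, computed on the
#' flattened elevation profile interpolated through reach midpoints.
#' Reaches whose midpoint lies less than `window_m` above the outlet have
#' no full window and are undefined (`NA`), unless `shrink_at_outlet` is
#' set, in which case the slope is taken over the available distance down
#' to the outlet.
#'
#' @param net a [StreamNetwork-class]
#' @param window_m evaluation window, m (default 1000)
#' @param shrink_at_outlet allow a shortened window near the outlet
#'   (default `FALSE`)
#' @return named numeric, percent per reach (NA = undefined)
#' @export
downstreamSlope <- function(net, window_m = 1000, shrink_at_outlet = FALSE) {
  rr <- net@reaches
  n <- nrow(rr)
  mid <- net@distDown + rr$length_m / 2
  slope <- rep(NA_real_, n)
  done <- logical(n)
  for (path in .leafPathsIdx(net)) {
    todo <- path[!done[path]]
    if (!length(todo)) next
    prof <- .pathProfile(net, path)
    tgt <- mid[todo] - window_m
    full <- tgt >= -1e-9
    val <- rep(NA_real_, length(todo))
    if (any(full)) {
      e_tgt <- .profileElev(prof, pmax(tgt[full], 0))
      val[full] <- 100 * (rr$elev_flat_m[todo[full]] - e_tgt) / window_m
    }
    if (shrink_at_outlet && any(!full)) {
      sh <- !full
      e0 <- .profileElev(prof, rep(0, sum(sh)))
      w <- pmax(mid[todo[sh]], 1e-9)
      val[sh] <- 100 * (rr$elev_flat_m[todo[sh]] - e0) / w
    }
    slope[todo] <- val
    done[todo] <- TRUE
  }
  names(slope) <- rr$reach_id
  slope
}

#' Median-normalized elevation
#'
#' Divides each reach's elevation by the median reach elevation of its
#' spatial block (a pseudo sub-watershed), so the block median maps to 1.
#' With `method = "subtract"` the block median is subtracted instead.
#'
#' @param net a [StreamNetwork-class]
#' @param blocks named character/factor: reach id -> block id; defaults to
#'   the network's `block` column
#' @param method `"divide"` (default) or `"subtract"`
#' @return named numeric per reach
#' @export
normalizeElevation <- function(net, blocks = NULL, method = c("divide", "subtract")) {
  method <- match.arg(method)
  rr <- net@reaches
  blocks <- .resolveBlocks(net, blocks)
  out <- numeric(nrow(rr))
  for (b in unique(blocks)) {
    sel <- blocks == b
    med <- stats::median(rr$elev_m[sel])
    if (method == "divide") {
      if (med == 0)
        stop("block ", b, " has zero median elevation; cannot divide")
      out[sel] <- rr$elev_m[sel] / med
    } else {
      out[sel] <- rr$elev_m[sel] - med
    }
  }
  names(out) <- rr$reach_id
  out
}

.resolveBlocks <- function(net, blocks) {
  rr <- net@reaches
  if (is.null(blocks)) {
    if (is.null(rr$block))
      stop("no block assignment: supply `blocks` or a `block` reach column")
    return(as.character(rr$block))
  }
  blocks <- blocks[rr$reach_id]
  if (anyNA(blocks))
    stop("block assignment missing for some reaches")
  as.character(blocks)
}

#' Patch-scale (flow-conditioned) mean of a local variable
#'
#' The upstream-weighted average of a per-reach variable over the drainage
#' patch of each reach (the reach and everything upstream of it), weighted
#' by incremental drainage area (default) or reach length.  Equals the
#' local value at headwater reaches with positive own weight.
#'
#' @param net a [StreamNetwork-class]
#' @param local_values numeric named by reach id (or in reach-table order)
#' @param weights `"drainage-area"` (default) or `"length"`
#' @return named numeric per reach
#' @export
patchMean <- function(net, local_values, weights = c("drainage-area", "length")) {
  weights <- match.arg(weights)
  rr <- net@reaches
  v <- if (is.null(names(local_values))) as.numeric(local_values)
       else as.numeric(local_values[rr$reach_id])
  if (length(v) != nrow(rr))
    stop("local_values must cover every reach")
  w <- if (weights == "drainage-area") rr$incr_area_km2 else rr$length_m
  num <- w * v
  den <- w
  for (i in rev(net@order)) {
    d <- net@downstream[i]
    if (!is.na(d)) {
      num[d] <- num[d] + num[i]
      den[d] <- den[d] + den[i]
    }
  }
  if (any(den == 0 & !is.na(num)))
    stop("zero total weight in the upstream patch of: ",
         paste(rr$reach_id[den == 0], collapse = ", "))
  out <- num / den
  names(out) <- rr$reach_id
  out
}

#' Channel run slope upstream of each reach's downstream node
#'
#' For each reach position (its downstream node), the average percent slope
#' of the `run_m` metres of channel immediately upstream, following the
#' larger-drainage-area branch at confluences.  Undefined (`NA`) where less
#' than `run_m` of channel exists upstream of the position.
#'
#' @param net a [StreamNetwork-class]
#' @param run_m run length, m (default 20)
#' @return named numeric, percent per reach position (NA = undefined)
#' @export
runSlopes <- function(net, run_m = 20) {
  rr <- net@reaches
  n <- nrow(rr)
  area <- accumulateDrainageArea(net)
  ups <- .upstreamNeighbors(net)
  out <- rep(NA_real_, n)
  mid <- net@distDown + rr$length_m / 2
  for (i in seq_len(n)) {
    d0 <- net@distDown[i]
    walk <- i
    top <- d0 + rr$length_m[i]
    cur <- i
    # extend until the window top is bracketed by a midpoint (or the
    # channel ends; the profile is linearly extended at its ends)
    while (top < d0 + run_m || mid[cur] < d0 + run_m) {
      nxt <- ups[[cur]]
      if (is.null(nxt) || !length(nxt)) break
      cur <- nxt[which.max(area[nxt])]
      walk <- c(walk, cur)
      top <- net@distDown[cur] + rr$length_m[cur]
    }
    if (top + 1e-9 < d0 + run_m) next       # < run_m of channel above
    d_idx <- net@downstream[i]              # bracket the window bottom
    if (!is.na(d_idx)) walk <- c(d_idx, walk)
    prof <- .pathProfile(net, walk)
    ee <- .profileElev(prof, c(d0, d0 + run_m))
    out[i] <- 100 * (ee[2] - ee[1]) / run_m
  }
  names(out) <- rr$reach_id
  out
}

#' Assemble the core covariate table
#'
#' Builds the per-reach predictor table used by the presence models: total
#' upstream channel length (km), drainage area (km2) and its log10,
#' downstream channel slope over `window_m` (percent; NA where the outlet
#' is nearer than the window), and block-median-normalized elevation.
#' Extra named covariate vectors are bound on unchanged.
#'
#' @param net a [StreamNetwork-class]
#' @param window_m slope window, m (default 1000)
#' @param blocks optional reach -> block assignment (see
#'   [normalizeElevation()])
#' @param extra optional data.frame (or named list of vectors) of
#'   additional covariates in reach-table order
#' @return data.frame: `reach_id` plus covariate columns; `NA` marks a
#'   reach as "no prediction" for downstream stages
#' @export
buildCovariateTable <- function(net, window_m = 1000, blocks = NULL,
                                extra = NULL) {
  area <- accumulateDrainageArea(net)
  if (any(area <= 0))
    stop("drainage area must be positive to log-transform; offending reach: ",
         paste(names(area)[area <= 0], collapse = ", "))
  tab <- data.frame(
    reach_id            = net@reaches$reach_id,
    upstream_length_km  = unname(upstreamChannelLength(net)),
    drainage_area_km2   = unname(area),
    log_drainage_area   = unname(log10(area)),
    downstream_slope_pct = unname(downstreamSlope(net, window_m)),
    elev_norm           = unname(normalizeElevation(net, blocks)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    if (nrow(extra) != nrow(tab))
      stop("extra covariates must have one row per reach")
    tab <- cbind(tab, extra)
  }
  tab
}
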