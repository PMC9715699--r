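# Dendritic network construction and along-network geometry.
# Reaches are oriented downstream: from_node is the upstream end.

#' Build a validated stream network from reach records
#'
#' Assembles a [StreamNetwork-class] from a tabular description of reaches,
#' auto-detecting the outlet as the unique reach whose downstream node has
#' no continuation.  The directed graph must be a tree oriented toward that
#' single outlet.  Elevations are expected to be non-increasing downstream;
#' violations beyond a 0.01 m per-reach tolerance raise a warning and the
#' profile is flattened (each reach's flattened elevation carries the
#' running downstream minimum) for slope computations.
#'
#' @param reach_records data.frame with columns `reach_id`, `from_node`,
#'   `to_node`, `length_m`, `elev_m`, `incr_area_km2`; optional `category`
#'   and `block` columns are carried through.
#' @return a validated `StreamNetwork`.
#' @examples
#' rr <- data.frame(reach_id = c("a", "b", "c"),
#'                  from_node = c("n3", "n2", "n1"),
#'                  to_node   = c("n2", "n1", "n0"),
#'                  length_m = c(5, 6, 7),
#'                  elev_m = c(30, 20, 10),
#'                  incr_area_km2 = c(1, 1, 2))
#' net <- buildNetwork(rr)
#' outletReach(net)
#' @export
buildNetwork <- function(reach_records) {
  rr <- as.data.frame(reach_records, stringsAsFactors = FALSE)
  need <- c("reach_id", "from_node", "to_node", "length_m", "elev_m",
            "incr_area_km2")
  miss <- setdiff(need, names(rr))
  if (length(miss))
    stop("reach records are missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rr) < 1L)
    stop("need at least one reach")
  rr$reach_id  <- as.character(rr$reach_id)
  rr$from_node <- as.character(rr$from_node)
  rr$to_node   <- as.character(rr$to_node)
  if (is.null(rr$category)) rr$category <- "uncategorized"
  rr$category <- as.character(rr$category)

  dup <- rr$reach_id[duplicated(rr$reach_id)]
  if (length(dup))
    stop("duplicate reach_id: ", paste(unique(dup), collapse = ", "))
  bad <- rr$reach_id[!(rr$length_m > 0)]
  if (length(bad))
    stop("non-positive length for reach: ", paste(bad, collapse = ", "))
  dupfrom <- rr$from_node[duplicated(rr$from_node)]
  if (length(dupfrom))
    stop("node has more than one downstream reach (divergence): ",
         paste(unique(dupfrom), collapse = ", "))

  # downstream neighbour: the reach whose from_node equals our to_node
  downstream <- match(rr$to_node, rr$from_node)
  outlet_idx <- which(is.na(downstream))
  if (length(outlet_idx) == 0L)
    stop("cycle detected: no outlet reach exists")
  if (length(outlet_idx) > 1L)
    stop("multiple outlets: reaches ",
         paste(rr$reach_id[outlet_idx], collapse = ", "),
         " share no path to a common outlet")

  # BFS from the outlet over upstream neighbours; unvisited reaches are
  # orphaned or cyclic
  ups <- split(seq_len(nrow(rr)), downstream)   # index -> upstream rows
  ord <- integer(nrow(rr))
  ord[1L] <- outlet_idx
  head_q <- 1L; tail_q <- 1L
  while (head_q <= tail_q) {
    cur <- ord[head_q]
    kids <- ups[[as.character(cur)]]
    if (!is.null(kids)) {
      ord[tail_q + seq_along(kids)] <- kids
      tail_q <- tail_q + length(kids)
    }
    head_q <- head_q + 1L
  }
  if (tail_q < nrow(rr)) {
    seen <- logical(nrow(rr)); seen[ord[seq_len(tail_q)]] <- TRUE
    stop("orphan or cyclic reaches with no path to the outlet: ",
         paste(rr$reach_id[!seen], collapse = ", "))
  }

  distDown <- numeric(nrow(rr))
  for (i in ord) {
    d <- downstream[i]
    if (!is.na(d)) distDown[i] <- distDown[d] + rr$length_m[d]
  }

  # flatten elevation so it is non-increasing downstream (tolerance 0.01 m)
  viol <- 0L
  elev_flat <- rr$elev_m
  for (i in rev(ord)) {            # leaves first
    d <- downstream[i]
    if (!is.na(d)) {
      if (rr$elev_m[d] > rr$elev_m[i] + 0.01) viol <- viol + 1L
      if (elev_flat[d] > elev_flat[i]) elev_flat[d] <- elev_flat[i]
    }
  }
  if (viol > 0L)
    warning(viol, " reach(es) violate downstream elevation monotonicity ",
            "beyond 0.01 m; profile flattened for slope computations")
  rr$elev_flat_m <- elev_flat

  keep <- c("reach_id", "from_node", "to_node", "length_m", "elev_m",
            "elev_flat_m", "incr_area_km2", "category",
            intersect("block", names(rr)))
  new("StreamNetwork",
      reaches    = rr[, keep],
      outlet     = rr$reach_id[outlet_idx],
      downstream = as.integer(downstream),
      order      = ord,
      distDown   = distDown)
}

## ---- accessors -----------------------------------------------------------

#' Reach table of a network
#' @param net a [StreamNetwork-class]
#' @return data.frame of reach attributes
#' @export
reaches <- function(net) net@reaches

#' Number of reaches
#' @param net a [StreamNetwork-class]
#' @export
nReaches <- function(net) nrow(net@reaches)

#' Outlet reach id
#' @param net a [StreamNetwork-class]
#' @export
outletReach <- function(net) net@outlet

#' Headwater (leaf) reach ids
#'
#' Reaches with no upstream neighbour; one flow path runs from each
#' headwater to the outlet.
#' @param net a [StreamNetwork-class]
#' @export
headwaterReaches <- function(net) {
  has_up <- logical(nReaches(net))
  has_up[net@downstream[!is.na(net@downstream)]] <- TRUE
  net@reaches$reach_id[!has_up]
}

## ---- internal index helpers ---------------------------------------------

.reachIdx <- function(net, reach_id) {
  i <- match(as.character(reach_id), net@reaches$reach_id)
  if (anyNA(i))
    stop("unknown reach id: ",
         paste(reach_id[is.na(i)], collapse = ", "))
  i
}

# list: reach index -> integer vector of immediate upstream reach indices
.upstreamNeighbors <- function(net) {
  out <- vector("list", nReaches(net))
  ok <- !is.na(net@downstream)
  sp <- split(seq_len(nReaches(net))[ok], net@downstream[ok])
  out[as.integer(names(sp))] <- sp
  out
}

# reach indices from a reach down to the outlet (inclusive), downstream order
.pathToOutletIdx <- function(net, i) {
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(path, i)
    i <- net@downstream[i]
  }
  path
}

# every headwater-to-outlet flow path, as reach indices ordered
# downstream -> upstream, named by headwater reach id
.leafPathsIdx <- function(net) {
  leaves <- .reachIdx(net, headwaterReaches(net))
  out <- lapply(leaves, function(l) rev(.pathToOutletIdx(net, l)))
  names(out) <- net@reaches$reach_id[leaves]
  out
}

## ---- network points and geometry ----------------------------------------

#' Construct network points
#'
#' A network point is a position on a reach, measured as an offset in
#' metres from the reach's downstream end (0 = downstream node,
#' `length_m` = upstream node).  Vectorized.
#'
#' @param reach_id character reach id(s)
#' @param offset_m numeric offset(s) from the downstream end, m
#' @return data.frame with columns `reach_id`, `offset_m`
#' @export
networkPoint <- function(reach_id, offset_m = 0) {
  data.frame(reach_id = as.character(reach_id),
             offset_m = as.numeric(offset_m),
             stringsAsFactors = FALSE)
}

.checkPoints <- function(net, points) {
  i <- .reachIdx(net, points$reach_id)
  len <- net@reaches$length_m[i]
  bad <- points$offset_m < -1e-9 | points$offset_m > len + 1e-9
  if (any(bad))
    stop("offset outside reach length for: ",
         paste(points$reach_id[bad], collapse = ", "))
  i
}

#' Along-network distance from a point to the outlet
#'
#' The linear stream distance (m): the sum of the full lengths of all
#' reaches strictly downstream of the point, plus the point's offset within
#' its own reach.  Zero at the outlet's downstream end.
#'
#' @param net a [StreamNetwork-class]
#' @param points data.frame from [networkPoint()] (vectorized)
#' @return numeric metres
#' @export
distanceToOutlet <- function(net, points) {
  i <- .checkPoints(net, points)
  net@distDown[i] + points$offset_m
}

#' Reaches strictly upstream of a reach
#'
#' All reaches whose flow path to the outlet passes through the given
#' reach, excluding the reach itself.
#'
#' @param net a [StreamNetwork-class]
#' @param reach_id a single reach id
#' @return character vector of reach ids (possibly empty)
#' @export
upstreamSet <- function(net, reach_id) {
  i0 <- .reachIdx(net, reach_id)
  ups <- .upstreamNeighbors(net)
  acc <- integer(0)
  stack <- ups[[i0]]
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    acc <- c(acc, cur)
    stack <- c(stack, ups[[cur]])
  }
  net@reaches$reach_id[acc]
}

#' Flow path between two network points
#'
#' When one point lies on the flow path of the other, returns the ordered
#' downstream-to-upstream sequence of reach ids connecting them (inclusive
#' of both end reaches).  Points on sibling tributaries share no single
#' flow path and return `NULL`.
#'
#' @param net a [StreamNetwork-class]
#' @param a,b single-row network points ([networkPoint()])
#' @return character vector of reach ids, or `NULL` when the points are
#'   not on one flow path
#' @export
pathBetween <- function(net, a, b) {
  ia <- .checkPoints(net, a)
  ib <- .checkPoints(net, b)
  if (ia == ib) return(net@reaches$reach_id[ia])
  # the deeper point (larger distance) must descend onto the other
  da <- net@distDown[ia] + a$offset_m
  db <- net@distDown[ib] + b$offset_m
  hi <- if (da >= db) ia else ib
  lo <- if (da >= db) ib else ia
  path <- .pathToOutletIdx(net, hi)
  k <- match(lo, path)
  if (is.na(k)) return(NULL)
  net@reaches$reach_id[rev(path[seq_len(k)])]
}

#' Snap a planar coordinate to the network
#'
#' Finds the nearest position on the supplied per-reach polylines within
#' `max_dist_m` and returns it as a network point.  Polyline vertices are
#' ordered upstream to downstream (direction of flow); the offset is scaled
#' so the polyline's arc length maps onto the reach's `length_m`.
#'
#' @param net a [StreamNetwork-class]
#' @param coord numeric length-2 planar x/y, in the same metric units as
#'   the geometry
#' @param reach_geometry named list of two-column matrices (x, y), one per
#'   reach id
#' @param max_dist_m rejection tolerance (m), default 30
#' @return list with `point` (a [networkPoint()] row) and `snap_dist_m`
#' @export
snapPoint <- function(net, coord, reach_geometry, max_dist_m = 30) {
  best <- list(dist = Inf, reach = NA_character_, along = NA_real_,
               total = NA_real_)
  for (rid in names(reach_geometry)) {
    g <- reach_geometry[[rid]]
    if (nrow(g) < 2L) next
    seg_len <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
    cum <- c(0, cumsum(seg_len))
    for (s in seq_len(nrow(g) - 1L)) {
      p1 <- g[s, ]; p2 <- g[s + 1L, ]
      v <- p2 - p1
      L2 <- sum(v^2)
      t <- if (L2 == 0) 0 else
        max(0, min(1, sum((coord - p1) * v) / L2))
      proj <- p1 + t * v
      d <- sqrt(sum((coord - proj)^2))
      if (d < best$dist) {
        best <- list(dist = d, reach = rid,
                     along = cum[s] + t * seg_len[s],
                     total = cum[length(cum)])
      }
    }
  }
  if (!is.finite(best$dist))
    stop("no usable reach geometry supplied")
  if (best$dist > max_dist_m)
    stop(sprintf(
      "nearest flowline is %.1f m away, beyond the %g m snap tolerance",
      best$dist, max_dist_m))
  i <- .reachIdx(net, best$reach)
  len <- net@reaches$length_m[i]
  # polyline runs upstream -> downstream; offset is from the downstream end
  offset <- len * (1 - best$along / best$total)
  list(point = networkPoint(best$reach, offset),
       snap_dist_m = best$dist)
}

## ---- along-path elevation profile (internal) -----------------------------

# Piecewise-linear elevation over distance-to-outlet through reach-midpoint
# samples of the flattened profile, constant-extended at both ends.
# path_idx: reach indices ordered downstream -> upstream.
.pathProfile <- function(net, path_idx) {
  rr <- net@reaches
  d <- net@distDown[path_idx] + rr$length_m[path_idx] / 2
  e <- rr$elev_flat_m[path_idx]
  list(dist = d, elev = e,
       top = net@distDown[path_idx[length(path_idx)]] +
         rr$length_m[path_idx[length(path_idx)]])
}

# piecewise-linear through the midpoint samples, linearly extended beyond
# the first/last sample (the local gradient continues to the reach ends)
.profileElev <- function(profile, at) {
  d <- profile$dist
  e <- profile$elev
  n <- length(d)
  if (n == 1L) return(rep(e, length(at)))
  out <- stats::approx(d, e, xout = pmin(pmax(at, d[1L]), d[n]))$y
  lo <- at < d[1L]
  hi <- at > d[n]
  if (any(lo))
    out[lo] <- e[1L] + (at[lo] - d[1L]) * (e[2L] - e[1L]) / (d[2L] - d[1L])
  if (any(hi))
    out[hi] <- e[n] + (at[hi] - d[n]) * (e[n] - e[n - 1L]) / (d[n] - d[n - 1L])
  out
}
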