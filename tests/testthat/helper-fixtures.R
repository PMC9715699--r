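# Fixture builders and independent brute-force oracles.  Oracles work on
# the raw reach table (from/to node matching) and never touch the
# package's internal slots, so they stay independent of the code they
# check.

# chain network: index 1 = outlet reach, increasing upstream
chainRecords <- function(lengths, elevs = NULL, incr = NULL) {
  n <- length(lengths)
  if (is.null(elevs)) elevs <- seq(0, by = 1, length.out = n)
  if (is.null(incr)) incr <- rep(1, n)
  data.frame(reach_id = sprintf("c%03d", seq_len(n)),
             from_node = sprintf("n%03d", seq_len(n)),
             to_node = sprintf("n%03d", seq_len(n) - 1L),
             length_m = lengths, elev_m = elevs, incr_area_km2 = incr,
             stringsAsFactors = FALSE)
}

chainNetwork <- function(lengths, elevs = NULL, incr = NULL)
  buildNetwork(chainRecords(lengths, elevs, incr))

# Y network: two headwater reaches (hL, hR) joining above an outlet chain
yRecords <- function(out_len = 10, head_len = c(10, 10),
                     out_elev = 5, head_elev = c(10, 10),
                     out_incr = 1, head_incr = c(1, 1)) {
  data.frame(reach_id = c("out", "hL", "hR"),
             from_node = c("nj", "nl", "nr"),
             to_node = c("n0", "nj", "nj"),
             length_m = c(out_len, head_len),
             elev_m = c(out_elev, head_elev),
             incr_area_km2 = c(out_incr, head_incr),
             stringsAsFactors = FALSE)
}

smallTree <- function(seed, n_blocks = 4, n_headwaters = 8,
                      mean_segment_reaches = 10)
  generateNetwork(generatorConfig(seed = seed, n_blocks = n_blocks,
                                  n_headwaters = n_headwaters,
                                  mean_segment_reaches = mean_segment_reaches))

## ---- brute-force oracles over a raw reach table --------------------------

# downstream reach id (NA at outlet), from raw records
.bfDown <- function(rec) rec$reach_id[match(rec$to_node, rec$from_node)]

# walk a point to the outlet summing full downstream reach lengths
bfDistToOutlet <- function(rec, reach_id, offset_m) {
  down <- .bfDown(rec)
  names(down) <- rec$reach_id
  len <- stats::setNames(rec$length_m, rec$reach_id)
  d <- offset_m
  cur <- down[[reach_id]]
  while (!is.na(cur)) {
    d <- d + len[[cur]]
    cur <- down[[cur]]
  }
  d
}

bfUpstreamSet <- function(rec, reach_id) {
  down <- stats::setNames(.bfDown(rec), rec$reach_id)
  out <- character(0)
  for (r in rec$reach_id) {
    cur <- down[[r]]
    while (!is.na(cur)) {
      if (cur == reach_id) { out <- c(out, r); break }
      cur <- down[[cur]]
    }
  }
  out
}

bfDrainageArea <- function(rec, reach_id) {
  ids <- c(reach_id, bfUpstreamSet(rec, reach_id))
  sum(rec$incr_area_km2[rec$reach_id %in% ids])
}

bfPatchMean <- function(rec, reach_id, values, weights) {
  ids <- c(reach_id, bfUpstreamSet(rec, reach_id))
  sel <- rec$reach_id %in% ids
  w <- weights[rec$reach_id[sel]]
  v <- values[rec$reach_id[sel]]
  sum(w * v) / sum(w)
}

## stopping-rule oracle: candidate-scan over one downstream-to-upstream
## probability vector; returns the number of trout reaches from the path
## bottom (n = no stop)
bfStopIndex <- function(v, rule, cut = 0.5, run = 3, window = 5) {
  n <- length(v)
  if (rule == "SR1") {
    # centred rolling mean with shrinking edges, written long-hand
    h <- (window - 1) %/% 2
    v <- vapply(seq_len(n), function(i)
      mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  if (rule == "SR2") {
    for (i in seq_len(n)) if (v[i] < cut) return(i - 1L)
    return(n)
  }
  # SR1 / SR3: first i whose next `run` reaches (truncated at the top)
  # are all below the cut
  for (i in seq_len(n)) {
    win <- v[i:min(n, i + run - 1L)]
    if (all(win < cut)) return(i - 1L)
  }
  n
}

# reach classification implied by per-path stop indices (union closure)
bfClosureClass <- function(paths, k_per_path, reach_ids) {
  trout <- character(0)
  for (j in seq_along(paths)) {
    k <- k_per_path[[j]]
    if (k > 0) trout <- union(trout, paths[[j]][seq_len(k)])
  }
  stats::setNames(ifelse(reach_ids %in% trout, "trout", "no_trout"),
                  reach_ids)
}

# downstream -> upstream reach-id paths from the raw table
bfLeafPaths <- function(rec) {
  down <- stats::setNames(.bfDown(rec), rec$reach_id)
  leaves <- setdiff(rec$reach_id, down[!is.na(down)])
  lapply(stats::setNames(leaves, leaves), function(l) {
    p <- l
    cur <- down[[l]]
    while (!is.na(cur)) { p <- c(p, cur); cur <- down[[cur]] }
    rev(p)
  })
}

# a comb network: three long parallel branches joining one node above a
# short outlet reach, giving three distinct flow paths on one outlet
combNetwork <- function(branch_len_m = 3600, reach_m = 10) {
  k <- branch_len_m / reach_m
  rows <- list(data.frame(reach_id = "out", from_node = "nj",
                          to_node = "n0", length_m = reach_m,
                          elev_m = 0.5, incr_area_km2 = 1))
  for (b in 1:3) {
    ids <- sprintf("p%d_%03d", b, seq_len(k))
    rows[[b + 1]] <- data.frame(
      reach_id = ids,
      from_node = sprintf("p%d_n%03d", b, seq_len(k)),
      to_node = c("nj", sprintf("p%d_n%03d", b, seq_len(k - 1))),
      length_m = reach_m,
      elev_m = reach_m + seq_len(k) * reach_m * 0.01,
      incr_area_km2 = 0.01)
  }
  buildNetwork(do.call(rbind, rows))
}

# a limit point at a given distance-to-outlet along branch b of the comb
combLimit <- function(net, b, dist_m, reach_m = 10) {
  j <- ceiling((dist_m - reach_m) / reach_m)
  data.frame(path_id = sprintf("p%d_%03d", b, 360),
             reach_id = sprintf("p%d_%03d", b, j),
             offset_m = dist_m - reach_m - (j - 1) * reach_m)
}

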