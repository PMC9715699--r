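# Seeded synthetic stream networks, covariates, occupancy truth and noisy
# observations, so the whole pipeline is testable without field data.

#' Construct a generator configuration
#'
#' Defaults describe the study conditions the package emulates: a
#' binary-branching tree of 5--7 m reaches with a concave longitudinal
#' profile, drainage area accumulating downstream, 63 spatially
#' autocorrelated nuisance covariates with no true effect, 21 contiguous
#' spatial blocks, occupancy driven by a logistic model of the four core
#' covariates (probability rising with upstream channel length and
#' drainage area, falling with slope and elevation), and 30 m
#' along-network observation noise.
#'
#' @param seed integer master seed
#' @param n_headwaters total headwater tips across all tributary
#'   sub-watersheds (default 42, two per block)
#' @param mean_segment_reaches mean reaches per branch segment (default 40)
#' @param reach_length_range m (default c(5, 7))
#' @param relief_m total relief outlet to highest tip (default 300)
#' @param concavity slope--area exponent: channel gradient scales as
#'   drainage area to the power `-concavity` (default 0.45), so tributary
#'   headwaters are steep and the mainstem is gentle
#' @param slope_segment_sd,slope_reach_sd lognormal SDs of channel-gradient
#'   variability at segment and reach scale (defaults 0.45 and 0.25)
#' @param area_shape,area_scale_km2 gamma incremental-area parameters
#'   (defaults 2 and 0.0015)
#' @param area_lognorm_sd SD of the along-network autocorrelated lognormal
#'   factor on incremental areas (default 1.2)
#' @param n_nuisance nuisance covariates (default 63)
#' @param nuisance_rho AR(1) autocorrelation of nuisance fields
#'   (default 0.95)
#' @param beta truth coefficients: intercept, upstream_length_km,
#'   log_drainage_area, downstream_slope_pct, elev_norm
#' @param obs_noise_m observation displacement SD, m (default 30)
#' @param barrier_slope_pct run-slope defining a habitat barrier
#'   (default 20)
#' @param n_blocks contiguous blocks (default 21)
#' @return a [GeneratorConfig-class]
#' @export
generatorConfig <- function(seed = 1L,
                            n_headwaters = 42,
                            mean_segment_reaches = 40,
                            reach_length_range = c(5, 7),
                            relief_m = 300,
                            concavity = 0.45,
                            slope_segment_sd = 0.45,
                            slope_reach_sd = 0.25,
                            area_shape = 2,
                            area_scale_km2 = 0.0015,
                            area_lognorm_sd = 1.2,
                            n_nuisance = 63,
                            nuisance_rho = 0.95,
                            beta = c(intercept = 3,
                                     upstream_length_km = 1.5,
                                     log_drainage_area = 2,
                                     downstream_slope_pct = -0.5,
                                     elev_norm = -3.5),
                            obs_noise_m = 30,
                            barrier_slope_pct = 20,
                            n_blocks = 21) {
  new("GeneratorConfig",
      seed = as.integer(seed),
      n_headwaters = as.integer(n_headwaters),
      mean_segment_reaches = mean_segment_reaches,
      reach_length_range = reach_length_range,
      relief_m = relief_m,
      concavity = concavity,
      slope_segment_sd = slope_segment_sd,
      slope_reach_sd = slope_reach_sd,
      area_shape = area_shape,
      area_scale_km2 = area_scale_km2,
      area_lognorm_sd = area_lognorm_sd,
      n_nuisance = as.integer(n_nuisance),
      nuisance_rho = nuisance_rho,
      beta = beta,
      obs_noise_m = obs_noise_m,
      barrier_slope_pct = barrier_slope_pct,
      n_blocks = as.integer(n_blocks))
}

#' Generate a random dendritic stream network
#'
#' Builds a mainstem valley with one tributary sub-watershed per spatial
#' block, the way a prediction region decomposes into sub-watersheds that
#' each hold their own headwaters: block `b` is the `b`-th mainstem
#' segment plus the branching tributary tree that joins it there.
#' Segments are filled with 5--7 m reaches; channel gradient follows the
#' fluvial slope--area law (gradient proportional to drainage area to the
#' power `-concavity`) with lognormal segment- and reach-scale
#' variability, and elevation is the upstream cumulative sum of per-reach
#' drops rescaled to the configured relief, so every profile is strictly
#' increasing upstream.  Incremental drainage areas are gamma draws with
#' an along-channel autocorrelated lognormal factor.  The result is
#' validated through [buildNetwork()].
#'
#' @param cfg a [GeneratorConfig-class]
#' @return a [StreamNetwork-class] with `block` and `category` columns
#' @export
generateNetwork <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  B <- cfg@n_blocks
  H <- max(cfg@n_headwaters, B)
  # mainstem chain of B segments; tributary subtree b joins at the tip of
  # mainstem segment b
  parent <- rep(NA_integer_, B)
  parent[-1L] <- seq_len(B - 1L)
  seg_trib <- rep(0L, B)                   # 0 = mainstem
  quota <- rep(H %/% B, B) + (seq_len(B) <= H %% B)
  for (b in seq_len(B)) {
    root_b <- length(parent) + 1L
    parent <- c(parent, b)
    seg_trib <- c(seg_trib, b)
    leaves_b <- root_b
    while (length(leaves_b) < quota[b]) {
      s <- if (length(leaves_b) == 1L) leaves_b else sample(leaves_b, 1L)
      parent <- c(parent, s, s)
      seg_trib <- c(seg_trib, b, b)
      leaves_b <- c(setdiff(leaves_b, s),
                    length(parent) - 1L, length(parent))
    }
  }
  nseg <- length(parent)
  nre <- pmax(1L, stats::rpois(nseg, cfg@mean_segment_reaches))
  total <- sum(nre)

  reach_id <- sprintf("r%05d", seq_len(total))
  from_node <- character(total)
  to_node <- character(total)
  length_m <- stats::runif(total, cfg@reach_length_range[1],
                           cfg@reach_length_range[2])
  node_ct <- 0L
  new_node <- function() {
    node_ct <<- node_ct + 1L
    sprintf("v%05d", node_ct)
  }
  root <- new_node()
  tip_node <- character(nseg)     # upstream tip node of each segment
  tip_dist <- numeric(nseg)       # distance-to-outlet of that tip
  seg_of <- integer(total)
  mid_dist <- numeric(total)
  pos <- 0L
  for (s in seq_len(nseg)) {
    down <- if (is.na(parent[s])) root else tip_node[parent[s]]
    d <- if (is.na(parent[s])) 0 else tip_dist[parent[s]]
    for (j in seq_len(nre[s])) {
      pos <- pos + 1L
      up <- new_node()
      from_node[pos] <- up
      to_node[pos] <- down
      seg_of[pos] <- s
      mid_dist[pos] <- d + length_m[pos] / 2
      d <- d + length_m[pos]
      down <- up
    }
    tip_node[s] <- down
    tip_dist[s] <- d
  }
  incr_area_km2 <- stats::rgamma(total, shape = cfg@area_shape,
                                 scale = cfg@area_scale_km2)
  # reaches are created downstream -> upstream within segments, with
  # parents before children, so position order is a valid downstream-
  # first order within this constructor
  down_of <- match(to_node, from_node)
  if (cfg@area_lognorm_sd > 0) {
    # along-channel autocorrelated lognormal factor: contributing
    # side-slope area varies smoothly but substantially along the valley
    rho_a <- 0.98
    eps <- stats::rnorm(total)
    fac <- numeric(total)
    for (i in seq_len(total)) {
      d <- down_of[i]
      fac[i] <- if (is.na(d)) eps[i]
                else rho_a * fac[d] + sqrt(1 - rho_a^2) * eps[i]
    }
    incr_area_km2 <- incr_area_km2 * exp(cfg@area_lognorm_sd * fac)
  }
  area <- incr_area_km2                      # accumulate downstream
  for (i in rev(seq_len(total))) {
    d <- down_of[i]
    if (!is.na(d)) area[d] <- area[d] + area[i]
  }

  # slope--area law: gradient ~ (A / median A)^(-concavity), with
  # persistent segment-scale and reach-scale lognormal variability;
  # drops accumulate upstream and are rescaled to the target relief
  seg_fac <- exp(stats::rnorm(nseg, 0, cfg@slope_segment_sd))
  grad <- (area / stats::median(area))^(-cfg@concavity) *
    seg_fac[seg_of] * exp(stats::rnorm(total, 0, cfg@slope_reach_sd))
  drop <- grad * length_m
  elev_m <- numeric(total)
  tip_elev <- numeric(nseg)
  pos <- 0L
  for (s in seq_len(nseg)) {
    e <- if (is.na(parent[s])) 0 else tip_elev[parent[s]]
    for (j in seq_len(nre[s])) {
      pos <- pos + 1L
      elev_m[pos] <- e + drop[pos] / 2
      e <- e + drop[pos]
    }
    tip_elev[s] <- e
  }
  scale_f <- cfg@relief_m / max(tip_elev)
  elev_m <- elev_m * scale_f

  # block = mainstem segment + the tributary sub-watershed joining there
  seg_block <- ifelse(seg_trib == 0L, seq_len(nseg), seg_trib)
  block <- sprintf("b%02d", seg_block[seg_of])
  owners <- c("private_industrial", "private_nonindustrial", "state",
              "blm", "usfs", "other")
  seg_owner <- sample(owners, nseg, replace = TRUE,
                      prob = c(0.3, 0.2, 0.15, 0.15, 0.15, 0.05))
  buildNetwork(data.frame(
    reach_id = reach_id, from_node = from_node, to_node = to_node,
    length_m = length_m, elev_m = elev_m, incr_area_km2 = incr_area_km2,
    category = seg_owner[seg_of], block = block,
    stringsAsFactors = FALSE))
}

#' Simulate the covariate table for a generated network
#'
#' The four core covariates are computed by the covariate engine itself
#' (never re-derived here); nuisance covariates are seeded AR(1) fields
#' propagated upstream along the network, spatially autocorrelated but
#' with no true effect on occupancy.
#'
#' @param net a [StreamNetwork-class] with a `block` column
#' @param cfg a [GeneratorConfig-class]
#' @return covariate data.frame (`reach_id`, core four, `nuisNN` columns)
#' @export
simulateCovariates <- function(net, cfg) {
  tab <- buildCovariateTable(net)
  n <- nReaches(net)
  if (cfg@n_nuisance > 0L) {
    set.seed(cfg@seed + 7L)
    rho <- cfg@nuisance_rho
    nuis <- matrix(NA_real_, n, cfg@n_nuisance)
    for (k in seq_len(cfg@n_nuisance)) {
      eps <- stats::rnorm(n)
      v <- numeric(n)
      for (i in net@order) {
        d <- net@downstream[i]
        v[i] <- if (is.na(d)) eps[i]
                else rho * v[d] + sqrt(1 - rho^2) * eps[i]
      }
      nuis[, k] <- v
    }
    colnames(nuis) <- sprintf("nuis%02d", seq_len(cfg@n_nuisance))
    tab <- cbind(tab, as.data.frame(nuis))
  }
  tab
}

#' Simulate true occupancy from a known logistic model
#'
#' Computes the exact inverse-logit probability of presence from the four
#' core covariates (the downstream slope is evaluated with a shrunken
#' window near the outlet so the truth is defined on every reach), derives
#' the true upper-limit point on each headwater path as the
#' most-downstream upstream-crossing of 0.5, and draws per-reach Bernoulli
#' occupancy for label-noise experiments.
#'
#' @param net a [StreamNetwork-class]
#' @param covariates covariate table from [simulateCovariates()] (or
#'   [buildCovariateTable()])
#' @param beta numeric length 5: intercept + four core covariates
#' @param seed integer seed for the Bernoulli draws
#' @return object of class `SyntheticTruth`: list with `net`,
#'   `covariates`, `prob` (named), `limits` (data.frame), `draws`, `beta`
#' @export
simulateOccupancy <- function(net, covariates, beta, seed = 1) {
  if (length(beta) != 5L)
    stop("beta must have 5 elements: intercept + four core covariates")
  core <- c("upstream_length_km", "log_drainage_area",
            "downstream_slope_pct", "elev_norm")
  covariates <- as.data.frame(covariates)
  X <- cbind(
    covariates$upstream_length_km,
    covariates$log_drainage_area,
    unname(downstreamSlope(net, 1000, shrink_at_outlet = TRUE)),
    covariates$elev_norm)
  colnames(X) <- core
  p <- stats::plogis(beta[1L] + as.numeric(X %*% beta[-1L]))
  names(p) <- net@reaches$reach_id

  rr <- net@reaches
  rows <- list()
  for (leaf in names(paths <- .leafPathsIdx(net))) {
    path <- paths[[leaf]]
    v <- p[path]
    sub <- v < 0.5
    if (!any(sub)) next                         # saturated: all trout
    k <- which(sub)[1L] - 1L
    host <- if (k >= 1L) path[k] else path[1L]
    off <- if (k >= 1L) rr$length_m[host] else 0
    rows[[leaf]] <- data.frame(
      path_id = leaf, reach_id = rr$reach_id[host], offset_m = off,
      dist_to_outlet_m = net@distDown[host] + off,
      stringsAsFactors = FALSE)
  }
  limits <- if (length(rows)) do.call(rbind, rows)
            else data.frame(path_id = character(0), reach_id = character(0),
                            offset_m = numeric(0),
                            dist_to_outlet_m = numeric(0))
  rownames(limits) <- NULL
  set.seed(as.integer(seed))
  draws <- stats::rbinom(length(p), 1L, p)
  names(draws) <- names(p)
  structure(list(net = net, covariates = covariates, prob = p,
                 limits = limits, draws = draws, beta = beta),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", nReaches(x$net), "reaches,",
      nrow(x$limits), "true upper-limit point(s)\n")
  cat("  probability range:",
      sprintf("%.3f-%.3f", min(x$prob), max(x$prob)), "\n")
  invisible(x)
}

#' Simulate a regional survey of many small sub-watersheds
#'
#' Emulates a survey region: many independent small basins whose drainage
#' density (incremental-area scale) and relief vary lognormally from basin
#' to basin, all sharing one true occupancy model.  Pooling the basins
#' yields a large, well-conditioned design for coefficient-recovery
#' studies.
#'
#' @param seed integer master seed
#' @param n_basins number of basins (default 36, about 20,000 reaches)
#' @param beta truth coefficients shared by all basins (default: the
#'   [generatorConfig()] default)
#' @param area_scale_sd,relief_sd lognormal SDs of the between-basin
#'   variability in drainage density and relief (defaults 1.0 and 0.4)
#' @return list with `X` (pooled covariate data.frame of the four core
#'   covariates, slope evaluated with a shrunken window near each outlet
#'   so every reach is usable), `y` (pooled Bernoulli presence draws),
#'   `basin` (basin index per row), and `beta`
#' @export
simulateRegionalSurvey <- function(seed, n_basins = 36, beta = NULL,
                                   area_scale_sd = 1.0, relief_sd = 0.4) {
  core <- c("upstream_length_km", "log_drainage_area",
            "downstream_slope_pct", "elev_norm")
  if (is.null(beta)) beta <- generatorConfig()@beta
  set.seed(as.integer(seed))
  scale_draw <- 0.0015 * exp(stats::rnorm(n_basins, 0, area_scale_sd))
  relief_draw <- 150 * exp(stats::rnorm(n_basins, 0, relief_sd))
  Xs <- vector("list", n_basins)
  ys <- vector("list", n_basins)
  for (k in seq_len(n_basins)) {
    cfg <- generatorConfig(seed = seed * 1000L + k, beta = beta,
                           n_blocks = 7, n_headwaters = 14,
                           mean_segment_reaches = 20,
                           area_scale_km2 = scale_draw[k],
                           relief_m = relief_draw[k])
    net <- generateNetwork(cfg)
    cov <- simulateCovariates(net, cfg)
    tr <- simulateOccupancy(net, cov, beta, seed = seed * 1000L + k + 500L)
    cov$downstream_slope_pct <-
      unname(downstreamSlope(net, 1000, shrink_at_outlet = TRUE))
    Xs[[k]] <- cov[, core]
    ys[[k]] <- unname(tr$draws)
  }
  list(X = do.call(rbind, Xs), y = unlist(ys),
       basin = rep(seq_len(n_basins), vapply(ys, length, 1L)),
       beta = beta)
}

#' Sample noisy upper-limit observations from the truth
#'
#' `O` observations displace each true limit along its flow path by seeded
#' Gaussian noise (truncated at the path ends); `H` observations sit at
#' the first position upstream of `O` whose channel run slope reaches the
#' barrier threshold, or at the path top when no barrier exists, so `H`
#' is never downstream of `O`.
#'
#' Several flow paths that share a stem share one true limit; such
#' duplicates are surveyed once (one upper-limit point per stream), and
#' displacements are truncated so an observation never drops below the
#' junction where another surveyed path diverges, which would imply
#' contradictory labels.
#'
#' @param truth a `SyntheticTruth`
#' @param noise_m displacement SD in metres (0 = observations exactly at
#'   the true limits)
#' @param seed integer seed
#' @param barrier_slope_pct run-slope threshold for H (default 20)
#' @param run_m barrier run length, m (default 20)
#' @return an [observationSet()] with O and H rows
#' @export
sampleObservations <- function(truth, noise_m, seed = 1,
                               barrier_slope_pct = 20, run_m = 20) {
  net <- truth$net
  rr <- net@reaches
  if (!nrow(truth$limits)) stop("truth has no upper-limit points")
  set.seed(as.integer(seed))
  paths <- .leafPathsIdx(net)
  lim <- truth$limits[!duplicated(truth$limits[, c("reach_id", "offset_m")]), ,
                      drop = FALSE]
  # lower truncation per surveyed path: deepest divergence from any other
  # surveyed path (structurally below the true limit for distinct limits)
  psets <- lapply(lim$path_id, function(lf) paths[[lf]])
  bound <- numeric(nrow(lim))
  for (k in seq_len(nrow(lim))) {
    b <- 0
    for (j in seq_len(nrow(lim))) {
      if (j == k) next
      common <- intersect(psets[[k]], psets[[j]])
      if (length(common)) {
        i_top <- common[which.max(net@distDown[common])]
        b <- max(b, net@distDown[i_top] + rr$length_m[i_top])
      }
    }
    bound[k] <- b
  }
  rows <- list()
  for (k in seq_len(nrow(lim))) {
    leaf <- lim$path_id[k]
    path <- paths[[leaf]]
    d_lo <- net@distDown[path]                 # downstream-node distances
    top <- d_lo[length(path)] + rr$length_m[path[length(path)]]
    y <- lim$dist_to_outlet_m[k]
    target <- min(max(y + stats::rnorm(1, 0, noise_m), bound[k]), top)
    j <- findInterval(target, d_lo, rightmost.closed = FALSE)
    j <- max(1L, min(j, length(path)))
    o_reach <- path[j]
    o_off <- min(max(target - d_lo[j], 0), rr$length_m[o_reach])
    o_dist <- d_lo[j] + o_off

    # H: first barrier-grade run strictly above O, else the path top
    prof <- .pathProfile(net, path)
    cand <- which(d_lo > o_dist & d_lo + run_m <= top + 1e-9)
    h_reach <- path[length(path)]
    h_off <- rr$length_m[h_reach]
    if (length(cand)) {
      e_lo <- .profileElev(prof, d_lo[cand])
      e_hi <- .profileElev(prof, d_lo[cand] + run_m)
      slope <- 100 * (e_hi - e_lo) / run_m
      hit <- which(slope >= barrier_slope_pct)
      if (length(hit)) {
        h_reach <- path[cand[hit[1L]]]
        h_off <- 0
      }
    }
    blk <- function(i) if (!is.null(rr$block)) rr$block[i] else "all"
    rows[[k]] <- observationSet(
      networkPoint(rr$reach_id[c(o_reach, h_reach)], c(o_off, h_off)),
      kind = c("O", "H"), block = c(blk(o_reach), blk(h_reach)),
      path_id = leaf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
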