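# File formats, configuration and the end-to-end pipeline driver.
# CSV is the canonical interchange; GeoJSON points are optional sugar.
# Units in files: metres for lengths/distances, km2 for areas, percent for
# slopes.

.log <- function(level, ..., verbosity = 1L) {
  lv <- c(error = 0L, warn = 1L, info = 2L)[[level]]
  if (lv <= verbosity + 1L)
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

.reachTableHeader <- c("reach_id", "from_node", "to_node", "length_m",
                       "elev_m", "incr_area_km2", "category")

#' Read a reach table CSV
#'
#' The canonical network interchange format: a CSV whose header starts
#' with `reach_id, from_node, to_node, length_m, elev_m, incr_area_km2,
#' category`; any further columns are per-reach covariates (a column named
#' `block` is treated as the spatial-block assignment).  Empty fields are
#' undefined (`NA`).
#'
#' @param path CSV file path
#' @return list: `network` (a validated [StreamNetwork-class]) and
#'   `covariates` (data.frame `reach_id` + extra columns, or `NULL`)
#' @export
readReachTable <- function(path) {
  if (!file.exists(path)) stop("reach table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reach_id = "character",
                                       from_node = "character",
                                       to_node = "character"))
  if (length(names(df)) < length(.reachTableHeader) ||
      !identical(names(df)[seq_along(.reachTableHeader)], .reachTableHeader))
    stop("reach table header must start with: ",
         paste(.reachTableHeader, collapse = ", "))
  dup <- df$reach_id[duplicated(df$reach_id)]
  if (length(dup))
    stop("duplicate reach_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  extras <- setdiff(names(df), c(.reachTableHeader, "block"))
  net <- buildNetwork(df[, c(.reachTableHeader,
                             intersect("block", names(df)))])
  cov <- NULL
  if (length(extras))
    cov <- df[, c("reach_id", extras), drop = FALSE]
  list(network = net, covariates = cov)
}

#' Write a reach table CSV
#'
#' Round-trips losslessly through [readReachTable()].
#'
#' @param net a [StreamNetwork-class]
#' @param path output CSV path
#' @param covariates optional data.frame with `reach_id` plus covariate
#'   columns to append
#' @export
writeReachTable <- function(net, path, covariates = NULL) {
  rr <- net@reaches
  out <- rr[, c(.reachTableHeader, intersect("block", names(rr)))]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    m <- match(out$reach_id, covariates$reach_id)
    out <- cbind(out, covariates[m, setdiff(names(covariates), "reach_id"),
                                 drop = FALSE])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write observation CSVs
#'
#' Columns: `reach_id, offset_m, kind, block, path_id`.
#'
#' @param path CSV path
#' @return an [observationSet()]
#' @export
readObservations <- function(path) {
  if (!file.exists(path)) stop("observations not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reach_id = "character"))
  need <- c("reach_id", "offset_m", "kind", "block", "path_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation file missing column(s): ", paste(miss, collapse = ", "))
  pid <- as.character(df$path_id)
  pid[!is.na(pid) & pid == ""] <- NA_character_
  observationSet(networkPoint(df$reach_id, df$offset_m),
                 kind = df$kind, block = df$block, path_id = pid)
}

#' @rdname readObservations
#' @param obs an [observationSet()]
#' @export
writeObservations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write upper-limit points
#'
#' CSV columns: `path_id, reach_id, offset_m, dist_to_outlet_m,
#' limit_type, rule, cut_point`.  With `format = "geojson"`, per-reach
#' polylines must be supplied and each limit is written as a GeoJSON Point
#' feature positioned along its host reach.
#'
#' @param path output path
#' @param limits limit data.frame (from [findUpperLimits()])
#' @param format `"csv"` (default) or `"geojson"`
#' @param reach_geometry named list of two-column polyline matrices
#'   (upstream to downstream), required for GeoJSON
#' @param reach_lengths optional named numeric of reach lengths (m); when
#'   supplied, offsets are rescaled from reach length onto polyline arc
#'   length, otherwise the polyline is taken as true length
#' @export
writeLimits <- function(path, limits, format = c("csv", "geojson"),
                        reach_geometry = NULL, reach_lengths = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(limits, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  if (is.null(reach_geometry))
    stop("GeoJSON output requested but no reach geometry supplied")
  feats <- lapply(seq_len(nrow(limits)), function(k) {
    rid <- limits$reach_id[k]
    g <- reach_geometry[[rid]]
    if (is.null(g))
      stop("no geometry for reach ", rid)
    seg <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    len <- if (!is.null(reach_lengths)) reach_lengths[[rid]] else total
    # polyline runs upstream -> downstream; offset is from downstream end
    target <- total * max(0, min(1, 1 - limits$offset_m[k] / len))
    i <- findInterval(target, cum, rightmost.closed = TRUE)
    i <- max(1L, min(i, length(seg)))
    t <- if (seg[i] == 0) 0 else (target - cum[i]) / seg[i]
    xy <- g[i, ] + t * (g[i + 1L, ] - g[i, ])
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = as.numeric(xy)),
         properties = as.list(limits[k, ]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---- pipeline driver -----------------------------------------------------

.loadConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

.cfgPath <- function(cfg, key, dir = NULL, must_exist = FALSE) {
  p <- cfg[[key]]
  ext <- if (key == "model") ".json" else ".csv"
  if (is.null(p) && !is.null(dir)) p <- file.path(dir, paste0(key, ext))
  if (must_exist && (is.null(p) || !file.exists(p)))
    stop("required input missing: ", key,
         if (!is.null(p)) paste0(" (", p, ")"))
  p
}

#' Run a pipeline command
#'
#' Drives the end-to-end `simulate -> fit -> predict -> limits ->
#' evaluate / compare` workflow over CSV artifacts in an output directory.
#' Every command is a pure function of its inputs, configuration and seed:
#' reruns with the same seed produce byte-identical primary outputs.
#'
#' Commands and their artifacts (all under `config$out_dir`):
#' \describe{
#'   \item{simulate}{writes `reaches.csv`, `observations.csv`,
#'     `truth_limits.csv` from the synthetic generator}
#'   \item{fit}{reads reaches + observations, propagates and balances
#'     labels, fits a logistic sub-model; writes `model.json`}
#'   \item{predict}{applies `model.json`; writes `probabilities.csv`}
#'   \item{limits}{applies the configured stopping rule; writes
#'     `limits.csv`}
#'   \item{evaluate}{nested spatial CV of the configured model; writes
#'     `cv_report.csv` and `cv_summary.json`}
#'   \item{compare}{signed comparison of `limits_a` vs `limits_b`; writes
#'     `comparison.csv`}
#' }
#'
#' @param command one of `simulate`, `fit`, `predict`, `limits`,
#'   `evaluate`, `compare`
#' @param config named list or YAML path; recognised keys include
#'   `out_dir`, `seed`, `reaches`, `observations`, `model`,
#'   `probabilities`, `kind`, `variables`, `slope_window_m`, `rule`,
#'   `cut_point`,
#'   `smooth_window`, `persistence_run`, `repeats`, `folds`,
#'   `limits_a`, `limits_b`, generator overrides under `generator`,
#'   and `verbosity`
#' @param seed overrides `config$seed`
#' @return invisibly, a list of the file paths written
#' @export
runPipeline <- function(command = c("simulate", "fit", "predict", "limits",
                                    "evaluate", "compare"),
                        config = list(), seed = NULL) {
  command <- match.arg(command)
  cfg <- .loadConfig(config)
  if (!is.null(seed)) cfg$seed <- seed
  verb <- cfg$verbosity %||% 1L
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (command %in% c("simulate", "fit", "evaluate") && is.null(cfg$seed))
    stop("a seed is mandatory for stochastic command '", command, "'")
  .log("info", "command=", command, " seed=", cfg$seed %||% "none",
       verbosity = verb)
  written <- character(0)

  if (command == "simulate") {
    gen <- do.call(generatorConfig,
                   c(list(seed = cfg$seed), cfg$generator))
    net <- generateNetwork(gen)
    truth <- simulateOccupancy(net, simulateCovariates(net, gen),
                               gen@beta, seed = gen@seed + 11L)
    obs <- sampleObservations(truth, gen@obs_noise_m, seed = gen@seed + 13L,
                              barrier_slope_pct = gen@barrier_slope_pct)
    p1 <- file.path(out_dir, "reaches.csv")
    p2 <- file.path(out_dir, "observations.csv")
    p3 <- file.path(out_dir, "truth_limits.csv")
    writeReachTable(net, p1)
    writeObservations(obs, p2)
    utils::write.csv(truth$limits, p3, row.names = FALSE, quote = FALSE)
    .log("info", "simulated ", nReaches(net), " reaches, ",
         nrow(obs), " observations", verbosity = verb)
    written <- c(p1, p2, p3)
  } else if (command == "fit") {
    inp <- readReachTable(.cfgPath(cfg, "reaches", out_dir, TRUE))
    obs <- readObservations(.cfgPath(cfg, "observations", out_dir, TRUE))
    net <- inp$network
    kind <- cfg$kind %||% "O"
    vars <- cfg$variables %||% c("upstream_length_km", "log_drainage_area",
                                 "downstream_slope_pct", "elev_norm")
    window <- cfg$slope_window_m %||% 1000
    cov <- buildCovariateTable(net, window_m = window)
    if (!is.null(inp$covariates))
      cov <- cbind(cov, inp$covariates[match(cov$reach_id,
                                             inp$covariates$reach_id),
                                       -1, drop = FALSE])
    blocks <- stats::setNames(net@reaches$block, net@reaches$reach_id)
    labels <- propagateLabels(net, obs, kind)
    bal <- balanceClasses(labels, blocks, seed = cfg$seed)
    X <- cov[match(bal$reach_id, cov$reach_id), vars, drop = FALSE]
    keep <- stats::complete.cases(X)
    model <- suppressWarnings(
      fitLogistic(X[keep, , drop = FALSE],
                  as.integer(bal$label == "trout")[keep]))
    mp <- file.path(out_dir, "model.json")
    jsonlite::write_json(list(
      algorithm = "LR", variables = vars,
      coefficients = as.list(model@coefficients),
      seed = cfg$seed, kind = kind,
      slope_window_m = window,
      n = model@metadata$n,
      provenance_md5 = unname(tools::md5sum(
        .cfgPath(cfg, "reaches", out_dir, TRUE)))),
      mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log("info", "fitted LR on ", model@metadata$n, " balanced reaches",
         verbosity = verb)
    written <- mp
  } else if (command == "predict") {
    inp <- readReachTable(.cfgPath(cfg, "reaches", out_dir, TRUE))
    mj <- jsonlite::read_json(.cfgPath(cfg, "model", out_dir, TRUE),
                              simplifyVector = TRUE)
    model <- new("PresenceModel", algorithm = "LR",
                 variables = mj$variables,
                 coefficients = unlist(mj$coefficients),
                 fit = NULL, metadata = list(n = mj$n))
    cov <- buildCovariateTable(inp$network,
                               window_m = mj$slope_window_m %||% 1000)
    p <- predictProbability(model, cov)
    pp <- file.path(out_dir, "probabilities.csv")
    utils::write.csv(data.frame(reach_id = cov$reach_id,
                                probability = unname(p)),
                     pp, row.names = FALSE, quote = FALSE, na = "")
    written <- pp
  } else if (command == "limits") {
    inp <- readReachTable(.cfgPath(cfg, "reaches", out_dir, TRUE))
    rule <- stoppingRuleConfig(
      rule = cfg$rule %||% "SR2",
      cut_point = cfg$cut_point %||% 0.5,
      smooth_window = cfg$smooth_window %||% 5,
      persistence_run = cfg$persistence_run %||% 3,
      slope_threshold_pct = cfg$slope_threshold_pct %||% 20,
      run_m = cfg$run_m %||% 20)
    if (rule@rule == "SLOPE20") {
      res <- applySlope20(inp$network, rule)
    } else {
      pr <- utils::read.csv(.cfgPath(cfg, "probabilities", out_dir, TRUE),
                            colClasses = c(reach_id = "character"))
      probs <- stats::setNames(pr$probability, pr$reach_id)
      res <- findUpperLimits(inp$network, probs, rule)
    }
    lp <- file.path(out_dir, "limits.csv")
    writeLimits(lp, res$limits)
    cp <- file.path(out_dir, "classification.csv")
    utils::write.csv(data.frame(reach_id = names(res$classification),
                                class = unname(res$classification)),
                     cp, row.names = FALSE, quote = FALSE)
    .log("info", nrow(res$limits), " limit point(s)", verbosity = verb)
    written <- c(lp, cp)
  } else if (command == "evaluate") {
    inp <- readReachTable(.cfgPath(cfg, "reaches", out_dir, TRUE))
    obs <- readObservations(.cfgPath(cfg, "observations", out_dir, TRUE))
    net <- inp$network
    if (!file.exists(.cfgPath(cfg, "model", out_dir)))
      stop("evaluate requires a fitted model (run 'fit' first): ",
           .cfgPath(cfg, "model", out_dir))
    mj <- jsonlite::read_json(.cfgPath(cfg, "model", out_dir),
                              simplifyVector = TRUE)
    cov <- buildCovariateTable(net,
                               window_m = mj$slope_window_m %||% 1000)
    blocks <- stats::setNames(net@reaches$block, net@reaches$reach_id)
    labels <- propagateLabels(net, obs, mj$kind %||% "O")
    plan <- makeCVPlan(unique(unname(blocks[labels$reach_id])),
                       repeats = cfg$repeats %||% 5,
                       folds = cfg$folds %||% 5, seed = cfg$seed)
    res <- runNestedCV(list(net = net, covariates = cov, labels = labels,
                            blocks = blocks),
                       list(algorithm = "LR", variables = mj$variables),
                       plan)
    rp <- file.path(out_dir, "cv_report.csv")
    utils::write.csv(res$splits, rp, row.names = FALSE, quote = FALSE, na = "")
    sp <- file.path(out_dir, "cv_summary.json")
    jsonlite::write_json(list(mean_mcc = res$mean_mcc,
                              mean_mae_m = res$mean_mae_m,
                              n_splits = nrow(res$splits),
                              seed = cfg$seed),
                         sp, auto_unbox = TRUE, digits = NA, na = "null")
    .log("info", "mean MCC = ", sprintf("%.4f", res$mean_mcc),
         verbosity = verb)
    written <- c(rp, sp)
  } else if (command == "compare") {
    inp <- readReachTable(.cfgPath(cfg, "reaches", out_dir, TRUE))
    la <- utils::read.csv(.cfgPath(cfg, "limits_a", out_dir, TRUE),
                          colClasses = c(reach_id = "character",
                                         path_id = "character"))
    lb <- utils::read.csv(.cfgPath(cfg, "limits_b", out_dir, TRUE),
                          colClasses = c(reach_id = "character",
                                         path_id = "character"))
    res <- compareLimitSets(inp$network, la, lb)
    cp <- file.path(out_dir, "comparison.csv")
    utils::write.csv(res$per_path, cp, row.names = FALSE, quote = FALSE,
                     na = "")
    written <- cp
  }
  invisible(list(written = written))
}
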