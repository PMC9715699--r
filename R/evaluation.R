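# Metrics, nested spatial cross-validation, model explanation, and
# limit-set comparison.

#' Confusion counts from binary vectors
#'
#' @param predicted,actual logical (or 0/1) vectors of equal length
#' @return named integer vector with elements `TP`, `TN`, `FP`, `FN`
#' @export
confusionCounts <- function(predicted, actual) {
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  ok <- !is.na(predicted) & !is.na(actual)
  predicted <- predicted[ok]; actual <- actual[ok]
  c(TP = sum(predicted & actual),
    TN = sum(!predicted & !actual),
    FP = sum(predicted & !actual),
    FN = sum(!predicted & actual))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\].
#' By convention the value is 0 whenever any marginal total is zero (the
#' coefficient is then undefined as a correlation).
#'
#' @param counts named vector/list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusionCounts()])
#' @return numeric in \[-1, 1\]
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  if (tp + tn + fp + fn == 0) stop("all-zero confusion counts")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

## ---- limit pairing and MAE ----------------------------------------------

# pair limit rows by flow path: for each reference row (with path_id =
# headwater reach id), find the unique row of `other` whose host reach lies
# on that headwater's path
.pairLimits <- function(net, reference, other) {
  y <- distanceToOutlet(net, reference)
  top <- numeric(nrow(reference))
  x <- rep(NA_real_, nrow(reference))
  other_dist <- if (nrow(other)) distanceToOutlet(net, other) else numeric(0)
  for (k in seq_len(nrow(reference))) {
    leaf <- reference$path_id[k]
    li <- .reachIdx(net, leaf)
    path <- net@reaches$reach_id[.pathToOutletIdx(net, li)]
    top[k] <- net@distDown[li] + net@reaches$length_m[li]
    hit <- which(other$reach_id %in% path)
    # several limits can sit on one flow path's reaches when tributary
    # boundaries fall at confluences; the path's own boundary is the
    # most-upstream one
    if (length(hit)) x[k] <- max(other_dist[hit])
  }
  data.frame(path_id = reference$path_id, y_m = y, x_m = x,
             path_top_m = top, stringsAsFactors = FALSE)
}

#' Along-network mean absolute error between limit sets
#'
#' Pairs observed and predicted upper-limit points by headwater flow path
#' and averages the absolute difference of their linear stream distances to
#' the outlet (m).  Observed paths with no predicted limit either
#' contribute the distance from the observed limit to the top of the path
#' (`unpaired = "top"`, default) or are excluded and reported.
#'
#' @param net a [StreamNetwork-class]
#' @param observed data.frame of observed limits with `path_id`,
#'   `reach_id`, `offset_m`
#' @param predicted data.frame of predicted limits (e.g. from
#'   [findUpperLimits()])
#' @param unpaired `"top"` or `"exclude"`
#' @return list: `mae_m`, `n`, `pairs` (per-path table with `y_m`
#'   observed and `x_m` predicted distances), `n_unpaired`
#' @export
maeUpperLimit <- function(net, observed, predicted,
                          unpaired = c("top", "exclude")) {
  unpaired <- match.arg(unpaired)
  if (!nrow(observed)) stop("zero observed limit points")
  pairs <- .pairLimits(net, observed, predicted)
  pairs$abs_err_m <- abs(pairs$y_m - pairs$x_m)
  miss <- is.na(pairs$x_m)
  if (unpaired == "top")
    pairs$abs_err_m[miss] <- pairs$path_top_m[miss] - pairs$y_m[miss]
  use <- !is.na(pairs$abs_err_m)
  if (!any(use)) stop("zero paired limit points")
  list(mae_m = mean(pairs$abs_err_m[use]), n = sum(use),
       pairs = pairs, n_unpaired = sum(miss))
}

## ---- cross-validation ----------------------------------------------------

#' Build a repeated spatial-block cross-validation plan
#'
#' Randomly partitions spatial blocks into folds for each repeat, balanced
#' to within one block, fully determined by the seed.
#'
#' @param blocks character block ids
#' @param repeats,folds plan dimensions (defaults 5 and 5)
#' @param seed integer seed
#' @return a [CVPlan-class]
#' @export
makeCVPlan <- function(blocks, repeats = 5, folds = 5, seed) {
  blocks <- as.character(unique(blocks))
  n <- length(blocks)
  if (n < folds)
    stop("fewer blocks (", n, ") than folds (", folds, ")")
  set.seed(as.integer(seed))
  rows <- vector("list", repeats)
  sizes <- rep(n %/% folds, folds) + (seq_len(folds) <= n %% folds)
  for (r in seq_len(repeats)) {
    perm <- sample(blocks)
    rows[[r]] <- data.frame(block = perm,
                            repeat_id = r,
                            fold = rep(seq_len(folds), times = sizes),
                            stringsAsFactors = FALSE)
  }
  new("CVPlan", repeats = as.integer(repeats), folds = as.integer(folds),
      assignment = do.call(rbind, rows), seed = as.integer(seed))
}

#' Nested spatial cross-validation of a presence sub-model
#'
#' For every repeat-by-fold split of the plan: balances the training
#' blocks, fits the sub-model (with an inner tuning loop for random
#' forests only), and scores the held-out blocks with MCC; optionally runs
#' a stopping rule on the resulting probability field and computes the
#' along-network MAE against observed limits in the held-out blocks.  An
#' internal audit asserts that no reach from a test block ever enters the
#' corresponding training set.
#'
#' @param data list with `net` (a [StreamNetwork-class]), `covariates`
#'   (data.frame with `reach_id`), `labels` (from [propagateLabels()]),
#'   and `blocks` (named character reach id -> block id)
#' @param model_spec list: `algorithm` (`"LR"`/`"RF"`), `variables`,
#'   optional `penalty`
#' @param plan a [CVPlan-class]
#' @param stopping optional [StoppingRuleConfig-class]
#' @param observed_limits optional observed limit data.frame (needed for
#'   MAE; limits are attributed to blocks through their host reach)
#' @return list: `splits` (one row per repeat x fold: mcc, mae_m, n_test),
#'   `mean_mcc`, `mean_mae_m` (mean of per-split MAEs), `pooled_mae_m`
#'   (over all pairs), `plan`
#' @export
runNestedCV <- function(data, model_spec, plan, stopping = NULL,
                        observed_limits = NULL) {
  net <- data$net
  cov <- as.data.frame(data$covariates)
  labels <- data$labels
  blocks <- data$blocks
  vars <- model_spec$variables
  algorithm <- model_spec$algorithm
  labels$block <- as.character(blocks[labels$reach_id])
  if (anyNA(labels$block)) stop("labelled reach without a block")
  if (length(unique(labels$block[labels$label == "trout"])) < 2L ||
      length(unique(labels$block[labels$label == "no_trout"])) < 2L)
    stop("labels must span at least two blocks per class")
  obs_block <- NULL
  if (!is.null(observed_limits))
    obs_block <- as.character(blocks[observed_limits$reach_id])

  set.seed(plan@seed)
  subseed <- sample.int(.Machine$integer.max %/% 2L,
                        plan@repeats * plan@folds)
  cov_idx <- match(labels$reach_id, cov$reach_id)
  if (anyNA(cov_idx)) stop("labelled reach missing from covariate table")

  rows <- list(); all_pairs <- list(); s_i <- 0L
  for (r in seq_len(plan@repeats)) {
    ar <- plan@assignment[plan@assignment$repeat_id == r, ]
    for (f in seq_len(plan@folds)) {
      s_i <- s_i + 1L
      test_blocks <- ar$block[ar$fold == f]
      is_test <- labels$block %in% test_blocks
      train_labels <- labels[!is_test, , drop = FALSE]
      test_labels <- labels[is_test, , drop = FALSE]
      bal <- suppressWarnings(
        balanceClasses(train_labels, blocks, seed = subseed[s_i]))
      # leakage audit: balanced training reaches vs held-out reaches
      if (length(intersect(bal$reach_id, test_labels$reach_id)))
        stop("cross-validation leakage: training and test reaches overlap")
      Xtr <- cov[match(bal$reach_id, cov$reach_id), vars, drop = FALSE]
      ytr <- as.integer(bal$label == "trout")
      keep <- stats::complete.cases(Xtr)
      model <- if (algorithm == "LR")
        suppressWarnings(fitLogistic(Xtr[keep, , drop = FALSE], ytr[keep],
                                     penalty = model_spec$penalty %||% "none"))
      else
        fitRandomForest(Xtr[keep, , drop = FALSE], ytr[keep],
                        seed = subseed[s_i])
      Xte <- cov[match(test_labels$reach_id, cov$reach_id), vars,
                 drop = FALSE]
      ph <- predictProbability(model, Xte)
      m <- mcc(confusionCounts(ph >= 0.5, test_labels$label == "trout"))

      mae_m <- NA_real_; n_pairs <- NA_integer_
      if (!is.null(stopping) && !is.null(observed_limits)) {
        pfull <- predictProbability(model, cov)
        names(pfull) <- cov$reach_id
        lim <- findUpperLimits(net, pfull, stopping)
        obs_f <- observed_limits[obs_block %in% test_blocks, , drop = FALSE]
        if (nrow(obs_f)) {
          res <- maeUpperLimit(net, obs_f, lim$limits)
          mae_m <- res$mae_m; n_pairs <- res$n
          pp <- res$pairs; pp$repeat_id <- r; pp$fold <- f
          all_pairs[[length(all_pairs) + 1L]] <- pp
        }
      }
      rows[[s_i]] <- data.frame(repeat_id = r, fold = f, mcc = m,
                                mae_m = mae_m, n_test = nrow(test_labels),
                                n_pairs = n_pairs)
    }
  }
  splits <- do.call(rbind, rows)
  pooled <- NA_real_
  if (length(all_pairs)) {
    pl <- do.call(rbind, all_pairs)
    pooled <- mean(pl$abs_err_m, na.rm = TRUE)
  }
  list(splits = splits,
       mean_mcc = mean(splits$mcc),
       mean_mae_m = if (all(is.na(splits$mae_m))) NA_real_
                    else mean(splits$mae_m, na.rm = TRUE),
       pooled_mae_m = pooled,
       plan = plan)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- model explanation ---------------------------------------------------

#' Partial-dependence profile of one covariate
#'
#' For each grid value, clamps the covariate to that value across the data
#' and averages the model's predicted probabilities.
#'
#' @param model a [PresenceModel-class]
#' @param covariates covariate data.frame
#' @param variable covariate name (must be in the model)
#' @param grid numeric grid values
#' @return data.frame with `value` and `mean_prob`
#' @export
partialDependence <- function(model, covariates, variable, grid) {
  if (!variable %in% model@variables)
    stop("variable '", variable, "' is not in the model")
  covariates <- as.data.frame(covariates)
  mp <- vapply(grid, function(v) {
    cc <- covariates
    cc[[variable]] <- v
    mean(predictProbability(model, cc), na.rm = TRUE)
  }, numeric(1))
  data.frame(value = grid, mean_prob = mp)
}

#' Permutation importance on MCC
#'
#' Shuffles each covariate column within the data and measures the mean
#' drop in MCC (at a 0.5 threshold) relative to the unpermuted baseline.
#'
#' @param model a [PresenceModel-class]
#' @param covariates covariate data.frame
#' @param labels binary response aligned to the covariate rows
#' @param n_permutations permutations per variable (must be >= 1)
#' @param seed integer seed
#' @return named numeric mean MCC drop per model variable, decreasing
#' @export
permutationImportance <- function(model, covariates, labels,
                                  n_permutations = 10, seed = 1) {
  if (n_permutations < 1L)
    stop("n_permutations must be >= 1")
  covariates <- as.data.frame(covariates)
  y <- .asBinary(labels)
  base_p <- predictProbability(model, covariates)
  baseline <- mcc(confusionCounts(base_p >= 0.5, y == 1))
  set.seed(as.integer(seed))
  drops <- vapply(model@variables, function(v) {
    d <- numeric(n_permutations)
    for (k in seq_len(n_permutations)) {
      cc <- covariates
      cc[[v]] <- sample(cc[[v]])
      p <- predictProbability(model, cc)
      d[k] <- baseline - mcc(confusionCounts(p >= 0.5, y == 1))
    }
    mean(d)
  }, numeric(1))
  sort(drops, decreasing = TRUE)
}

## ---- limit comparison and summaries --------------------------------------

#' Signed along-network comparison of two limit sets
#'
#' Pairs limits by flow path and reports the signed distance of each
#' `other` limit relative to the `reference` limit: positive values lie
#' upstream of the reference (overestimation of the fish-bearing extent),
#' negative values downstream.
#'
#' @param net a [StreamNetwork-class]
#' @param reference,other limit data.frames with `path_id`, `reach_id`,
#'   `offset_m`
#' @return list: `per_path` (path_id, signed_m) and `summary` (n pairs,
#'   counts upstream/downstream/equal, mean and median signed distance)
#' @export
compareLimitSets <- function(net, reference, other) {
  pairs <- .pairLimits(net, reference, other)
  pairs$signed_m <- pairs$x_m - pairs$y_m
  ok <- !is.na(pairs$signed_m)
  if (!any(ok)) stop("no limits on common flow paths")
  s <- pairs$signed_m[ok]
  list(per_path = pairs[, c("path_id", "signed_m")],
       summary = data.frame(n = sum(ok),
                            n_upstream = sum(s > 0),
                            n_downstream = sum(s < 0),
                            n_equal = sum(s == 0),
                            mean_signed_m = mean(s),
                            median_signed_m = stats::median(s)))
}

#' Summarize classified stream length by category
#'
#' Sums classified stream length (km) and counts upper-limit points per
#' reach category (e.g. land ownership).  Lengths conserve the network
#' total across categories and classes.
#'
#' @param net a [StreamNetwork-class]
#' @param classification named character per reach (`trout` / `no_trout` /
#'   `no_prediction`), as returned by [findUpperLimits()]
#' @param limits limit data.frame (host `reach_id` determines the
#'   category a limit is counted in)
#' @param category optional named character reach id -> label; defaults to
#'   the network's `category` column
#' @return data.frame: category, trout_km, no_trout_km, no_prediction_km,
#'   limit_count
#' @export
summarizeByCategory <- function(net, classification, limits,
                                category = NULL) {
  rr <- net@reaches
  cls <- as.character(classification[rr$reach_id])
  if (anyNA(cls)) stop("classification must cover every reach")
  cat_v <- if (is.null(category)) rr$category
           else as.character(category[rr$reach_id])
  if (anyNA(cat_v)) stop("every reach must be categorized")
  km <- rr$length_m / 1000
  agg <- function(which_cls)
    vapply(split(km[cls == which_cls], cat_v[cls == which_cls]), sum, 0)
  cats <- sort(unique(cat_v))
  pick <- function(x) ifelse(cats %in% names(x), x[cats], 0)
  lim_cat <- if (nrow(limits))
    table(cat_v[match(limits$reach_id, rr$reach_id)]) else table(character(0))
  out <- data.frame(category = cats,
                    trout_km = pick(agg("trout")),
                    no_trout_km = pick(agg("no_trout")),
                    no_prediction_km = pick(agg("no_prediction")),
                    limit_count = as.integer(pick(lim_cat)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
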