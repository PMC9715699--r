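# Reach-level presence modelling: turn upper-limit observations into
# binomial training labels, balance them within spatial blocks, and fit /
# apply presence sub-models.

#' Construct an observation set
#'
#' Upper-limit observations are network points of kind `"O"` (uppermost
#' fish occurrence) or `"H"` (nearest upstream habitat barrier), each with
#' a spatial block id and, optionally, the headwater reach id of the
#' surveyed flow path.
#'
#' @param points data.frame from [networkPoint()] (columns `reach_id`,
#'   `offset_m`)
#' @param kind character vector of `"O"`/`"H"`
#' @param block character vector of block ids
#' @param path_id optional character vector of headwater reach ids
#'   identifying the surveyed path (NA = follow the larger-drainage branch)
#' @return data.frame with class columns for the observation set
#' @export
observationSet <- function(points, kind, block, path_id = NA_character_) {
  if (!all(kind %in% c("O", "H")))
    stop("observation kind must be 'O' or 'H'")
  data.frame(reach_id = points$reach_id, offset_m = points$offset_m,
             kind = kind, block = as.character(block),
             path_id = as.character(path_id), stringsAsFactors = FALSE)
}

#' Propagate binomial labels from upper-limit observations
#'
#' For each observation of the requested kind, every reach on the flow
#' path from the observation down to the outlet is labelled `trout`, and
#' every reach strictly upstream of the observation on the surveyed
#' headwater path is labelled `no_trout`.  Reaches on unsurveyed
#' tributaries stay unlabelled.  When an observation carries no `path_id`,
#' the surveyed path is taken up the larger-drainage-area branch at each
#' confluence.  Contradictory labels (trout vs. no_trout on one reach from
#' two observations of the same kind) raise an error.
#'
#' @param net a [StreamNetwork-class]
#' @param obs an [observationSet()]
#' @param kind `"O"` or `"H"`
#' @return data.frame `reach_id`, `label` (`trout`/`no_trout`), `source`
#'   (index of the generating observation)
#' @export
propagateLabels <- function(net, obs, kind = c("O", "H")) {
  kind <- match.arg(kind)
  obs <- obs[obs$kind == kind, , drop = FALSE]
  if (!nrow(obs)) stop("no observations of kind ", kind)
  rr <- net@reaches
  area <- accumulateDrainageArea(net)
  ups <- .upstreamNeighbors(net)
  lab <- rep(NA_character_, nrow(rr))
  src <- rep(NA_integer_, nrow(rr))

  assign_label <- function(idx, value, o) {
    conflict <- !is.na(lab[idx]) & lab[idx] != value
    if (any(conflict))
      stop("contradictory ", kind, "-labels on reach(es): ",
           paste(rr$reach_id[idx[conflict]], collapse = ", "))
    fresh <- is.na(lab[idx])
    lab[idx[fresh]] <<- value
    src[idx[fresh]] <<- o
  }

  for (o in seq_len(nrow(obs))) {
    i0 <- .reachIdx(net, obs$reach_id[o])
    assign_label(.pathToOutletIdx(net, i0), "trout", o)
    # upstream along the surveyed path
    if (!is.na(obs$path_id[o])) {
      leaf <- .reachIdx(net, obs$path_id[o])
      leaf_path <- .pathToOutletIdx(net, leaf)     # leaf -> outlet
      k <- match(i0, leaf_path)
      if (is.na(k))
        stop("observation ", o, " does not lie on the path of headwater ",
             obs$path_id[o])
      up_idx <- leaf_path[seq_len(k - 1L)]
    } else {
      up_idx <- integer(0)
      cur <- i0
      repeat {
        nxt <- ups[[cur]]
        if (is.null(nxt) || !length(nxt)) break
        cur <- nxt[which.max(area[nxt])]
        up_idx <- c(up_idx, cur)
      }
    }
    if (length(up_idx)) assign_label(up_idx, "no_trout", o)
  }
  keep <- !is.na(lab)
  data.frame(reach_id = rr$reach_id[keep], label = lab[keep],
             source = src[keep], stringsAsFactors = FALSE)
}

#' Balance classes within spatial blocks by undersampling
#'
#' Within every block, the majority class is undersampled without
#' replacement so that trout and no-trout reach counts are equal; the
#' minority class is untouched.  Blocks containing a single class are
#' dropped with a warning.
#'
#' @param labels data.frame from [propagateLabels()]
#' @param block_assignment named character: reach id -> block id
#' @param seed integer seed for the subsampling
#' @return the balanced label data.frame with a `block` column
#' @export
balanceClasses <- function(labels, block_assignment, seed) {
  labels$block <- as.character(block_assignment[labels$reach_id])
  if (anyNA(labels$block))
    stop("block assignment missing for some labelled reaches")
  out <- list()
  dropped <- character(0)
  set.seed(as.integer(seed))
  for (b in sort(unique(labels$block))) {
    lb <- labels[labels$block == b, , drop = FALSE]
    n_t <- sum(lb$label == "trout")
    n_n <- sum(lb$label == "no_trout")
    if (n_t == 0L || n_n == 0L) {
      dropped <- c(dropped, b)
      next
    }
    n_keep <- min(n_t, n_n)
    keep_rows <- function(cls, n_cls) {
      rows <- which(lb$label == cls)
      if (n_cls > n_keep) rows <- sort(sample(rows, n_keep))
      rows
    }
    out[[b]] <- lb[sort(c(keep_rows("trout", n_t), keep_rows("no_trout", n_n))), ]
  }
  if (length(dropped))
    warning("dropped single-class block(s): ", paste(dropped, collapse = ", "))
  if (!length(out))
    stop("no block retains both classes")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- model fitting -------------------------------------------------------

.designMatrix <- function(X, variables) {
  X <- as.data.frame(X)
  miss <- setdiff(variables, names(X))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  as.matrix(X[, variables, drop = FALSE])
}

#' Fit a logistic-regression presence sub-model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary trout/no-trout response on reach covariates, optionally with an
#' L2 (ridge) penalty via glmnet.  Non-convergence and (quasi-)complete
#' separation are detected and recorded in the model metadata, not
#' silently ignored.
#'
#' @param X covariate data.frame/matrix (no undefined values)
#' @param y response: 0/1, logical, or `trout`/`no_trout` labels
#' @param penalty `"none"` (default) or `"L2"`
#' @param lambda ridge penalty weight when `penalty = "L2"`
#' @param max_iter,tol IRLS control
#' @return a [PresenceModel-class] (`algorithm = "LR"`)
#' @export
fitLogistic <- function(X, y, penalty = c("none", "L2"), lambda = 1e-3,
                        max_iter = 50, tol = 1e-8) {
  penalty <- match.arg(penalty)
  y <- .asBinary(y)
  X <- as.data.frame(X)
  X$reach_id <- NULL
  if (anyNA(X) || anyNA(y))
    stop("undefined covariates or labels in training rows")
  if (length(unique(y)) < 2L)
    stop("need at least one case of each class")
  vars <- names(X)

  if (penalty == "L2") {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("penalty = 'L2' needs the glmnet package")
    fit <- glmnet::glmnet(as.matrix(X), y, family = "binomial",
                          alpha = 0, lambda = lambda,
                          maxit = max_iter * 1000, thresh = tol)
    co <- as.numeric(stats::coef(fit))
    names(co) <- c("(Intercept)", vars)
    meta <- list(penalty = "L2", lambda = lambda, n = length(y),
                 converged = TRUE, separation = FALSE, se = NULL,
                 deviance = stats::deviance(fit))
  } else {
    wrn <- character(0)
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial(),
                 control = stats::glm.control(maxit = max_iter, epsilon = tol)),
      warning = function(w) {
        wrn <<- c(wrn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    p <- stats::fitted(fit)
    separation <- any(grepl("fitted probabilities numerically 0 or 1", wrn)) ||
      all(p[y == 1] > 1 - 1e-8) && all(p[y == 0] < 1e-8)
    if (separation)
      warning("complete or quasi-complete separation detected")
    if (!fit$converged)
      warning("IRLS did not converge in ", max_iter, " iterations")
    co <- stats::coef(fit)
    names(co) <- c("(Intercept)", vars)
    meta <- list(penalty = "none", n = length(y),
                 converged = fit$converged, separation = separation,
                 se = sqrt(diag(stats::vcov(fit))),
                 deviance = stats::deviance(fit))
  }
  new("PresenceModel", algorithm = "LR", variables = vars,
      coefficients = co, fit = fit, metadata = meta)
}

.asBinary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("trout", "no_trout")))
      stop("character labels must be 'trout'/'no_trout'")
    as.integer(y == "trout")
  } else {
    as.integer(as.logical(y) | y == 1)
  }
}

#' Fit a random-forest presence sub-model
#'
#' Probability random forest (ranger delegate) with a small hyperparameter
#' grid tuned by an inner cross-validation on MCC, fully seeded.  The
#' fitted model satisfies the same prediction contract as the logistic
#' sub-model.
#'
#' @param X covariate data.frame (no undefined values)
#' @param y binary response as in [fitLogistic()]
#' @param tuning_grid data.frame of `mtry`, `min_node_size` combinations
#'   (default: a small grid around sqrt(p))
#' @param inner_cv number of inner folds (default 3)
#' @param seed integer seed
#' @param num_trees trees per forest (default 300)
#' @return a [PresenceModel-class] (`algorithm = "RF"`)
#' @export
fitRandomForest <- function(X, y, tuning_grid = NULL, inner_cv = 3,
                            seed = 1, num_trees = 300) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("random-forest sub-models need the ranger package; ",
         "logistic-regression functionality is unaffected")
  y <- .asBinary(y)
  X <- as.data.frame(X)
  X$reach_id <- NULL
  if (anyNA(X) || anyNA(y))
    stop("undefined covariates or labels in training rows")
  p <- ncol(X)
  if (is.null(tuning_grid))
    tuning_grid <- expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), max(1L, p %/% 3L)))),
      min_node_size = c(1L, 5L))
  dat <- cbind(.y = factor(y, levels = c(0, 1)), X)

  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(inner_cv), nrow(dat)))
  score <- numeric(nrow(tuning_grid))
  for (g in seq_len(nrow(tuning_grid))) {
    ms <- numeric(inner_cv)
    for (f in seq_len(inner_cv)) {
      tr <- dat[fold != f, , drop = FALSE]
      te <- dat[fold == f, , drop = FALSE]
      rf <- ranger::ranger(.y ~ ., data = tr, probability = TRUE,
                           num.trees = num_trees,
                           mtry = tuning_grid$mtry[g],
                           min.node.size = tuning_grid$min_node_size[g],
                           seed = seed + g * 100 + f, num.threads = 1)
      ph <- stats::predict(rf, te)$predictions[, "1"]
      ms[f] <- mcc(confusionCounts(ph >= 0.5, te$.y == "1"))
    }
    score[g] <- mean(ms)
  }
  best <- which.max(score)
  rf <- ranger::ranger(.y ~ ., data = dat, probability = TRUE,
                       num.trees = num_trees,
                       mtry = tuning_grid$mtry[best],
                       min.node.size = tuning_grid$min_node_size[best],
                       seed = seed, num.threads = 1)
  new("PresenceModel", algorithm = "RF", variables = names(X),
      coefficients = numeric(0), fit = rf,
      metadata = list(seed = seed, n = nrow(dat),
                      mtry = tuning_grid$mtry[best],
                      min_node_size = tuning_grid$min_node_size[best],
                      inner_cv_mcc = score[best]))
}

#' Predict per-reach presence probability
#'
#' Applies a fitted presence sub-model to a covariate table.  Reaches with
#' any undefined model covariate get `NA` ("no prediction"); all other
#' reaches get a probability in (0, 1).
#'
#' @param model a [PresenceModel-class]
#' @param covariates data.frame with the model's variables (a `reach_id`
#'   column, if present, names the result)
#' @return named numeric probabilities with NA for no-prediction reaches
#' @export
predictProbability <- function(model, covariates) {
  covariates <- as.data.frame(covariates)
  ids <- covariates$reach_id
  M <- .designMatrix(covariates, model@variables)
  ok <- stats::complete.cases(M)
  p <- rep(NA_real_, nrow(M))
  if (any(ok)) {
    if (model@algorithm == "LR") {
      eta <- model@coefficients[1L] +
        as.numeric(M[ok, , drop = FALSE] %*% model@coefficients[-1L])
      p[ok] <- stats::plogis(eta)
    } else {
      nd <- as.data.frame(M[ok, , drop = FALSE])
      p[ok] <- stats::predict(model@fit, nd)$predictions[, "1"]
    }
  }
  if (!is.null(ids)) names(p) <- ids
  p
}

#' Greedy-forward variable selection by cross-validated MCC
#'
#' Adds, at each step, the candidate variable whose addition maximizes the
#' mean cross-validated MCC over the supplied spatial plan; stops when no
#' addition improves the mean MCC by more than `tol` or when `max_vars`
#' is reached.  The full step trace is returned.
#'
#' @param candidates character candidate variable names
#' @param data list with `X` (covariate data.frame), `y` (binary response)
#'   and `block` (block id per row)
#' @param algorithm `"LR"` or `"RF"`
#' @param cv a [CVPlan-class] over the blocks in `data$block`
#' @param max_vars maximum variables to keep (default: all)
#' @param tol minimum mean-MCC improvement to continue (default 0.005)
#' @param seed seed for RF fits (ignored for LR)
#' @return list with `selected` (ordered names) and `trace` (one row per
#'   accepted step: variable, mean MCC)
#' @export
selectVariables <- function(candidates, data, algorithm = c("LR", "RF"),
                            cv, max_vars = length(candidates), tol = 0.005,
                            seed = 1) {
  algorithm <- match.arg(algorithm)
  if (!length(candidates)) stop("empty candidate list")
  selected <- character(0)
  best_mcc <- -Inf
  trace <- data.frame(step = integer(0), variable = character(0),
                      mean_mcc = numeric(0))
  while (length(selected) < max_vars) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    step_mcc <- vapply(remaining, function(v) {
      .cvMeanMCC(c(selected, v), data, algorithm, cv, seed)
    }, numeric(1))
    v_best <- remaining[which.max(step_mcc)]
    gain <- max(step_mcc) - max(best_mcc, 0)
    if (length(selected) > 0L && gain <= tol) break
    if (length(selected) == 0L && max(step_mcc) <= tol) {
      # not even the first variable beats a no-skill model
      break
    }
    selected <- c(selected, v_best)
    best_mcc <- max(step_mcc)
    trace <- rbind(trace, data.frame(step = length(selected),
                                     variable = v_best,
                                     mean_mcc = best_mcc))
  }
  list(selected = selected, trace = trace)
}

.cvMeanMCC <- function(vars, data, algorithm, cv, seed) {
  a <- cv@assignment
  ms <- numeric(0)
  for (r in seq_len(cv@repeats)) {
    ar <- a[a$repeat_id == r, ]
    for (f in seq_len(cv@folds)) {
      test_blocks <- ar$block[ar$fold == f]
      te <- data$block %in% test_blocks
      if (!any(te) || all(te)) next
      Xtr <- data$X[!te, vars, drop = FALSE]
      ytr <- data$y[!te]
      if (length(unique(ytr)) < 2L) next
      m <- if (algorithm == "LR")
        suppressWarnings(fitLogistic(Xtr, ytr))
      else
        fitRandomForest(Xtr, ytr, seed = seed + r * 10 + f)
      ph <- predictProbability(m, data$X[te, vars, drop = FALSE])
      ms <- c(ms, mcc(confusionCounts(ph >= 0.5, data$y[te] == 1)))
    }
  }
  if (!length(ms)) return(-Inf)
  mean(ms)
}
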