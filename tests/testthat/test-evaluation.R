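test_that("MCC matches its closed form and degenerate conventions", {
  expect_equal(mcc(c(TP = 10, TN = 10, FP = 0, FN = 0)), 1)
  expect_equal(mcc(c(TP = 4, FP = 1, TN = 3, FN = 2)), 10 / sqrt(600))
  expect_equal(mcc(c(TP = 0, FP = 0, TN = 5, FN = 3)), 0)
  # symmetry under simultaneous class swap
  cc <- c(TP = 7, TN = 2, FP = 3, FN = 1)
  expect_equal(mcc(cc), mcc(c(TP = 2, TN = 7, FP = 1, FN = 3)))
  expect_error(mcc(c(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")
  # equals the Pearson correlation of the binary vectors
  set.seed(3)
  for (i in 1:20) {
    pred <- rbinom(40, 1, 0.5)
    act <- rbinom(40, 1, 0.5)
    cc <- confusionCounts(pred == 1, act == 1)
    r <- suppressWarnings(cor(pred, act))
    if (!is.na(r)) expect_equal(mcc(cc), r, tolerance = 1e-12)
  }
})

test_that("upper-limit MAE averages along-network absolute errors by path", {
  net <- combNetwork()
  obs <- rbind(combLimit(net, 1, 1000), combLimit(net, 2, 2000),
               combLimit(net, 3, 3000))
  pred <- rbind(combLimit(net, 1, 900), combLimit(net, 2, 2100),
                combLimit(net, 3, 3300))
  res <- maeUpperLimit(net, obs, pred)
  expect_equal(res$mae_m, mean(c(100, 100, 300)), tolerance = 1e-9)
  expect_equal(res$n, 3)
  # identical limits -> 0; single pair
  expect_equal(maeUpperLimit(net, obs, obs)$mae_m, 0)
  expect_equal(maeUpperLimit(net, combLimit(net, 1, 500),
                             combLimit(net, 1, 800))$mae_m, 300)
  # datum shift: moving both sets upstream equally leaves MAE unchanged
  obs2 <- rbind(combLimit(net, 1, 1100), combLimit(net, 2, 2100),
                combLimit(net, 3, 3100))
  pred2 <- rbind(combLimit(net, 1, 1000), combLimit(net, 2, 2200),
                 combLimit(net, 3, 3400))
  expect_equal(maeUpperLimit(net, obs2, pred2)$mae_m, res$mae_m)
  # unpaired handling
  res3 <- maeUpperLimit(net, obs, pred[1:2, ], unpaired = "exclude")
  expect_equal(res3$n, 2)
  expect_equal(res3$n_unpaired, 1)
  res4 <- maeUpperLimit(net, obs, pred[1:2, ], unpaired = "top")
  expect_equal(res4$n, 3)
  expect_equal(res4$mae_m, mean(c(100, 100, 3610 - 3000)))
})

test_that("CV plans are balanced, seeded partitions of the blocks", {
  blocks <- sprintf("h%02d", 1:21)
  plan <- makeCVPlan(blocks, repeats = 5, folds = 5, seed = 7)
  a <- plan@assignment
  expect_equal(nrow(a), 105)
  for (r in 1:5) {
    ar <- a[a$repeat_id == r, ]
    expect_setequal(ar$block, blocks)
    expect_equal(sort(as.integer(table(ar$fold)), decreasing = TRUE),
                 c(5, 4, 4, 4, 4))
  }
  expect_identical(makeCVPlan(blocks, 5, 5, seed = 7)@assignment, a)
  expect_false(identical(makeCVPlan(blocks, 5, 5, seed = 8)@assignment, a))
  expect_error(makeCVPlan(sprintf("h%d", 1:4), folds = 5, seed = 1),
               "fewer blocks")
})

test_that("nested spatial CV is leak-free and spans all repeat-fold splits", {
  cfg <- generatorConfig(seed = 2)
  net <- generateNetwork(cfg)
  cov <- simulateCovariates(net, cfg)
  truth <- simulateOccupancy(net, cov, cfg@beta, seed = 3)
  rr <- reaches(net)
  blocks <- stats::setNames(rr$block, rr$reach_id)
  labels <- data.frame(reach_id = rr$reach_id,
                       label = ifelse(truth$prob >= 0.5, "trout",
                                      "no_trout"))
  core <- c("upstream_length_km", "log_drainage_area",
            "downstream_slope_pct", "elev_norm")
  plan <- makeCVPlan(unique(rr$block), repeats = 2, folds = 4, seed = 5)
  res <- suppressWarnings(
    runNestedCV(list(net = net, covariates = cov, labels = labels,
                     blocks = blocks),
                list(algorithm = "LR", variables = core), plan))
  expect_equal(nrow(res$splits), 8)
  expect_equal(res$mean_mcc, mean(res$splits$mcc))
  expect_gt(res$mean_mcc, 0.8)
  # shuffling labels across the network destroys the signal
  set.seed(6)
  labels2 <- labels
  labels2$label <- sample(labels$label)
  res2 <- suppressWarnings(
    runNestedCV(list(net = net, covariates = cov, labels = labels2,
                     blocks = blocks),
                list(algorithm = "LR", variables = core), plan))
  expect_lt(abs(res2$mean_mcc), 0.2)
})

test_that("partial dependence reproduces the inverse-logit curve exactly", {
  m <- new("PresenceModel", algorithm = "LR", variables = "x",
           coefficients = c("(Intercept)" = 0, x = 1.3),
           fit = NULL, metadata = list())
  dat <- data.frame(x = rnorm(50))
  grid <- seq(-3, 3, by = 0.5)
  pd <- partialDependence(m, dat, "x", grid)
  expect_equal(pd$mean_prob, plogis(1.3 * grid), tolerance = 1e-9)
  expect_equal(partialDependence(m, dat, "x", 0)$mean_prob, 0.5)
  # constant (zero-slope) model is flat
  m0 <- new("PresenceModel", algorithm = "LR", variables = "x",
            coefficients = c("(Intercept)" = 0.4, x = 0),
            fit = NULL, metadata = list())
  pd0 <- partialDependence(m0, dat, "x", grid)
  expect_equal(diff(range(pd0$mean_prob)), 0)
  expect_error(partialDependence(m, dat, "z", grid), "not in the model")
})

test_that("permutation importance separates signal from nuisance", {
  set.seed(41)
  n <- 5000
  X <- data.frame(signal = rnorm(n), nuisance = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$signal))
  m <- fitLogistic(X, y)
  imp <- permutationImportance(m, X, y, n_permutations = 5, seed = 2)
  expect_equal(names(imp)[1], "signal")
  expect_lt(abs(imp[["nuisance"]]), 0.05)
  expect_gt(imp[["signal"]], 0.2)
  expect_error(permutationImportance(m, X, y, n_permutations = 0),
               "n_permutations")
})

test_that("limit-set comparison reports signed upstream distances", {
  net <- combNetwork()
  ref <- rbind(combLimit(net, 1, 1000), combLimit(net, 2, 2000))
  other <- rbind(combLimit(net, 1, 1200), combLimit(net, 2, 1700))
  res <- compareLimitSets(net, ref, other)
  expect_equal(res$per_path$signed_m, c(200, -300))
  expect_equal(res$summary$n_upstream, 1)
  expect_equal(res$summary$n_downstream, 1)
  same <- compareLimitSets(net, ref, ref)
  expect_true(all(same$per_path$signed_m == 0))
})

test_that("category summaries conserve total stream length", {
  net <- smallTree(12)
  rr <- reaches(net)
  p <- stats::setNames(runif(nrow(rr)), rr$reach_id)
  res <- findUpperLimits(net, p, stoppingRuleConfig("SR3"))
  sm <- summarizeByCategory(net, res$classification, res$limits)
  expect_equal(sum(sm$trout_km + sm$no_trout_km + sm$no_prediction_km),
               sum(rr$length_m) / 1000, tolerance = 1e-6)
  expect_equal(sum(sm$limit_count), nrow(res$limits))
  # all-trout classification leaves the fishless column empty
  all_trout <- stats::setNames(rep("trout", nrow(rr)), rr$reach_id)
  sm2 <- summarizeByCategory(net, all_trout, res$limits[0, ])
  expect_true(all(sm2$no_trout_km == 0))
})
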