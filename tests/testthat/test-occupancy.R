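test_that("labels propagate down to the outlet and up the surveyed path", {
  net <- chainNetwork(rep(10, 10))
  # limit at the top of reach 6
  obs <- observationSet(networkPoint("c006", 10), "O", "b1", path_id = "c010")
  lab <- propagateLabels(net, obs, "O")
  got <- stats::setNames(lab$label, lab$reach_id)
  expect_equal(unname(got[sprintf("c%03d", 1:6)]), rep("trout", 6))
  expect_equal(unname(got[sprintf("c%03d", 7:10)]), rep("no_trout", 4))

  # limit at the outlet's downstream end: one trout reach, rest fishless
  obs2 <- observationSet(networkPoint("c001", 0), "O", "b1", path_id = "c010")
  lab2 <- propagateLabels(net, obs2, "O")
  expect_equal(sum(lab2$label == "trout"), 1)
  expect_equal(sum(lab2$label == "no_trout"), 9)

  # Y network: observation on the left branch leaves the right unlabelled
  y <- buildNetwork(yRecords())
  lab3 <- propagateLabels(net = y,
                          obs = observationSet(networkPoint("hL", 5), "O", "b"),
                          kind = "O")
  expect_false("hR" %in% lab3$reach_id)
  expect_setequal(lab3$reach_id, c("out", "hL"))

  # contradictory observations of one kind raise
  bad <- observationSet(networkPoint(c("c002", "c006"), c(10, 10)),
                        c("O", "O"), c("b1", "b1"),
                        path_id = c("c010", "c010"))
  expect_error(propagateLabels(net, bad, "O"), "contradictory")
})

test_that("label topology: trout sorts below no_trout along any labelled path", {
  net <- smallTree(6)
  truth <- simulateOccupancy(net, simulateCovariates(
    net, generatorConfig(seed = 6)), generatorConfig()@beta, seed = 7)
  obs <- sampleObservations(truth, 25, seed = 8)
  lab <- propagateLabels(net, obs, "O")
  # on each surveyed path, every trout reach lies below every no_trout
  # reach
  for (leaf in unique(obs$path_id)) {
    p <- pathBetween(net, networkPoint(outletReach(net), 0),
                     networkPoint(leaf, 0))
    onp <- lab[lab$reach_id %in% p, ]
    if (!nrow(onp)) next
    dd <- distanceToOutlet(net, networkPoint(onp$reach_id, 0))
    if (any(onp$label == "trout") && any(onp$label == "no_trout"))
      expect_lt(max(dd[onp$label == "trout"]),
                min(dd[onp$label == "no_trout"]))
  }
})

test_that("class balancing undersamples the majority within each block", {
  labels <- data.frame(
    reach_id = sprintf("r%02d", 1:17),
    label = c(rep("trout", 12), rep("no_trout", 5)))
  blocks <- stats::setNames(rep("b1", 17), labels$reach_id)
  bal <- balanceClasses(labels, blocks, seed = 4)
  expect_equal(unname(table(bal$label)["trout"]), 5L,
               ignore_attr = TRUE)
  expect_equal(unname(table(bal$label)["no_trout"]), 5L,
               ignore_attr = TRUE)
  # the minority class is untouched
  expect_setequal(bal$reach_id[bal$label == "no_trout"],
                  labels$reach_id[labels$label == "no_trout"])
  # already balanced -> unchanged; determinism under one seed
  bal2 <- balanceClasses(bal[, c("reach_id", "label")], blocks, seed = 99)
  expect_setequal(bal2$reach_id, bal$reach_id)
  expect_identical(balanceClasses(labels, blocks, seed = 4)$reach_id,
                   bal$reach_id)
  # single-class blocks are dropped with a warning
  labels$block <- NULL
  lab2 <- rbind(labels,
                data.frame(reach_id = "r99", label = "trout"))
  blocks2 <- c(blocks, r99 = "lonely")
  expect_warning(out <- balanceClasses(lab2, blocks2, seed = 1), "lonely")
  expect_false("r99" %in% out$reach_id)
})

test_that("logistic fitting recovers truth and flags degenerate data", {
  # null data: coefficients within 3 SE of zero
  set.seed(10)
  X <- data.frame(a = rnorm(400), b = rnorm(400))
  y <- rbinom(400, 1, 0.5)
  m <- fitLogistic(X, y)
  expect_true(all(abs(m@coefficients) < 3 * m@metadata$se))
  expect_true(m@metadata$converged)

  # simulation from known coefficients at n = 20,000: within 10 percent
  set.seed(11)
  n <- 20000
  X2 <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(-2, 1.5, -0.8)
  y2 <- rbinom(n, 1, plogis(beta[1] + beta[2] * X2$x1 + beta[3] * X2$x2))
  m2 <- fitLogistic(X2, y2)
  expect_true(all(abs(m2@coefficients - beta) / abs(beta) < 0.10))

  # perfectly separated toy data is flagged, not silently accepted
  Xs <- data.frame(x = c(-2, -1, 1, 2))
  expect_warning(ms <- fitLogistic(Xs, c(0, 0, 1, 1)), "separation")
  expect_true(ms@metadata$separation)

  expect_error(fitLogistic(data.frame(x = c(1, NA)), c(0, 1)), "undefined")
  expect_error(fitLogistic(data.frame(x = c(1, 2)), c(1, 1)), "each class")
})

test_that("prediction applies the inverse logit with no-prediction semantics", {
  m <- new("PresenceModel", algorithm = "LR", variables = c("x"),
           coefficients = c("(Intercept)" = 0, x = 1),
           fit = NULL, metadata = list())
  tab <- data.frame(reach_id = c("a", "b", "c"),
                    x = c(0, log(3), NA))
  p <- predictProbability(m, tab)
  expect_equal(unname(p[c("a", "b")]), c(0.5, 0.75))
  expect_true(is.na(p[["c"]]))
  expect_error(predictProbability(m, data.frame(z = 1)), "missing covariate")
  # monotone in a fixed-sign coefficient
  grid <- data.frame(x = seq(-4, 4, by = 0.25))
  expect_true(all(diff(predictProbability(m, grid)) > 0))
})

test_that("random forests honour the shared prediction contract", {
  set.seed(21)
  n <- 1500
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y_sig <- as.integer(X$x1 + 0.5 * X$x2 + rnorm(n, 0, 0.3) > 0)
  rf <- fitRandomForest(X, y_sig, seed = 5, num_trees = 150)
  p <- predictProbability(rf, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(!is.null(rf@metadata$mtry))
  # strong signal: good out-of-fold skill on fresh data
  Xn <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  yn <- as.integer(Xn$x1 + 0.5 * Xn$x2 + rnorm(n, 0, 0.3) > 0)
  pn <- predictProbability(rf, Xn)
  expect_gt(mcc(confusionCounts(pn >= 0.5, yn == 1)), 0.8)
  # pure-noise labels: no skill
  set.seed(22)
  y_noise <- rbinom(n, 1, 0.5)
  rf2 <- fitRandomForest(X, y_noise, seed = 6, num_trees = 150)
  p2 <- predictProbability(rf2, Xn)
  expect_lt(abs(mcc(confusionCounts(p2 >= 0.5, rbinom(n, 1, 0.5) == 1))),
            0.1)
})

test_that("greedy forward selection finds the informative variable", {
  set.seed(31)
  n <- 900
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- c("signal", paste0("noise", 1:5))
  y <- rbinom(n, 1, plogis(2 * X$signal))
  block <- rep(sprintf("b%02d", 1:10), length.out = n)
  plan <- makeCVPlan(unique(block), repeats = 1, folds = 5, seed = 2)
  sel <- selectVariables(names(X), list(X = X, y = y, block = block),
                         algorithm = "LR", cv = plan, max_vars = 3)
  expect_equal(sel$selected[1], "signal")
  # max_vars = 1 keeps exactly one variable
  sel1 <- selectVariables(names(X), list(X = X, y = y, block = block),
                          algorithm = "LR", cv = plan, max_vars = 1)
  expect_length(sel1$selected, 1)
  # all-nuisance candidates stall at no-skill
  y0 <- rbinom(n, 1, 0.5)
  sel0 <- selectVariables(paste0("noise", 1:5),
                          list(X = X, y = y0, block = block),
                          algorithm = "LR", cv = plan)
  expect_lte(length(sel0$selected), 1)
  expect_error(selectVariables(character(0),
                               list(X = X, y = y, block = block),
                               cv = plan), "empty candidate")
})
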