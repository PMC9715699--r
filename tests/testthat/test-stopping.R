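test_that("rolling smoothing shrinks its window at path ends", {
  expect_equal(smoothProbabilities(c(0.9, 0.3, 0.9), 3), c(0.6, 0.7, 0.6))
  v <- runif(10)
  expect_equal(smoothProbabilities(v, 1), v)
  expect_equal(smoothProbabilities(rep(0.4, 7), 5), rep(0.4, 7))
  expect_error(smoothProbabilities(numeric(0), 3), "empty")
  expect_error(smoothProbabilities(v, 4), "odd")
})

test_that("SR2 stops at the most-downstream crossing of the cut point", {
  net <- chainNetwork(rep(10, 5))
  p <- stats::setNames(c(0.9, 0.8, 0.6, 0.4, 0.2), reaches(net)$reach_id)
  res <- findUpperLimits(net, p, stoppingRuleConfig("SR2"))
  expect_equal(unname(res$classification[sprintf("c%03d", 1:5)]),
               c("trout", "trout", "trout", "no_trout", "no_trout"))
  expect_equal(nrow(res$limits), 1)
  expect_equal(res$limits$reach_id, "c003")
  expect_equal(res$limits$dist_to_outlet_m, 30)   # top of the 3rd reach
  # ties at the cut count as presence
  p2 <- stats::setNames(c(0.9, 0.5, 0.4, 0.4, 0.4), reaches(net)$reach_id)
  res2 <- findUpperLimits(net, p2, stoppingRuleConfig("SR2"))
  expect_equal(res2$limits$reach_id, "c002")
})

test_that("the persistence run lets short dips survive", {
  net <- chainNetwork(rep(10, 6))
  p <- stats::setNames(c(0.9, 0.4, 0.6, 0.4, 0.3, 0.2),
                       reaches(net)$reach_id)
  res <- findUpperLimits(net, p,
                         stoppingRuleConfig("SR3", persistence_run = 2))
  expect_equal(res$limits$reach_id, "c003")   # the dip at reach 2 survives
  expect_equal(unname(res$classification[sprintf("c%03d", 1:6)]),
               c(rep("trout", 3), rep("no_trout", 3)))
  # SR2 on the same field stops at the dip
  res2 <- findUpperLimits(net, p, stoppingRuleConfig("SR2"))
  expect_equal(res2$limits$reach_id, "c001")
})

test_that("SR1 with window 1 and a full-tail run reduces to SR2 on monotone paths", {
  net <- chainNetwork(rep(10, 8))
  p <- stats::setNames(seq(0.95, 0.25, length.out = 8),
                       reaches(net)$reach_id)
  sr2 <- findUpperLimits(net, p, stoppingRuleConfig("SR2"))
  k <- sum(p >= 0.5)
  sr1 <- findUpperLimits(net, p, stoppingRuleConfig(
    "SR1", smooth_window = 1, persistence_run = 8 - k))
  expect_equal(sr1$limits$reach_id, sr2$limits$reach_id)
  expect_equal(sr1$classification, sr2$classification)
})

test_that("stopping rules match the exhaustive per-path oracle on random fields", {
  rules <- list(
    SR2 = stoppingRuleConfig("SR2"),
    SR3 = stoppingRuleConfig("SR3", persistence_run = 3),
    SR1 = stoppingRuleConfig("SR1", smooth_window = 5, persistence_run = 3))
  for (s in 1:8) {
    net <- smallTree(100 + s)
    rec <- reaches(net)
    set.seed(1000 + s)
    p <- stats::setNames(runif(nrow(rec)), rec$reach_id)
    paths <- bfLeafPaths(rec)
    for (rn in names(rules)) {
      cfg <- rules[[rn]]
      res <- findUpperLimits(net, p, cfg)
      k <- vapply(paths, function(pp)
        bfStopIndex(unname(p[pp]), rn, cut = cfg@cut_point,
                    run = cfg@persistence_run,
                    window = cfg@smooth_window), integer(1))
      want <- bfClosureClass(paths, k, rec$reach_id)
      expect_equal(res$classification[rec$reach_id], want,
                   info = paste("seed", s, rn))
      # downstream closure of the trout set
      down <- rec$reach_id[match(rec$to_node, rec$from_node)]
      tr <- res$classification == "trout"
      ok <- !is.na(down)
      expect_true(all(res$classification[down[ok]][tr[ok]] == "trout"),
                  info = paste("closure", s, rn))
      # one limit at the top of every maximal trout reach with upstream
      # neighbours; raising the cut never moves a limit upstream
      res_hi <- findUpperLimits(net, p, stoppingRuleConfig(
        rn, cut_point = 0.7, smooth_window = cfg@smooth_window,
        persistence_run = cfg@persistence_run))
      if (nrow(res$limits) && nrow(res_hi$limits)) {
        for (leaf in names(paths)) {
          on_lo <- res$limits$dist_to_outlet_m[
            res$limits$reach_id %in% paths[[leaf]]]
          on_hi <- res_hi$limits$dist_to_outlet_m[
            res_hi$limits$reach_id %in% paths[[leaf]]]
          if (length(on_lo) && length(on_hi))
            expect_lte(max(on_hi), max(on_lo) + 1e-9)
        }
      }
    }
  }
})

test_that("no-prediction reaches pass probability through but never host limits", {
  net <- chainNetwork(rep(10, 6))
  p <- stats::setNames(c(0.9, NA, 0.8, 0.4, NA, 0.2),
                       reaches(net)$reach_id)
  res <- findUpperLimits(net, p, stoppingRuleConfig("SR2"))
  cls <- res$classification
  expect_equal(unname(cls[c("c002", "c005")]),
               c("no_prediction", "no_prediction"))
  # traversal treated c002 as 0.9 (copied from downstream), so the
  # crossing is above c003
  expect_equal(res$limits$reach_id, "c003")
  expect_false(any(res$limits$reach_id %in% c("c002", "c005")))
  expect_error(findUpperLimits(net, stats::setNames(rep(NA_real_, 6),
                                                    reaches(net)$reach_id)),
               "zero reaches")
})

test_that("the slope baseline stops below the lowest steep run", {
  # flat 5 m reaches with one 25 percent, 20 m run just above 100 m;
  # the lowest reach boundary whose 20 m window clears the threshold
  # is exactly 100 m above the outlet
  n <- 60
  lens <- rep(5, n)
  mid <- cumsum(lens) - 2.5
  ramp <- function(m, at) 0.25 * pmin(pmax(m - at, 0), 20)
  net <- chainNetwork(lens, elevs = 50 + ramp(mid, 102.5))
  res <- applySlope20(net, stoppingRuleConfig("SLOPE20"))
  expect_equal(nrow(res$limits), 1)
  expect_equal(res$limits$dist_to_outlet_m, 100)
  # below the run: trout; above: no_trout
  expect_equal(unname(res$classification[["c005"]]), "trout")
  expect_equal(unname(res$classification[["c030"]]), "no_trout")
  # uniform 5 percent: threshold never met, whole path trout, no limit
  net2 <- chainNetwork(rep(5, 40), elevs = (seq_len(40) * 5 - 2.5) * 0.05)
  res2 <- applySlope20(net2, stoppingRuleConfig("SLOPE20"))
  expect_equal(nrow(res2$limits), 0)
  expect_true(all(res2$classification == "trout"))
  # two qualifying runs: the lowest wins
  n3 <- 120
  mid3 <- cumsum(rep(5, n3)) - 2.5
  net3 <- chainNetwork(rep(5, n3),
                       elevs = 50 + ramp(mid3, 102.5) + ramp(mid3, 402.5))
  res3 <- applySlope20(net3, stoppingRuleConfig("SLOPE20"))
  expect_equal(res3$limits$dist_to_outlet_m, 100)
})

test_that("limit types distinguish lateral, midstream and confluence ends", {
  # tributary hR (small) joins mainstem hL (large) above the outlet
  rec <- data.frame(
    reach_id = c("out", "mainA", "mainB", "tribA", "tribB"),
    from_node = c("nj", "nmA", "nmB", "ntA", "ntB"),
    to_node = c("n0", "nj", "nmA", "nj", "ntA"),
    length_m = 10, elev_m = c(5, 10, 15, 10, 15),
    incr_area_km2 = c(1, 5, 5, 0.5, 0.5))
  net <- buildNetwork(rec)
  # limits on the tributary's lowest reach sit within one reach-length of
  # the junction with the larger channel -> lateral
  expect_equal(classifyLimitType(net, networkPoint("tribA", 10)), "lateral")
  expect_equal(classifyLimitType(net, networkPoint("tribA", 5)), "lateral")
  # on the larger branch the junction does not make a limit lateral
  expect_equal(classifyLimitType(net, networkPoint("mainA", 5)),
               "midstream_terminal")
  # exactly at the confluence node on the combined channel
  expect_equal(classifyLimitType(net, networkPoint("out", 10)),
               "confluence_terminal")
  # mid-chain, far from any junction
  expect_equal(classifyLimitType(net, networkPoint("mainB", 5)),
               "midstream_terminal")
})
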