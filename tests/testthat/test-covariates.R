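test_that("drainage area accumulates downstream and conserves mass", {
  net <- chainNetwork(c(5, 5, 5), incr = c(2, 1, 1))   # outlet incr = 2
  a <- accumulateDrainageArea(net)
  expect_equal(unname(a[c("c003", "c002", "c001")]), c(1, 2, 4))
  y <- buildNetwork(yRecords(out_incr = 0.5, head_incr = c(1, 3)))
  expect_equal(unname(accumulateDrainageArea(y)[["out"]]), 4.5)
  # conservation + brute force on random trees
  for (s in c(3, 8)) {
    net <- smallTree(s, n_blocks = 6, n_headwaters = 12,
                     mean_segment_reaches = 8)
    rec <- reaches(net)
    expect_lte(nrow(rec), 300)
    a <- accumulateDrainageArea(net)
    expect_equal(unname(a[[outletReach(net)]]), sum(rec$incr_area_km2),
                 tolerance = 1e-9)
    pick <- rec$reach_id[seq(1, nrow(rec), by = 7)]
    for (r in pick)
      expect_equal(unname(a[[r]]), bfDrainageArea(rec, r), tolerance = 1e-12)
    # non-increasing upstream (strict where siblings contribute)
    down <- match(rec$to_node, rec$from_node)
    ok <- !is.na(down)
    expect_true(all(a[down[ok]] >= a[ok]))
  }
})

test_that("upstream channel length is the stream length above the reach", {
  net <- buildNetwork(yRecords(out_len = 10, head_len = c(10, 10)))
  u <- upstreamChannelLength(net)
  expect_equal(unname(u[c("hL", "hR", "out")]), c(0, 0, 0.020))
  ui <- upstreamChannelLength(net, inclusive = TRUE)
  expect_equal(unname(ui[["out"]]), 0.030)
  net2 <- smallTree(9)
  rec <- reaches(net2)
  u2 <- upstreamChannelLength(net2)
  pick <- rec$reach_id[seq(1, nrow(rec), by = 11)]
  for (r in pick) {
    ids <- bfUpstreamSet(rec, r)
    expect_equal(unname(u2[[r]]),
                 sum(rec$length_m[rec$reach_id %in% ids]) / 1000,
                 tolerance = 1e-12)
  }
})

test_that("downstream slope uses a fixed window and is undefined near the outlet", {
  # uniform 5% profile over 2 km of 10 m reaches
  n <- 200
  net <- chainNetwork(rep(10, n), elevs = (seq_len(n) * 10 - 5) * 0.05)
  s <- downstreamSlope(net, window_m = 1000)
  mid <- distanceToOutlet(net, networkPoint(reaches(net)$reach_id,
                                            reaches(net)$length_m / 2))
  expect_true(all(is.na(s[mid < 1000])))
  expect_equal(unname(s[mid >= 1000]), rep(5, sum(mid >= 1000)),
               tolerance = 1e-9)
  # flat profile -> 0 where defined
  flat <- chainNetwork(rep(10, 150), elevs = rep(100, 150))
  sf <- downstreamSlope(flat, 1000)
  expect_equal(unname(sf[!is.na(sf)]),
               rep(0, sum(!is.na(sf))))
  # a reach 600 m above the outlet has no 1000 m window
  short <- chainNetwork(rep(10, 70), elevs = seq_len(70))
  expect_true(is.na(downstreamSlope(short, 1000)[["c060"]]))
  # shrunken-window variant is defined everywhere
  expect_false(anyNA(downstreamSlope(short, 1000, shrink_at_outlet = TRUE)))
})

test_that("elevation is normalized by the block median", {
  rec <- chainRecords(c(5, 5, 5), elevs = c(100, 200, 300))
  rec$block <- "b1"
  net <- buildNetwork(rec)
  expect_equal(unname(normalizeElevation(net)), c(0.5, 1.0, 1.5))
  # single-reach block and all-equal elevations -> exactly 1
  rec2 <- chainRecords(c(5, 5), elevs = c(50, 50))
  rec2$block <- c("a", "b")
  net2 <- buildNetwork(rec2)
  expect_equal(unname(normalizeElevation(net2)), c(1, 1))
  # zero median errors; subtraction variant handles it
  rec3 <- chainRecords(c(5, 5), elevs = c(0, 0))
  rec3$block <- "z"
  net3 <- buildNetwork(rec3)
  expect_error(normalizeElevation(net3), "zero median")
  expect_equal(unname(normalizeElevation(net3, method = "subtract")), c(0, 0))
})

test_that("patch mean is the upstream area-weighted average", {
  y <- buildNetwork(yRecords(out_incr = 0, head_incr = c(1, 3)))
  v <- c(out = 99, hL = 2, hR = 4)     # self weight 0 at the junction
  pm <- patchMean(y, v)
  expect_equal(unname(pm[["out"]]), 3.5)
  expect_equal(unname(pm[["hL"]]), 2)  # headwater keeps its own value
  # constant field is preserved everywhere, both weightings
  net <- smallTree(13)
  const <- stats::setNames(rep(4.2, nReaches(net)), reaches(net)$reach_id)
  expect_equal(unname(patchMean(net, const)), rep(4.2, nReaches(net)))
  expect_equal(unname(patchMean(net, const, weights = "length")),
               rep(4.2, nReaches(net)))
  # random values against brute force
  rec <- reaches(net)
  set.seed(1)
  vals <- stats::setNames(stats::rnorm(nrow(rec)), rec$reach_id)
  w <- stats::setNames(rec$incr_area_km2, rec$reach_id)
  pm2 <- patchMean(net, vals)
  for (r in rec$reach_id[seq(1, nrow(rec), by = 13)])
    expect_equal(unname(pm2[[r]]), bfPatchMean(rec, r, vals, w),
                 tolerance = 1e-12)
})

test_that("run slopes average the channel immediately upstream", {
  # 25% over the first 20 m above every position (uniform grade)
  n <- 30
  net <- chainNetwork(rep(10, n), elevs = (seq_len(n) * 10 - 5) * 0.25)
  rs <- runSlopes(net, run_m = 20)
  defined <- !is.na(rs)
  expect_equal(unname(rs[defined]), rep(25, sum(defined)), tolerance = 1e-9)
  # a position with only 10 m of channel above is undefined
  tiny <- chainNetwork(c(10), elevs = 5)
  expect_true(is.na(runSlopes(tiny, 20)[["c001"]]))
})

test_that("the covariate table flags undefined cells and validates areas", {
  net <- smallTree(4)
  tab <- buildCovariateTable(net)
  expect_named(tab, c("reach_id", "upstream_length_km", "drainage_area_km2",
                      "log_drainage_area", "downstream_slope_pct",
                      "elev_norm"))
  expect_true(all(tab$drainage_area_km2 >=
                  reaches(net)$incr_area_km2 - 1e-12))
  expect_equal(tab$log_drainage_area, log10(tab$drainage_area_km2))
  rec <- chainRecords(c(5, 5), elevs = c(1, 2), incr = c(0, 0))
  rec$block <- "b"
  expect_error(buildCovariateTable(buildNetwork(rec)), "log-transform")
})
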