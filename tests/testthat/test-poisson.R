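test_that("occupancy matches the closed form and rejects saturation", {
  expect_identical(occupancy(0), 0)
  expect_equal(occupancy(0.1317), -log(1 - 0.1317))
  expect_equal(occupancy(1 - exp(-1)), 1)
  expect_error(occupancy(1), "saturated")
  expect_error(occupancy(-0.1), ">= 0")
})

test_that("single-molecule fraction reproduces the assay's limiting-dilution anchors", {
  # 13.17% positive droplets -> 93.11% single-molecule; 0.08% -> 99.96%
  expect_equal(signif(100 * singleMoleculeFraction(0.1317), 4), 93.11)
  expect_equal(signif(100 * singleMoleculeFraction(0.0008), 4), 99.96)
  # rare-event limit -> 1
  expect_equal(singleMoleculeFraction(1e-10), 1, tolerance = 1e-6)
  expect_error(singleMoleculeFraction(0), "undefined")
  expect_error(singleMoleculeFraction(1), "saturated")
})

test_that("occupancy and single-molecule fraction are strictly monotone, with exact round trip", {
  p <- seq(0.001, 0.95, length.out = 200)
  lam <- occupancy(p)
  expect_true(all(diff(lam) > 0))
  expect_true(all(diff(singleMoleculeFraction(p)) < 0))
  expect_equal(1 - exp(-lam), p, tolerance = 1e-14)
})

test_that("QC gates are inclusive at their boundaries and floor empty wells", {
  # exactly 10% positives passes the positive-fraction gate; at that load the
  # single-molecule fraction is 94.82%, so the default occupancy gate decides
  atGate <- ClusterCounts("ELOVL2", 20000, 18000, 2000, 600)
  q <- qcEvaluate(atGate)
  expect_true(q@pPositive <= 0.10)
  expect_true(qcEvaluate(atGate, QCRule(minSingleFraction = 0.9))@pass)
  expect_false(q@pass)  # 0.9482 < 0.95
  # at exactly the 95% single-molecule boundary (p such that single = 0.95)
  # both inclusive gates pass
  nPos <- 1900L
  q95 <- qcEvaluate(ClusterCounts("ELOVL2", 20000L, 20000L - nPos, nPos, 500L))
  expect_true(q95@singleFraction >= 0.95 && q95@pass)
  # 13.17% exceeds the recommended range
  above <- ClusterCounts("ELOVL2", 20000, 20000 - 2634, 2634, 800)
  expect_false(qcEvaluate(above)@pass)
  # empty well fails via the droplet floor, without an exception
  empty <- ClusterCounts("ELOVL2", 20000, 20000, 0, 0)
  q0 <- qcEvaluate(empty)
  expect_false(q0@pass)
  expect_identical(q0@lambda, 0)
  expect_identical(q0@copies, 0)
})

test_that("qcEvaluate populates occupancy, copies, and single fraction consistently", {
  cc <- ClusterCounts("FHL2", 20000, 19000, 1000, 300)
  q <- qcEvaluate(cc)
  expect_equal(q@pPositive, 0.05)
  expect_equal(q@lambda, -log(0.95))
  expect_equal(q@copies, 20000 * -log(0.95))
  expect_equal(q@singleFraction, singleMoleculeFraction(0.05))
  expect_true(q@pass)
})

test_that("empirical single-molecule fraction matches the analytic value", {
  # ground-truth molecule placements at 20,000 droplets vs Poisson closed form
  cfg <- quickConfig(beta = 0.5, molecules = 2000)
  agreePos <- agreeSingle <- 0
  for (s in 1:5) {
    sim <- simulateWell(cfg, seed = 300 + s)
    tr <- sim$truth$ELOVL2
    occ <- tr$methPerDroplet + tr$unmethPerDroplet
    pPos <- mean(occ > 0)
    empirical <- sum(occ == 1) / sum(occ > 0)
    analytic <- singleMoleculeFraction(pPos)
    # Monte-Carlo error of the empirical fraction at ~1900 positives
    expect_lt(abs(empirical - analytic), 3 * sqrt(analytic * (1 - analytic) / sum(occ > 0)))
  }
})

test_that("occupancy-corrected methylation agrees with the ratio at low load and is exact under symmetry", {
  cfg <- quickConfig(beta = 0.3, molecules = 150)   # p < 1%
  sim <- simulateWell(cfg, seed = 7)
  cc <- classifyDroplets(sim$well, defaultThresholds("ELOVL2"))
  expect_lt(abs(correctedMethylation(cc) - methylationFraction(cc)@beta), 1e-3)

  # equal allele occupancies -> exactly 0.5 (labeled cluster count chosen so
  # the conditional unlabeled fraction equals the labeled marginal fraction)
  n <- 20000L
  nAll <- 2000L
  nOther <- as.integer(round((n - nAll) * nAll / n))
  cc2 <- ClusterCounts("ELOVL2", n, n - nAll - nOther, nAll + nOther, nAll)
  expect_equal(correctedMethylation(cc2), 0.5, tolerance = 1e-12)

  expect_error(correctedMethylation(ClusterCounts("ELOVL2", 100L, 100L, 0L, 0L)),
               "no positive droplets")
})

test_that("occupancy correction beats the count ratio at high template load", {
  # at ~45% positive droplets the count ratio is biased toward the labeled
  # allele because co-occupied droplets land in the high cluster
  errRatio <- errCorr <- numeric(60)
  for (i in 1:60) {
    sim <- simulateWell(quickConfig(beta = 0.5, molecules = 12000), seed = 5000 + i)
    cc <- classifyDroplets(sim$well, defaultThresholds("ELOVL2"))
    errRatio[i] <- abs(methylationFraction(cc)@beta - 0.5)
    errCorr[i] <- abs(correctedMethylation(cc) - 0.5)
  }
  expect_lt(mean(errCorr), mean(errRatio))
})

test_that("Wilson interval behaves sensibly", {
  ci <- wilsonInterval(300, 700)
  expect_lt(ci["lower"], 0.3)
  expect_gt(ci["upper"], 0.3)
  expect_true(all(wilsonInterval(0, 10) >= 0) && all(wilsonInterval(10, 0) <= 1))
  expect_error(wilsonInterval(0, 0), ">= 1")
})
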