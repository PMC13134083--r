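test_that("two-threshold classification counts droplets with the strict-> convention", {
  w <- DropletWell("A01", list(ELOVL2 = c(1000, 1500, 3000, 7000)))
  cc <- classifyDroplets(w, ChannelThresholds("ELOVL2", 2000, 6000))
  expect_counts_equal(cc, 2, 2, 1)

  # droplets exactly at a threshold are below it
  cc <- classifyDroplets(w, ChannelThresholds("ELOVL2", 1500, 3000))
  expect_counts_equal(cc, 2, 2, 1)

  # all-negative well
  w2 <- DropletWell("A02", list(ELOVL2 = c(900, 1000, 1100)))
  cc2 <- classifyDroplets(w2, ChannelThresholds("ELOVL2", 2000, 6000))
  expect_counts_equal(cc2, 3, 0, 0)

  expect_error(classifyDroplets(w, ChannelThresholds("FHL2", 2000, 6000)),
               "unknown channel")
  expect_error(ChannelThresholds("ELOVL2", 6000, 2000), "tTotal")
})

test_that("classification reproduces simulator ground truth without rain", {
  cfg <- assaySimConfig(cpgPanel(), trueBeta = c(.7, .6, .5, .3, .3, .4),
                        totalMolecules = 1500)
  sim <- simulateWell(cfg, seed = 101)
  for (cpg in cpgPanel()) {
    cc <- classifyDroplets(sim$well, defaultThresholds(cpg))
    tc <- truthCounts(sim, cpg)
    expect_identical(cc@nNegative, tc@nNegative)
    expect_identical(cc@nPositiveTotal, tc@nPositiveTotal)
    expect_identical(cc@nAllele, tc@nAllele)
  }
})

test_that("classification counts always partition the well and respect threshold monotonicity", {
  cfg <- quickConfig(beta = 0.4, molecules = 3000)
  sim <- simulateWell(cfg, seed = 7)
  tT <- seq(1500, 3500, by = 500)
  tA <- seq(5000, 7500, by = 500)
  prevPos <- Inf
  for (t1 in tT) {
    cc <- classifyDroplets(sim$well, ChannelThresholds("ELOVL2", t1, 9000))
    expect_identical(cc@nNegative + cc@nPositiveTotal, cc@nTotal)
    expect_lte(cc@nPositiveTotal, prevPos)   # raising tTotal never adds positives
    prevPos <- cc@nPositiveTotal
  }
  prevAllele <- Inf
  for (t2 in tA) {
    cc <- classifyDroplets(sim$well, ChannelThresholds("ELOVL2", 2500, t2))
    expect_identical(cc@nNegative + cc@nPositiveTotal, cc@nTotal)
    expect_lte(cc@nAllele, prevAllele)       # raising tAllele never adds high droplets
    prevAllele <- cc@nAllele
  }
})

test_that("methylation fraction is invariant to labeling orientation", {
  # the two printed formulas are the same quantity M/(M+U)
  set.seed(42)
  for (i in 1:200) {
    M <- sample(0:500, 1)
    U <- sample(0:500, 1)
    if (M + U == 0) U <- 1
    n <- 20000L
    ccM <- ClusterCounts("ELOVL2", n, n - M - U, M + U, M, labeled = "methylated")
    ccU <- ClusterCounts("FHL2", n, n - M - U, M + U, U, labeled = "unmethylated")
    expect_identical(methylatedCount(ccM), M)
    expect_identical(unmethylatedCount(ccU), U)
    expect_equal(methylationFraction(ccM)@beta, methylationFraction(ccU)@beta)
    expect_equal(methylationFraction(ccM)@beta, M / (M + U))
  }
})

test_that("methylation fraction handles boundary counts and refuses empty channels", {
  n <- 20000L
  zeroM <- ClusterCounts("ELOVL2", n, n - 500L, 500L, 0L, labeled = "methylated")
  expect_equal(methylationFraction(zeroM)@beta, 0)
  balanced <- ClusterCounts("ELOVL2", n, n - 600L, 600L, 300L, labeled = "methylated")
  expect_equal(methylationFraction(balanced)@beta, 0.5)
  empty <- ClusterCounts("ELOVL2", n, n, 0L, 0L, labeled = "methylated")
  expect_error(methylationFraction(empty), "no positive droplets")
})

test_that("simulated beta recovery stays within 3 binomial SEs at limiting dilution", {
  cfg <- quickConfig(beta = 0.25, molecules = 1500)  # p ~ 7%
  sim <- simulateWell(cfg, seed = 11)
  r <- quantifyWell(sim$well, list(defaultThresholds("ELOVL2")))$ELOVL2
  se <- sqrt(0.25 * 0.75 / (r@M + r@U))
  expect_lt(abs(r@beta - 0.25), 3 * se)
  expect_true(r@qc@pass)
})

test_that("quantifyWell drives all channels, propagates errors and rejects bad threshold sets", {
  cfg <- assaySimConfig(cpgPanel(), trueBeta = 0.4, totalMolecules = 1200)
  sim <- simulateWell(cfg, seed = 3)
  thr <- lapply(cpgPanel(), defaultThresholds)
  res <- quantifyWell(sim$well, thr)
  expect_named(res, cpgPanel())
  expect_true(all(vapply(res, function(r) is(r, "MethylationResult"), logical(1))))
  expect_true(all(vapply(res, function(r) r@qc@pass, logical(1))))

  # one all-negative channel -> five results + one labeled channel error
  cfg0 <- assaySimConfig(cpgPanel(), trueBeta = 0.4,
                         totalMolecules = c(0L, rep(1200L, 5)))
  sim0 <- simulateWell(cfg0, seed = 3)
  res0 <- quantifyWell(sim0$well, thr)
  expect_s3_class(res0$ASPA, "simpleError")
  expect_match(conditionMessage(res0$ASPA), "\\[ASPA\\]")
  expect_true(all(vapply(res0[-1], function(r) is(r, "MethylationResult"), logical(1))))

  expect_error(quantifyWell(sim$well, c(thr, thr[1])), "duplicate")
  expect_error(quantifyWell(sim$well, thr[-1]), "no thresholds")
})

test_that("droplet CSV round trips in both dialects and threshold configs load", {
  cfg <- assaySimConfig(c("ELOVL2", "FHL2"), trueBeta = c(0.3, 0.6),
                        totalMolecules = 400, nDroplets = 2000)
  sim <- simulateWell(cfg, seed = 5, wellId = "B07")
  long <- tempfile(fileext = ".csv")
  writeDroplets(sim$well, long)
  wells <- readDroplets(long)
  expect_named(wells, "B07")
  # text round trip preserves amplitudes to printed precision
  expect_equal(amplitudes(wells$B07, "ELOVL2"), amplitudes(sim$well, "ELOVL2"),
               tolerance = 1e-9)

  # wide dialect
  wide <- tempfile(fileext = ".csv")
  df <- data.frame(well = "B07",
                   ELOVL2 = amplitudes(sim$well, "ELOVL2"),
                   FHL2 = amplitudes(sim$well, "FHL2"))
  write.csv(df, wide, row.names = FALSE)
  wells2 <- readDroplets(wide)
  expect_equal(amplitudes(wells2$B07, "FHL2"), amplitudes(sim$well, "FHL2"))

  thrFile <- tempfile(fileext = ".csv")
  write.csv(data.frame(cpg = c("ELOVL2", "FHL2"), t_total = 2500,
                       t_allele = 6000), thrFile, row.names = FALSE)
  thr <- readThresholds(thrFile)
  expect_length(thr, 2)
  expect_identical(thr[[1]]@labeledAllele, "methylated")

  out <- quantifyWells(wells, thr)
  expect_identical(nrow(out), 2L)
  expect_true(all(c("beta", "M", "U", "qc_pass", "single_fraction") %in% names(out)))
})
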