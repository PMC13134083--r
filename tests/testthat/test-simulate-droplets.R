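test_that("simulated wells conserve molecules and label droplets consistently", {
  cfg <- assaySimConfig(cpgPanel(), trueBeta = c(.7, .6, .5, .3, .3, .4),
                        totalMolecules = 1800)
  sim <- simulateWell(cfg, seed = 21)
  expect_identical(dropletCount(sim$well), 20000L)
  for (cpg in cpgPanel()) {
    tr <- sim$truth[[cpg]]
    expect_identical(sum(tr$methPerDroplet), tr$nMeth)
    expect_identical(sum(tr$unmethPerDroplet), tr$nUnmeth)
    expect_identical(tr$nMeth + tr$nUnmeth, 1800L)
    labeledPer <- if (tr$labeled == "methylated") tr$methPerDroplet else tr$unmethPerDroplet
    expect_identical(tr$label == "high", labeledPer > 0L)
    expect_identical(tr$label == "negative", tr$methPerDroplet + tr$unmethPerDroplet == 0L)
    expect_identical(as.integer(sum(table(tr$label))), 20000L)
  }
})

test_that("boundary beta gives an empty labeled-allele cluster", {
  cfg <- quickConfig(cpg = "ELOVL2", beta = 0, molecules = 1000)
  sim <- simulateWell(cfg, seed = 2)
  expect_identical(sim$truth$ELOVL2$nMeth, 0L)
  expect_identical(sum(sim$truth$ELOVL2$label == "high"), 0L)
})

test_that("simulation is bit-reproducible under (seed, config) and varies across seeds", {
  cfg <- quickConfig(beta = 0.4, molecules = 800, nDroplets = 5000)
  a <- simulateWell(cfg, seed = 9)
  b <- simulateWell(cfg, seed = 9)
  expect_identical(amplitudes(a$well, "ELOVL2"), amplitudes(b$well, "ELOVL2"))
  expect_identical(a$truth, b$truth)
  c <- simulateWell(cfg, seed = 10)
  expect_false(identical(amplitudes(a$well, "ELOVL2"), amplitudes(c$well, "ELOVL2")))
})

test_that("positive-droplet fraction follows 1 - exp(-molecules/droplets)", {
  # 2,482 molecules in 20,000 droplets -> expected positive fraction ~11.67%
  expected <- 1 - exp(-2482 / 20000)
  pHat <- vapply(1:10, function(s) {
    sim <- simulateWell(quickConfig(beta = 0.5, molecules = 2482), seed = 400 + s)
    mean(sim$truth$ELOVL2$label != "negative")
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mean(pHat) - expected), 3 * se / sqrt(10))
})

test_that("per-droplet molecule counts fit a Poisson law", {
  # aggregate chi-square goodness of fit across seeds at lambda = 0.15
  counts <- integer(0)
  for (s in 1:30) {
    sim <- simulateWell(quickConfig(beta = 0.5, molecules = 3000), seed = 600 + s)
    tr <- sim$truth$ELOVL2
    counts <- c(counts, tr$methPerDroplet + tr$unmethPerDroplet)
  }
  lambda <- mean(counts)
  tab <- table(factor(pmin(counts, 4), levels = 0:4))
  p <- c(dpois(0:3, lambda), 1 - ppois(3, lambda))
  chisq <- sum((as.numeric(tab) - length(counts) * p)^2 / (length(counts) * p))
  expect_lt(chisq, qchisq(0.99, df = 3))  # not rejected at alpha = 0.01
})

test_that("rain-free wells classify exactly; rain biases beta toward the common allele", {
  cfg0 <- quickConfig(beta = 0.2, molecules = 1500, rain = 0)
  sim0 <- simulateWell(cfg0, seed = 31)
  cc0 <- classifyDroplets(sim0$well, defaultThresholds("ELOVL2"))
  tc0 <- truthCounts(sim0, "ELOVL2")
  expect_identical(cc0@nAllele, tc0@nAllele)

  # labeled = methylated = rarer allele at beta 0.2: rain knocks high droplets
  # below tAllele, so measured beta underestimates the rare labeled allele
  signs <- vapply(1:25, function(s) {
    sim <- simulateWell(quickConfig(beta = 0.2, molecules = 1500, rain = 0.25),
                        seed = 700 + s)
    cc <- classifyDroplets(sim$well, defaultThresholds("ELOVL2"))
    methylationFraction(cc)@beta < 0.2
  }, logical(1))
  expect_lt(binom.test(sum(signs), 25, alternative = "greater")$p.value, 0.01)
})

test_that("dilution series scales molecules, keeps sub-seeds distinct, and inflates low-input spread", {
  cfg <- quickConfig(beta = 0.3, molecules = 12000, nDroplets = 10000)
  series <- simulateDilutionSeries(cfg, dilutionFactors = 2^(0:6),
                                   replicates = 2, seed = 1)
  expect_length(series, 14)
  pPos <- vapply(series, function(s) mean(s$truth$ELOVL2$label != "negative"),
                 numeric(1))
  byLevel <- tapply(pPos, rep(1:7, each = 2), mean)
  expect_true(all(diff(byLevel) < 0))  # monotone decreasing positive fractions

  # degenerate series: a single level
  single <- simulateDilutionSeries(cfg, dilutionFactors = 1, replicates = 3, seed = 1)
  expect_length(single, 3)

  # replicate beta spread grows as input shrinks (binomial variance oracle)
  sdLow <- sdHigh <- numeric(12)
  thr <- defaultThresholds("ELOVL2")
  for (s in 1:12) {
    ser <- simulateDilutionSeries(quickConfig(beta = 0.3, molecules = 6000),
                                  dilutionFactors = c(1, 64), replicates = 4,
                                  seed = 800 + s)
    beta <- vapply(ser, function(w)
      methylationFraction(classifyDroplets(w$well, thr))@beta, numeric(1))
    sdHigh[s] <- sd(beta[1:4]); sdLow[s] <- sd(beta[5:8])
  }
  expect_gt(mean(sdLow), mean(sdHigh))
  expect_gt(sum(sdLow > sdHigh), 9)
})

test_that("degenerate configurations are rejected", {
  expect_error(assaySimConfig("ELOVL2", nDroplets = 0), "nDroplets")
  expect_error(assaySimConfig("ELOVL2", totalMolecules = -5), "totalMolecules")
  expect_error(assaySimConfig("ELOVL2", trueBeta = 1.2), "trueBeta")
  expect_error(assaySimConfig("ELOVL2", rainFraction = 0.6), "rainFraction")
  expect_error(simulateDilutionSeries(quickConfig(), dilutionFactors = c(4, 2)),
               "increasing")
  # scaling to zero molecules is allowed and yields all-negative wells
  ser <- simulateDilutionSeries(quickConfig(molecules = 10, nDroplets = 1000),
                                dilutionFactors = c(1, 1e6), replicates = 1, seed = 1)
  expect_identical(sum(ser[[2]]$truth$ELOVL2$label != "negative"), 0L)
})

test_that("ngToMolecules applies genome mass and amplifiable fraction", {
  expect_identical(ngToMolecules(40), as.integer(round(40000 / 3.3 * 0.2)))
  expect_identical(ngToMolecules(0), 0L)
  expect_gt(ngToMolecules(40, 1), ngToMolecules(40, 0.2))
})
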