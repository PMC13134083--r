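# Shared fixtures: all synthetic, generated in code at test time.

# single-channel simulation config with convenient defaults
quickConfig <- function(cpg = "ELOVL2", beta = 0.25, molecules = 1500,
                        nDroplets = 20000, rain = 0) {
  assaySimConfig(cpg, trueBeta = beta, totalMolecules = molecules,
                 nDroplets = nDroplets, rainFraction = rain)
}

# noiseless cohort whose CpGs are exact linear functions of age
linearCohort <- function(n = 100, seed = 1, noise = 0) {
  set.seed(seed)
  age <- runif(n, 0, 95)
  data.frame(sample_id = sprintf("L%04d", seq_len(n)), age = age,
             FHL2 = 0.10 + 0.005 * age + rnorm(n, 0, noise),
             ASPA = 0.80 - 0.004 * age + rnorm(n, 0, noise),
             C1orf132 = 0.90 - 0.006 * age + rnorm(n, 0, noise))
}

expect_counts_equal <- function(cc, nNeg, nPos, nAllele) {
  expect_identical(cc@nNegative, as.integer(nNeg))
  expect_identical(cc@nPositiveTotal, as.integer(nPos))
  expect_identical(cc@nAllele, as.integer(nAllele))
}
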