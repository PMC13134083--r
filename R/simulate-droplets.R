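## Synthetic droplet-well generator: Poisson partitioning of methylated and
## unmethylated molecules into ~20,000 droplets, Gaussian amplitude clusters,
## optional 'rain' artifacts, and dilution series. Ground truth (per-droplet
## molecule placements and cluster labels) is recorded for every well so the
## classification and quantification paths can be checked exactly.

#' Default amplitude cluster model
#'
#' Cluster means and spreads for the negative, single-positive and
#' high-positive (labeled-allele) clusters of a channel. The defaults are
#' well-separated (inter-cluster gaps of many cluster SDs) so that the
#' default midpoint thresholds are unambiguous; droplet readers report
#' amplitudes in arbitrary fluorescence units, and the absolute scale is
#' synthetic.
#'
#' @param negMean,negSd Negative cluster mean and SD.
#' @param posMean,posSd Single-positive cluster mean and SD.
#' @param highMean,highSd High-positive (labeled-allele) cluster mean and SD.
#' @return Named list of amplitude parameters.
#' @export
amplitudeModel <- function(negMean = 1000, negSd = 100,
                           posMean = 4000, posSd = 150,
                           highMean = 8000, highSd = 200) {
  stopifnot(negMean < posMean, posMean < highMean,
            negSd > 0, posSd > 0, highSd > 0)
  list(negMean = negMean, negSd = negSd, posMean = posMean, posSd = posSd,
       highMean = highMean, highSd = highSd)
}

#' Default midpoint thresholds for a simulated channel
#'
#' Places \code{tTotal} halfway between the negative and single-positive
#' cluster means and \code{tAllele} halfway between the single-positive and
#' high-positive means.
#'
#' @param cpg CpG/channel name.
#' @param amp Amplitude model (see [amplitudeModel()]).
#' @param labeled Labeled-allele orientation.
#' @return A [ChannelThresholds-class].
#' @export
defaultThresholds <- function(cpg, amp = amplitudeModel(),
                              labeled = unname(labeledAllele(cpg))) {
  ChannelThresholds(cpg, (amp$negMean + amp$posMean) / 2,
                    (amp$posMean + amp$highMean) / 2, labeled)
}

#' Simulation configuration for a droplet well
#'
#' @param cpg Character vector of channel names to simulate.
#' @param trueBeta True methylation fraction per channel (recycled).
#' @param totalMolecules Amplifiable target molecules per channel (recycled).
#' @param nDroplets Droplets per well (default 20000).
#' @param labeled Labeled-allele orientation per channel.
#' @param amp Amplitude cluster model.
#' @param rainFraction Probability that a high-cluster droplet's amplitude is
#'   redrawn uniformly from the inter-cluster gap (the 'rain' artifact, where
#'   upper positive droplets fall toward the lower cluster). Must be < 0.5.
#' @return A list of class \code{AssaySimConfig}.
#' @export
#' @examples
#' assaySimConfig("ELOVL2", trueBeta = 0.25, totalMolecules = 1200)
assaySimConfig <- function(cpg = cpgPanel(), trueBeta = 0.5,
                           totalMolecules = 1500, nDroplets = 20000,
                           labeled = unname(labeledAllele(cpg)),
                           amp = amplitudeModel(), rainFraction = 0) {
  nDroplets <- as.integer(nDroplets)
  if (nDroplets <= 0L) stop("nDroplets must be > 0")
  if (rainFraction < 0 || rainFraction >= 0.5)
    stop("rainFraction must lie in [0, 0.5)")
  k <- length(cpg)
  trueBeta <- rep_len(trueBeta, k)
  totalMolecules <- as.integer(rep_len(totalMolecules, k))
  if (any(trueBeta < 0 | trueBeta > 1)) stop("trueBeta must lie in [0, 1]")
  if (any(totalMolecules < 0)) stop("totalMolecules must be >= 0")
  structure(list(cpg = cpg, trueBeta = trueBeta,
                 totalMolecules = totalMolecules, nDroplets = nDroplets,
                 labeled = labeled, amp = amp, rainFraction = rainFraction),
            class = "AssaySimConfig")
}

#' Convert a DNA input mass to amplifiable molecule copies
#'
#' Uses 3.3 pg per haploid genome equivalent and a configurable amplifiable
#' fraction reflecting losses to bisulfite degradation and partial
#' amplification; the default 0.2 is a modeling choice placing a 40 ng input
#' near the positive-droplet counts observed at the top of the assay's
#' sensitivity range.
#'
#' @param ng DNA input in nanograms.
#' @param amplifiableFraction Fraction of genome copies that amplify.
#' @return Expected amplifiable molecule count (rounded).
#' @export
#' @examples
#' ngToMolecules(40)
ngToMolecules <- function(ng, amplifiableFraction = 0.2) {
  stopifnot(ng >= 0, amplifiableFraction > 0, amplifiableFraction <= 1)
  as.integer(round(ng * 1000 / 3.3 * amplifiableFraction))
}

#' Simulate one droplet well with ground truth
#'
#' For each configured channel: the methylated molecule count is drawn as
#' Binomial(totalMolecules, trueBeta); each molecule is assigned to a droplet
#' uniformly at random (so per-droplet counts are multinomial, asymptotically
#' Poisson with occupancy totalMolecules/nDroplets); each droplet's true
#' cluster is "high" if it holds any labeled-allele molecule, else "positive"
#' if it holds any molecule, else "negative"; amplitudes are drawn from the
#' cluster's Gaussian; with probability \code{rainFraction} a high-cluster
#' droplet's amplitude is redrawn uniformly between the single-positive and
#' high cluster means (rain). Molecule placements, true labels and totals are
#' recorded per channel.
#'
#' @param config An [assaySimConfig()] object.
#' @param seed Integer seed; every simulated well is bit-reproducible given
#'   \code{(seed, config)}.
#' @param wellId Well identifier for the generated [DropletWell-class].
#' @return List with elements \code{well} (a [DropletWell-class]) and
#'   \code{truth}: per-channel list carrying \code{methPerDroplet},
#'   \code{unmethPerDroplet}, \code{label} (factor negative/positive/high),
#'   \code{trueBeta}, \code{nMeth}, \code{nUnmeth}, \code{labeled}.
#' @export
simulateWell <- function(config, seed = 1L, wellId = "S01") {
  stopifnot(inherits(config, "AssaySimConfig"))
  set.seed(as.integer(seed))
  n <- config$nDroplets
  amp <- config$amp
  amps <- list()
  truth <- list()
  for (i in seq_along(config$cpg)) {
    cpg <- config$cpg[i]
    total <- config$totalMolecules[i]
    beta <- config$trueBeta[i]
    nMeth <- rbinom(1L, total, beta)
    nUnmeth <- total - nMeth
    methPer <- tabulate(sample.int(n, nMeth, replace = TRUE), nbins = n)
    unmethPer <- tabulate(sample.int(n, nUnmeth, replace = TRUE), nbins = n)
    labeledPer <- if (config$labeled[i] == "methylated") methPer else unmethPer
    anyMol <- methPer + unmethPer > 0L
    lab <- ifelse(labeledPer > 0L, "high", ifelse(anyMol, "positive", "negative"))
    a <- rnorm(n, amp$negMean, amp$negSd)
    isPos <- lab == "positive"
    isHigh <- lab == "high"
    a[isPos] <- rnorm(sum(isPos), amp$posMean, amp$posSd)
    a[isHigh] <- rnorm(sum(isHigh), amp$highMean, amp$highSd)
    if (config$rainFraction > 0 && any(isHigh)) {
      rain <- isHigh & (runif(n) < config$rainFraction)
      a[rain] <- runif(sum(rain), amp$posMean, amp$highMean)
    }
    amps[[cpg]] <- a
    truth[[cpg]] <- list(methPerDroplet = methPer, unmethPerDroplet = unmethPer,
                         label = factor(lab, levels = c("negative", "positive", "high")),
                         trueBeta = beta, nMeth = nMeth, nUnmeth = nUnmeth,
                         labeled = config$labeled[i])
  }
  list(well = DropletWell(wellId, amps), truth = truth)
}

#' Simulate a dilution series of wells
#'
#' Scales each channel's molecule count by a descending series of dilution
#' factors and simulates replicate wells per level with distinct,
#' deterministic sub-seeds. Reproduces the qualitative sensitivity pattern of
#' a limiting-dilution series: stable methylation estimates at high input,
#' inflated replicate spread (and eventually empty channels) at low input.
#'
#' @param config Base [assaySimConfig()]; \code{totalMolecules} gives the
#'   undiluted counts.
#' @param dilutionFactors Positive, strictly increasing factors (1 = neat);
#'   molecules are divided by each factor.
#' @param replicates Wells per dilution level.
#' @param seed Integer master seed; well \code{j} of level \code{i} uses
#'   sub-seed \code{seed + 1000*i + j}.
#' @return List of per-well results as from [simulateWell()], each augmented
#'   with \code{dilutionFactor} and \code{replicate}.
#' @export
simulateDilutionSeries <- function(config, dilutionFactors = 2^(0:6),
                                   replicates = 2L, seed = 1L) {
  stopifnot(inherits(config, "AssaySimConfig"))
  if (any(dilutionFactors <= 0)) stop("dilution factors must be positive")
  if (is.unsorted(dilutionFactors, strictly = TRUE))
    stop("dilution factors must be strictly increasing (most concentrated first)")
  out <- list()
  for (i in seq_along(dilutionFactors)) {
    f <- dilutionFactors[i]
    cfg <- config
    cfg$totalMolecules <- as.integer(round(config$totalMolecules / f))
    for (j in seq_len(replicates)) {
      sw <- simulateWell(cfg, seed = as.integer(seed) + 1000L * i + j,
                         wellId = sprintf("D%02dR%02d", i, j))
      sw$dilutionFactor <- f
      sw$replicate <- j
      out[[length(out) + 1L]] <- sw
    }
  }
  out
}

#' Ground-truth cluster counts of a simulated channel
#'
#' Bookkeeping helper: turns a simulated channel's true labels into the
#' [ClusterCounts-class] a perfect classifier would produce.
#'
#' @param sim Result of [simulateWell()].
#' @param cpg Channel name.
#' @return A [ClusterCounts-class].
#' @export
truthCounts <- function(sim, cpg) {
  tr <- sim$truth[[cpg]]
  if (is.null(tr)) stop("no simulated channel '", cpg, "'")
  tab <- table(tr$label)
  ClusterCounts(cpg, nTotal = sum(tab), nNegative = tab[["negative"]],
                nPositiveTotal = tab[["positive"]] + tab[["high"]],
                nAllele = tab[["high"]], labeled = tr$labeled)
}
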