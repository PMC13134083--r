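#' @import methods
#' @importFrom stats rnorm runif rbinom coef cor lm predict qnorm quantile sd
#'   var residuals confint dpois pchisq setNames
NULL

#' The six-CpG assay panel
#'
#' Names of the six age-associated CpG targets quantified by the multiplex
#' ddPCR assay, one fluorescence channel per locus. For \code{CCDC102B} and
#' \code{ELOVL2} the fluorescent probe targets the methylated allele; for
#' \code{ASPA}, \code{C1orf132}, \code{EDARADD} and \code{FHL2} it targets the
#' unmethylated allele (the rarer allele per locus in blood, which limits the
#' impact of 'rain' on the labeled cluster).
#'
#' @return Character vector of the six CpG/channel names.
#' @export
#' @examples
#' cpgPanel()
cpgPanel <- function() c("ASPA", "C1orf132", "CCDC102B", "EDARADD", "ELOVL2", "FHL2")

#' Labeled-allele orientation of each panel CpG
#'
#' @param cpg Character vector of CpG names (default: the whole panel).
#' @return Named character vector, \code{"methylated"} or \code{"unmethylated"}.
#' @export
#' @examples
#' labeledAllele("ELOVL2")
labeledAllele <- function(cpg = cpgPanel()) {
  map <- c(ASPA = "unmethylated", C1orf132 = "unmethylated",
           CCDC102B = "methylated", EDARADD = "unmethylated",
           ELOVL2 = "methylated", FHL2 = "unmethylated")
  bad <- setdiff(cpg, names(map))
  if (length(bad))
    stop("unknown CpG name(s): ", paste(bad, collapse = ", "))
  map[cpg]
}

#' DropletWell: one well's droplet amplitudes
#'
#' Raw observation unit of the assay: per-channel fluorescence amplitudes for
#' the ~20,000 droplets of a single well, as exported one row per droplet per
#' channel by the droplet reader software.
#'
#' @slot wellId Single well identifier.
#' @slot amplitudes Named list, one numeric vector of droplet amplitudes per
#'   CpG/channel; all vectors have length \code{dropletCount}.
#' @slot dropletCount Number of droplets in the well.
#'
#' @seealso [DropletWell()], [classifyDroplets()]
#' @export
setClass("DropletWell",
  representation(wellId = "character", amplitudes = "list",
                 dropletCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@wellId) != 1L) msg <- c(msg, "wellId must be a single string")
    if (object@dropletCount <= 0L) msg <- c(msg, "dropletCount must be > 0")
    if (is.null(names(object@amplitudes)) || anyDuplicated(names(object@amplitudes)))
      msg <- c(msg, "amplitudes must be a uniquely named list of channels")
    for (ch in names(object@amplitudes)) {
      a <- object@amplitudes[[ch]]
      if (!is.numeric(a) || length(a) != object@dropletCount)
        msg <- c(msg, sprintf("channel '%s': amplitude vector length != dropletCount", ch))
      else if (!all(is.finite(a)))
        msg <- c(msg, sprintf("channel '%s': non-finite amplitudes", ch))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a DropletWell
#'
#' @param wellId Well identifier, e.g. \code{"A01"}.
#' @param amplitudes Named list of numeric amplitude vectors, one per channel;
#'   all vectors must have equal length.
#' @return A [DropletWell-class] object.
#' @export
#' @examples
#' w <- DropletWell("A01", list(ELOVL2 = c(900, 1100, 4100, 8200)))
#' dropletCount(w)
DropletWell <- function(wellId, amplitudes) {
  amplitudes <- lapply(amplitudes, as.numeric)
  n <- if (length(amplitudes)) length(amplitudes[[1L]]) else 0L
  new("DropletWell", wellId = as.character(wellId), amplitudes = amplitudes,
      dropletCount = as.integer(n))
}

#' ChannelThresholds: the two amplitude thresholds of one channel
#'
#' The assay is analyzed with two thresholds per channel: \code{tTotal}
#' separates negative droplets from all positives, and \code{tAllele}
#' separates single-positive droplets from the high-amplitude cluster carrying
#' the fluorescently labeled allele. Droplets strictly above a threshold are
#' above it.
#'
#' @slot cpg CpG/channel name.
#' @slot tTotal Threshold between negatives and positives.
#' @slot tAllele Threshold between single positives and the labeled-allele
#'   cluster; must exceed \code{tTotal}.
#' @slot labeledAllele \code{"methylated"} or \code{"unmethylated"}: which
#'   allele the high cluster counts.
#' @export
setClass("ChannelThresholds",
  representation(cpg = "character", tTotal = "numeric", tAllele = "numeric",
                 labeledAllele = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@cpg) != 1L) msg <- c(msg, "cpg must be a single name")
    if (!(object@labeledAllele %in% c("methylated", "unmethylated")))
      msg <- c(msg, "labeledAllele must be 'methylated' or 'unmethylated'")
    if (!(object@tTotal < object@tAllele))
      msg <- c(msg, "tTotal must be < tAllele")
    if (length(msg)) msg else TRUE
  })

#' Construct ChannelThresholds
#'
#' @param cpg CpG/channel name.
#' @param tTotal,tAllele Amplitude thresholds, \code{tTotal < tAllele}.
#' @param labeled Labeled allele; defaults to the panel orientation when
#'   \code{cpg} is a panel CpG.
#' @return A [ChannelThresholds-class] object.
#' @export
ChannelThresholds <- function(cpg, tTotal, tAllele,
                              labeled = unname(labeledAllele(cpg))) {
  new("ChannelThresholds", cpg = cpg, tTotal = as.numeric(tTotal),
      tAllele = as.numeric(tAllele), labeledAllele = labeled)
}

#' ClusterCounts: droplet cluster counts for one CpG channel
#'
#' The sufficient statistic for one channel's methylation estimate: how many
#' droplets fall below \code{tTotal} (negatives), above it (positives), and
#' above \code{tAllele} (labeled-allele cluster). \code{nNegative +
#' nPositiveTotal = nTotal} always.
#'
#' @slot cpg CpG name.
#' @slot nTotal,nNegative,nPositiveTotal,nAllele Droplet counts.
#' @slot labeledAllele Which allele the \code{nAllele} cluster counts.
#' @seealso [methylatedCount()], [unmethylatedCount()], [methylationFraction()]
#' @export
setClass("ClusterCounts",
  representation(cpg = "character", nTotal = "integer", nNegative = "integer",
                 nPositiveTotal = "integer", nAllele = "integer",
                 labeledAllele = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nNegative + object@nPositiveTotal != object@nTotal)
      msg <- c(msg, "nNegative + nPositiveTotal must equal nTotal")
    if (object@nAllele < 0L || object@nAllele > object@nPositiveTotal)
      msg <- c(msg, "nAllele must lie in [0, nPositiveTotal]")
    if (!(object@labeledAllele %in% c("methylated", "unmethylated")))
      msg <- c(msg, "labeledAllele must be 'methylated' or 'unmethylated'")
    if (length(msg)) msg else TRUE
  })

#' Construct ClusterCounts
#'
#' @param cpg CpG name.
#' @param nTotal,nNegative,nPositiveTotal,nAllele Droplet counts.
#' @param labeled Labeled allele orientation.
#' @return A [ClusterCounts-class] object.
#' @export
ClusterCounts <- function(cpg, nTotal, nNegative, nPositiveTotal, nAllele,
                          labeled = unname(labeledAllele(cpg))) {
  new("ClusterCounts", cpg = cpg, nTotal = as.integer(nTotal),
      nNegative = as.integer(nNegative),
      nPositiveTotal = as.integer(nPositiveTotal),
      nAllele = as.integer(nAllele), labeledAllele = labeled)
}

#' PoissonQuant: Poisson limiting-dilution statistics for one target
#'
#' Occupancy and quality-control summary derived from one channel's positive
#' droplet fraction: mean molecules per droplet \eqn{\lambda = -\ln(1-p)},
#' absolute copy estimate \eqn{\lambda n}, probability that a positive droplet
#' holds a single molecule, and the QC verdict.
#'
#' @slot cpg CpG name.
#' @slot pPositive Fraction of positive droplets.
#' @slot lambda Mean target molecules per droplet.
#' @slot copies Estimated molecules across the well.
#' @slot singleFraction P(exactly one molecule | positive).
#' @slot pass QC verdict.
#' @export
setClass("PoissonQuant",
  representation(cpg = "character", pPositive = "numeric", lambda = "numeric",
                 copies = "numeric", singleFraction = "numeric",
                 pass = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (object@pPositive < 0 || object@pPositive >= 1)
      msg <- c(msg, "pPositive must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' MethylationResult: methylation fraction for one CpG
#'
#' @slot cpg CpG name.
#' @slot beta Methylation fraction in [0, 1].
#' @slot M,U Methylated- and unmethylated-droplet counts.
#' @slot qc The channel's [PoissonQuant-class] record.
#' @export
setClass("MethylationResult",
  representation(cpg = "character", beta = "numeric", M = "integer",
                 U = "integer", qc = "PoissonQuant"),
  validity = function(object) {
    msg <- character()
    if (object@beta < 0 || object@beta > 1) msg <- c(msg, "beta must lie in [0, 1]")
    if (object@M + object@U < 1L) msg <- c(msg, "M + U must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' QCRule: quality-control gates for limiting dilution
#'
#' The recommended operating range of the assay: at most 10\% positive
#' droplets per target CpG (reached with roughly 5-30 ng of converted DNA),
#' which guarantees at least 95\% single-molecule occupancy after
#' partitioning. Gates are inclusive at their boundaries.
#'
#' @slot maxPositiveFraction Upper gate on the positive droplet fraction.
#' @slot minSingleFraction Lower gate on the single-molecule fraction.
#' @slot minPositiveDroplets Integer floor on positive droplets.
#' @export
setClass("QCRule",
  representation(maxPositiveFraction = "numeric", minSingleFraction = "numeric",
                 minPositiveDroplets = "integer"),
  validity = function(object) {
    msg <- character()
    f <- c(object@maxPositiveFraction, object@minSingleFraction)
    if (any(f <= 0) || any(f > 1))
      msg <- c(msg, "fraction gates must lie in (0, 1]")
    if (object@minPositiveDroplets < 0L)
      msg <- c(msg, "minPositiveDroplets must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a QCRule
#'
#' @param maxPositiveFraction Default 0.10.
#' @param minSingleFraction Default 0.95.
#' @param minPositiveDroplets Default 1.
#' @return A [QCRule-class] object.
#' @export
#' @examples
#' QCRule()
QCRule <- function(maxPositiveFraction = 0.10, minSingleFraction = 0.95,
                   minPositiveDroplets = 1L) {
  new("QCRule", maxPositiveFraction = maxPositiveFraction,
      minSingleFraction = minSingleFraction,
      minPositiveDroplets = as.integer(minPositiveDroplets))
}

## ---- accessors & show ----

#' @describeIn DropletWell-class well identifier
#' @param x,object Object.
#' @export
wellId <- function(x) x@wellId

#' @describeIn DropletWell-class channel names present in the well
#' @export
channelNames <- function(x) names(x@amplitudes)

#' @describeIn DropletWell-class number of droplets
#' @export
dropletCount <- function(x) x@dropletCount

#' @describeIn DropletWell-class amplitudes of one channel
#' @param channel Channel/CpG name.
#' @export
amplitudes <- function(x, channel) {
  if (!channel %in% names(x@amplitudes))
    stop("unknown channel '", channel, "' in well ", x@wellId)
  x@amplitudes[[channel]]
}

#' Methylated-droplet count of a ClusterCounts
#'
#' For channels labeling the methylated allele this is the high-amplitude
#' cluster; for channels labeling the unmethylated allele it is the remaining
#' (single-positive) droplets.
#' @param counts A [ClusterCounts-class] object.
#' @return Integer count.
#' @export
methylatedCount <- function(counts) {
  if (counts@labeledAllele == "methylated") counts@nAllele
  else counts@nPositiveTotal - counts@nAllele
}

#' Unmethylated-droplet count of a ClusterCounts
#' @param counts A [ClusterCounts-class] object.
#' @return Integer count.
#' @export
unmethylatedCount <- function(counts) counts@nPositiveTotal - methylatedCount(counts)

setMethod("show", "DropletWell", function(object) {
  cat(sprintf("DropletWell '%s': %d droplets, %d channel(s): %s\n",
              object@wellId, object@dropletCount, length(object@amplitudes),
              paste(names(object@amplitudes), collapse = ", ")))
})

setMethod("show", "ClusterCounts", function(object) {
  cat(sprintf("ClusterCounts [%s, labeled=%s]: total=%d neg=%d pos=%d allele=%d\n",
              object@cpg, object@labeledAllele, object@nTotal, object@nNegative,
              object@nPositiveTotal, object@nAllele))
})

setMethod("show", "PoissonQuant", function(object) {
  cat(sprintf("PoissonQuant [%s]: p=%.4f lambda=%.4f copies=%.1f single=%.4f QC %s\n",
              object@cpg, object@pPositive, object@lambda, object@copies,
              object@singleFraction, if (object@pass) "PASS" else "FAIL"))
})

setMethod("show", "MethylationResult", function(object) {
  cat(sprintf("MethylationResult [%s]: beta=%.4f (M=%d, U=%d), QC %s\n",
              object@cpg, object@beta, object@M, object@U,
              if (object@qc@pass) "PASS" else "FAIL"))
})
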