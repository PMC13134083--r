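## Synthetic cohort generator: six CpGs whose mean methylation follows signed,
## partly nonlinear trajectories over age, with Gaussian beta-scale noise.
## Three loci (ELOVL2, EDARADD, CCDC102B) flatten with age and are modeled as
## exponential approaches to an asymptote; the rest are linear. Default noise
## SDs are calibrated so that at n = 351 over ages 0-95 the per-CpG sample
## correlations with age land in the 0.83-0.93 magnitude band typical of
## blood methylation at these loci.

#' Age-trajectory model of one CpG
#'
#' The mean methylation curve is either linear,
#' \eqn{\beta(a) = b_0 + s\,a}, or saturating,
#' \eqn{\beta(a) = A + (b_0 - A) e^{-r a}} (an exponential approach from the
#' baseline \eqn{b_0} at age 0 to the asymptote \eqn{A}); observed values add
#' Gaussian noise and are truncated to [0, 1].
#'
#' @param cpg CpG name.
#' @param direction +1 (methylation rises with age) or -1 (falls).
#' @param shape \code{"linear"} or \code{"saturating"}.
#' @param baseline Mean beta at age 0.
#' @param slope Beta units per year (linear shape).
#' @param rate Per-year approach rate (saturating shape).
#' @param asymptote Limiting beta (saturating shape).
#' @param noiseSd Beta-scale Gaussian noise SD, > 0.
#' @return A list of class \code{CpGAgeModel}.
#' @export
cpgAgeModel <- function(cpg, direction, shape = c("linear", "saturating"),
                        baseline, slope = NULL, rate = NULL, asymptote = NULL,
                        noiseSd) {
  shape <- match.arg(shape)
  stopifnot(direction %in% c(-1, 1), noiseSd > 0,
            baseline >= 0, baseline <= 1)
  if (shape == "linear" && is.null(slope)) stop("linear shape needs 'slope'")
  if (shape == "saturating" && (is.null(rate) || is.null(asymptote)))
    stop("saturating shape needs 'rate' and 'asymptote'")
  structure(list(cpg = cpg, direction = direction, shape = shape,
                 baseline = baseline, slope = slope, rate = rate,
                 asymptote = asymptote, noiseSd = noiseSd),
            class = "CpGAgeModel")
}

#' Mean methylation of a CpG model at given ages
#'
#' @param model A [cpgAgeModel()].
#' @param age Numeric vector of ages in years.
#' @return Mean beta values (not noise-perturbed, not truncated).
#' @export
meanCurve <- function(model, age) {
  stopifnot(inherits(model, "CpGAgeModel"))
  if (model$shape == "linear") model$baseline + model$slope * age
  else model$asymptote + (model$baseline - model$asymptote) * exp(-model$rate * age)
}

#' Default six-CpG age models
#'
#' Trajectories emulating blood methylation at the panel loci: ELOVL2 and
#' FHL2 rise with age, the other four fall; ELOVL2, EDARADD and CCDC102B
#' saturate (their age trend flattens in older individuals) while the rest
#' are linear. Parameters are synthetic stand-ins chosen so the simulated
#' age-methylation correlations at n = 351 match the magnitudes observed in
#' blood (|r| roughly 0.83-0.93).
#'
#' @return Named list of six [cpgAgeModel()] objects.
#' @export
#' @examples
#' names(defaultCpGAgeModels())
defaultCpGAgeModels <- function() {
  list(
    ASPA = cpgAgeModel("ASPA", -1, "linear", baseline = 0.75,
                       slope = -0.0045, noiseSd = 0.072),
    C1orf132 = cpgAgeModel("C1orf132", -1, "linear", baseline = 0.85,
                           slope = -0.0060, noiseSd = 0.065),
    CCDC102B = cpgAgeModel("CCDC102B", -1, "saturating", baseline = 0.85,
                           rate = 0.025, asymptote = 0.30, noiseSd = 0.073),
    EDARADD = cpgAgeModel("EDARADD", -1, "saturating", baseline = 0.60,
                          rate = 0.030, asymptote = 0.12, noiseSd = 0.051),
    ELOVL2 = cpgAgeModel("ELOVL2", +1, "saturating", baseline = 0.05,
                         rate = 0.025, asymptote = 0.80, noiseSd = 0.095),
    FHL2 = cpgAgeModel("FHL2", +1, "linear", baseline = 0.10,
                       slope = 0.0055, noiseSd = 0.060)
  )
}

#' Simulate an age-structured methylation cohort
#'
#' Draws ages uniformly on \code{ageRange}, a balanced sex label with no
#' methylation effect, and per-CpG beta values as mean curve plus Gaussian
#' noise, truncated to [0, 1]. Deterministic under \code{seed}.
#'
#' @param models Named list of [cpgAgeModel()] objects (default: the
#'   six-CpG panel defaults).
#' @param n Number of samples (>= 2).
#' @param ageRange Two-element numeric range in years, default \code{c(0, 95)}.
#' @param seed Integer seed.
#' @return \code{data.frame} with columns \code{sample_id, age, sex} and one
#'   beta column per CpG.
#' @export
#' @examples
#' head(simulateCohort(n = 5, seed = 7))
simulateCohort <- function(models = defaultCpGAgeModels(), n = 351L,
                           ageRange = c(0, 95), seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (length(ageRange) != 2L || diff(ageRange) <= 0)
    stop("degenerate age range")
  for (m in models) {
    grid <- seq(ageRange[1L], ageRange[2L], length.out = 200L)
    mu <- meanCurve(m, grid)
    if (any(mu < 0 | mu > 1))
      stop("mean curve of '", m$cpg, "' leaves [0, 1] on the age range")
  }
  set.seed(as.integer(seed))
  age <- runif(n, ageRange[1L], ageRange[2L])
  sex <- sample(rep_len(c("F", "M"), n))
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)), age = age,
                    sex = sex, stringsAsFactors = FALSE)
  for (m in models) {
    beta <- meanCurve(m, age) + rnorm(n, 0, m$noiseSd)
    out[[m$cpg]] <- pmin(1, pmax(0, beta))
  }
  out
}

#' Stratified train/test split of a cohort
#'
#' Splits a cohort into disjoint, exhaustive train and test sets, stratified
#' by age decile (deciles of the observed ages) so both halves cover the full
#' age range. Deterministic under \code{seed}.
#'
#' @param cohort Cohort \code{data.frame} with an \code{age} column and
#'   unique \code{sample_id}s.
#' @param testFraction Fraction assigned to the test set, in (0, 1).
#' @param seed Integer seed.
#' @return List with elements \code{train} and \code{test}.
#' @export
splitCohort <- function(cohort, testFraction = 0.25, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample ids")
  set.seed(as.integer(seed))
  qs <- quantile(cohort$age, probs = seq(0, 1, 0.1), names = FALSE)
  stratum <- cut(cohort$age, breaks = unique(qs), include.lowest = TRUE)
  strata <- split(seq_len(nrow(cohort)), stratum)
  ## largest-remainder allocation so the overall test fraction is honored
  ## while every age decile contributes proportionally
  target <- vapply(strata, length, integer(1)) * testFraction
  k <- floor(target)
  extra <- round(nrow(cohort) * testFraction) - sum(k)
  if (extra > 0) {
    ord <- order(target - k, decreasing = TRUE)
    k[ord[seq_len(extra)]] <- k[ord[seq_len(extra)]] + 1L
  }
  testIdx <- unlist(lapply(seq_along(strata), function(i) {
    if (k[i] >= 1L) sample(strata[[i]], k[i]) else integer()
  }), use.names = FALSE)
  list(train = cohort[setdiff(seq_len(nrow(cohort)), testIdx), , drop = FALSE],
       test = cohort[sort(testIdx), , drop = FALSE])
}
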