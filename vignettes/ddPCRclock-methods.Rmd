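---
title: "Methods: droplet-level methylation quantification and six-CpG clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet-level methylation quantification and six-CpG clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddPCRclock)
```

# The measurement model

## Droplets, thresholds, and the methylation fraction

A multiplex ddPCR well partitions a bisulfite-converted DNA sample into
roughly 20,000 nanoliter droplets. In each fluorescence channel, one locus is
detected with probes such that *any* target molecule makes a droplet
positive, while the fluorescently labeled allele (methylated for *CCDC102B*
and *ELOVL2*, unmethylated for *ASPA*, *C1orf132*, *EDARADD*, *FHL2*) lifts
the droplet into a distinct high-amplitude cluster. The analysis is purely
threshold-based, one channel at a time: a droplet with amplitude strictly
greater than `tTotal` is positive, and strictly greater than `tAllele` it
belongs to the labeled-allele cluster. The instrument software never
documents what happens to a droplet exactly at a threshold, so the package
fixes the convention (strict `>` means above) and applies it uniformly;
'rain' droplets between clusters are assigned by the thresholds alone, with
no model-based rescue, because in this assay rain is managed upstream by
probe design rather than by an algorithm.

Writing M and U for the methylated- and unmethylated-droplet counts of a
channel, the methylation fraction is

$$\beta = \frac{M}{M+U} \;=\; 1 - \frac{U}{M+U},$$

the two orientation-specific forms being the same quantity. The package
computes both from the same `(M, U)` pair, so orientation cannot change the
result; a channel with $M+U=0$ raises an explicit error rather than
returning 0 or NaN.

## Poisson limiting-dilution statistics

Molecules land in droplets essentially independently, so per-droplet counts
are Poisson with occupancy $\lambda$ recovered from the positive fraction
$p$ as $\lambda = -\ln(1-p)$, total copies $\lambda n$, and single-molecule
fraction among positives

$$P(K{=}1 \mid K{\ge}1) = \frac{\lambda e^{-\lambda}}{1-e^{-\lambda}}.$$

At $p = 13.17\%$ this gives $93.11\%$ and at $p = 0.08\%$ it gives
$99.96\%$ — the working range of the assay's dilution series. Quality
control follows the recommended operating window: at most 10 % positive
droplets per channel and at least 95 % single-molecule occupancy, both
gates inclusive at their boundary, plus a floor of at least one positive
droplet. One nuance worth knowing: at *exactly* $p = 0.10$ the
single-molecule fraction is $94.82\%$, slightly under the 95 % gate, so
with the default rule the occupancy gate is the binding one near the
boundary ($p \lesssim 0.0975$ passes both). The two gates are kept
independent and inclusive rather than merged, since users may legitimately
relax one without the other.

## Occupancy-corrected methylation

The count-ratio estimator is accurate at limiting dilution but biased at
high load: a droplet containing both alleles shows the labeled allele's
amplitude, so co-occupied droplets are absorbed by the labeled cluster and
$\beta$ drifts toward the labeled allele. `correctedMethylation()` treats
the two alleles as independent Poisson processes. The labeled allele's
occupancy comes from its marginal cluster fraction,
$\lambda_{lab} = -\ln(1 - n_{allele}/n)$, which is exact because any labeled
molecule puts its droplet in the high cluster. The other allele is only
visible in droplets *free* of labeled molecules, so its occupancy is
estimated conditionally on that subset,
$\lambda_{other} = -\ln\!\big(1 - \tfrac{n_{pos}-n_{allele}}{\,n-n_{allele}}\big)$;
under independence the conditional occupancy equals the marginal one. The
corrected fraction is $\lambda_M/(\lambda_M+\lambda_U)$. A naive marginal
version ($-\ln(1 - (n_{pos}-n_{allele})/n)$ for the unlabeled allele) is
*worse* than the plain ratio, because it ignores exactly the hidden
co-occupied droplets the correction is meant to recover — at ~45 % positive
droplets and true $\beta = 0.5$, Monte-Carlo mean absolute error is about
0.075 for the ratio, 0.085 for the naive correction, and 0.004 for the
conditional form implemented here. The printed count-ratio estimator
remains the default everywhere; the correction is opt-in.

Binomial (Wilson) intervals on $M/(M+U)$ are provided as an extension for
flagging low-count wells; they are not part of the assay's printed analysis.

# The droplet-well simulator

`simulateWell()` draws, per channel, the methylated molecule count as
Binomial(total, $\beta_{true}$), scatters each molecule into a droplet
uniformly at random (multinomial occupancy, asymptotically Poisson), labels
each droplet by its true cluster (labeled molecule present → high; any
molecule → positive; else negative), and draws amplitudes from per-cluster
Gaussians. Defaults place clusters at 1000/4000/8000 arbitrary fluorescence
units with SDs 100/150/200 — gaps of many cluster SDs, so the default
midpoint thresholds (2500 and 6000) are unambiguous. Real amplitude scales
and spreads vary by channel and instrument and are configurable; the
defaults are synthetic.

Rain is modeled as displacement: with probability `rainFraction`, a
high-cluster droplet's amplitude is redrawn uniformly on the inter-cluster
interval, so part of the labeled cluster falls below `tAllele` and the
labeled allele is undercounted. With the labeled allele the rarer one (as
the assay's probe design prefers), rain therefore biases $\beta$ toward the
common allele, which the test suite verifies by sign test.

Mass inputs convert to molecules at 3.3 pg per haploid genome with an
"amplifiable fraction" default of 0.2, reflecting bisulfite degradation and
partial amplification. This is a modeling choice, not a measured constant:
it places a 40 ng input near the positive-droplet counts seen at the top of
the assay's sensitivity series. Dilution series scale molecules by a
strictly increasing factor list with per-well deterministic sub-seeds
(`seed + 1000*level + replicate`), making every simulated artifact
bit-reproducible from `(seed, config)`.

What the simulator does *not* emulate: PCR kinetics, probe chemistry,
droplet volume variation, cross-channel spectral overlap, or cluster-shape
asymmetries. Tests passing on simulated wells therefore validate the
counting, Poisson and QC arithmetic — not robustness to instrument-specific
amplitude pathologies.

# The cohort simulator

`simulateCohort()` draws ages uniformly on 0–95 years, a balanced sex label
with no methylation effect (matching the absence of sex bias at these
loci), and per-CpG betas as a mean trajectory plus Gaussian noise truncated
to $[0,1]$. *ELOVL2* and *FHL2* rise with age; the other four fall.
*ELOVL2*, *EDARADD* and *CCDC102B* flatten in older individuals and use a
saturating curve $\beta(a) = A + (b_0 - A)e^{-ra}$; the rest are linear.
The true functional forms at these loci are not published; the exponential
approach is a stated stand-in chosen for its monotone, flattening shape.

Curve parameters and noise SDs were calibrated once, by Monte-Carlo at
n = 351, so each locus's sample correlation with age falls in the
0.80–0.95 magnitude band (means roughly 0.85–0.93) that blood methylation
shows at these sites, with truncation affecting well under 1 % of values
and the quadratic age term significant for the saturating trio. The
defaults are frozen; they are study conditions, not tuning knobs.
`splitCohort()` stratifies by age decile with largest-remainder allocation,
so both halves cover the full age range and the overall test fraction is
honored exactly.

# Preprocessing

For the three saturating loci, a strictly monotone transform is selected on
*training data only* from a fixed candidate family — identity, `log`
(floored at $10^{-6}$), logit (clipped), square root, square — maximizing
$|r|$ between transformed beta and age. Identity is always a candidate, so
selection can never reduce training $|r|$; on an exactly exponential
trajectory the log candidate linearizes perfectly. After transformation,
every CpG is standardized with the training mean and SD (divisor $n-1$).
"Raw" mode skips the transform search and standardizes only. Applying a
fitted preprocessor to new data never updates its state; a dedicated test
mutates the test set and asserts the state is unchanged.

# Clock families

ENR (glmnet), GBR (xgboost, single-threaded), and SVM regression with
linear and radial kernels (e1071, fitted with `scale = FALSE` on the
already-standardized inputs) select hyperparameters by seeded 5-fold
cross-validation on the training set only: ENR over an alpha grid with the
lambda path extended down to 0 (so a noiseless linear signal is fitted
exactly), GBR over tree depth at fixed learning rate and 400 rounds, SVMs
over cost (and gamma for the radial kernel). The tuning protocol of the
original benchmark is not published; these grids are deliberately small,
deterministic stand-ins. SVM predictions are always evaluated from the
stored support vectors, coefficients and offset, so a serialized model
reloads with bit-identical predictions; GBR serializes the booster's raw
JSON; ENR and KDR store their coefficients directly. Model files carry a
format version and 17-significant-digit numbers, which round-trip doubles
exactly.

## The Klemera-Doubal estimator

Each (preprocessed) marker is regressed on chronological age by OLS,
$x_j = q_j + k_j\,CA + e_j$, keeping the intercept $q_j$, slope $k_j$ and
residual SD $s_j$; a marker with $|k_j|$ numerically zero is rejected as
uninformative. The age-blind estimate is the precision-weighted combination

$$BA_E = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j (k_j/s_j)^2},$$

and the age-anchored variant treats chronological age as an additional
noisy marker of biological age with SD $s_{BA}$:

$$BA_{EC} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2 + CA/s_{BA}^2}
                 {\sum_j (k_j/s_j)^2 + 1/s_{BA}^2}.$$

$s_{BA}$ is estimated as the training variance of $BA_E - CA$ minus the
propagated measurement-noise variance of $BA_E$ (which is
$1/\sum_j (k_j/s_j)^2$), floored at 0.5 years so the anchored variant stays
defined when markers are nearly exact. The floor is a numerical guard, not
a biological claim. BA_EC is the default variant because this class of
model takes chronological age as an input in its intended use; BA_E is
available for age-blind prediction. As $s_{BA} \to \infty$, BA_EC → BA_E;
as $s_{BA} \to 0$, BA_EC → CA — both limits are tested, and the whole
predictor is checked against an independently coded brute-force weighted
sum at tolerance $10^{-10}$.

Note what the anchoring implies for benchmarks: on cohorts where the
markers are tight, $s_{BA}$ is small and BA_EC tracks chronological age
closely, which is why KDR posts the best *test* errors among the families
while boosting, which interpolates, posts the best *training* errors. This
ordering is a qualitative property of the estimators and is asserted on
simulated cohorts; exact benchmark numbers depend on the original cohort
table, which is not redistributable here.

## Evaluation, acceleration, subset search

Metrics are Pearson's $r$, $R^2 = 1 - SS_{res}/SS_{tot}$ (negative out of
sample is possible), MAE and RMSE, with $r$ flagged `NA` for zero-variance
inputs — constant predictions, or cohorts with no age spread, where a
depressed $r$ is expected on narrow age ranges anyway. Absolute age
acceleration is predicted minus chronological age; relative acceleration is
the residual of predicted on chronological age within the evaluated cohort,
summing to zero by construction and removing the regression-to-the-mean
slope shared by most families. `subsetSearch()` enumerates all
$\binom{6}{2}+\dots+\binom{6}{6} = 57$ subsets per family, returns per-fit
failures as flagged rows, and ranks by test MAE with ties broken by fewer
CpGs then lexicographic subset name, so reports are deterministic.

# Problem sizes and numerical choices

The test suite exercises the methods at their native scale: 20,000-droplet
wells (1,000 of them for the end-to-end recovery check, at 5–30 ng
equivalent input where all QC gates pass), a 100-seed dilution comparison
between ~12,000 and ~94 molecules plus one two-fold series down to ~12
molecules (whose positive-droplet counts span above 2,482 and below 13),
and n = 351 cohorts with a 75/25 stratified split — 20 cohorts for the
family-ordering and subset-search properties, 100 for Klemera-Doubal
parameter-recovery coverage. Key numerical conventions: strict-`>`
threshold boundaries; inclusive QC gates; `log1p`-based occupancy for
accuracy at small $p$; residual SDs floored at $10^{-8}$ and $s_{BA}$ at
0.5 years; identity-first tie-breaking in the transform search; and a
single master seed with deterministic sub-seeds for every simulated
artifact.

# Limitations

Thresholds are supplied, not learned — automatic cluster detection is the
instrument software's job and out of scope, as are 2-D cluster
deconvolution and primer/probe design. The simulators' defaults are
synthetic stand-ins wherever the underlying distributions are unpublished
(amplitude scales, trajectory shapes, cohort age composition), so absolute
performance numbers on simulated data characterize the estimators under
these stated conditions, not the original instrument or cohort. Volume
calibration to copies/µl is not provided (droplet volume is not part of the
model), and multi-well merged quantification is not implemented.
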