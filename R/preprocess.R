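#' Preprocessor: per-CpG transform and standardization state
#'
#' Holds the preprocessing fitted on training data only: for a designated set
#' of nonlinear CpGs, a strictly monotone one-dimensional transform selected
#' from a fixed candidate family to maximize the magnitude of the Pearson
#' correlation between transformed methylation and age; then per-CpG
#' centering and scaling (mean/SD with divisor n-1) computed after
#' transformation. Applying the preprocessor to new data never updates its
#' state.
#'
#' @slot cpgs CpG columns the preprocessor covers.
#' @slot transformSet CpGs eligible for transformation.
#' @slot transforms Named list (per CpG in \code{cpgs}) with the selected
#'   transform name.
#' @slot center,scale Named numeric standardization parameters.
#' @export
setClass("Preprocessor",
  representation(cpgs = "character", transformSet = "character",
                 transforms = "list", center = "numeric", scale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@transformSet %in% object@cpgs))
      msg <- c(msg, "transformSet must be a subset of cpgs")
    if (any(object@scale <= 0)) msg <- c(msg, "scale values must be > 0")
    if (length(msg)) msg else TRUE
  })

## Candidate transform family: strictly increasing maps on (0, 1). Identity is
## always a candidate, so selection can never reduce |r| on training data.
.transformFuns <- list(
  identity = function(x) x,
  log      = function(x) log(pmax(x, 1e-6)),
  logit    = function(x) stats::qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)),
  sqrt     = function(x) sqrt(pmax(x, 0)),
  square   = function(x) x^2
)

#' Names of the candidate methylation transforms
#' @return Character vector.
#' @export
transformCandidates <- function() names(.transformFuns)

#' Fit preprocessing on a training cohort
#'
#' When \code{transform = TRUE}, each CpG in \code{transformSet} (by default
#' the three loci whose methylation flattens with age) gets the candidate
#' transform maximizing \code{|cor(f(beta), age)|} on the training data; all
#' other CpGs keep the identity. When \code{transform = FALSE} ("raw" mode),
#' every CpG keeps the identity and only standardization is fitted.
#' Standardization (mean and SD) is always computed on the transformed
#' training columns.
#'
#' @param train Training cohort \code{data.frame} with \code{age} and beta
#'   columns; needs at least 10 samples spanning more than 20 years.
#' @param transform Logical: search the transform family?
#' @param cpgs CpG columns to preprocess (default: the six-CpG panel).
#' @param transformSet CpGs eligible for transformation.
#' @return A [Preprocessor-class] object.
#' @export
fitPreprocessor <- function(train, transform = TRUE, cpgs = cpgPanel(),
                            transformSet = c("CCDC102B", "EDARADD", "ELOVL2")) {
  missing <- setdiff(c("age", cpgs), names(train))
  if (length(missing))
    stop("training data lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(train) < 10L) stop("need at least 10 training samples")
  if (diff(range(train$age)) <= 20)
    stop("training ages must span more than 20 years")
  transformSet <- intersect(transformSet, cpgs)
  transforms <- list()
  center <- scale <- setNames(numeric(length(cpgs)), cpgs)
  for (cpg in cpgs) {
    x <- train[[cpg]]
    if (sd(x) == 0) stop("zero-variance CpG column '", cpg, "'")
    name <- "identity"
    if (transform && cpg %in% transformSet) {
      rs <- vapply(.transformFuns, function(f) {
        fx <- f(x)
        if (sd(fx) == 0) 0 else abs(cor(fx, train$age))
      }, numeric(1))
      name <- names(rs)[which.max(rs)]
    }
    fx <- .transformFuns[[name]](x)
    transforms[[cpg]] <- list(name = name)
    center[cpg] <- mean(fx)
    scale[cpg] <- sd(fx)
    if (scale[cpg] == 0) stop("zero-variance transformed column '", cpg, "'")
  }
  new("Preprocessor", cpgs = cpgs, transformSet = transformSet,
      transforms = transforms, center = center, scale = scale)
}

#' Apply fitted preprocessing to a cohort
#'
#' Transforms and standardizes the CpG columns with the state learned at fit
#' time; all other columns pass through unchanged. The preprocessor itself is
#' immutable under application (no leakage of statistics from new data).
#'
#' @param prep A [Preprocessor-class].
#' @param data Cohort \code{data.frame} containing the preprocessor's CpG
#'   columns.
#' @return \code{data.frame} with preprocessed CpG columns.
#' @export
applyPreprocessor <- function(prep, data) {
  stopifnot(is(prep, "Preprocessor"))
  missing <- setdiff(prep@cpgs, names(data))
  if (length(missing))
    stop("data lacks CpG column(s): ", paste(missing, collapse = ", "))
  out <- data
  for (cpg in prep@cpgs) {
    f <- .transformFuns[[prep@transforms[[cpg]]$name]]
    out[[cpg]] <- (f(data[[cpg]]) - prep@center[cpg]) / prep@scale[cpg]
  }
  out
}

setMethod("show", "Preprocessor", function(object) {
  tr <- vapply(object@transforms, `[[`, character(1), "name")
  cat("Preprocessor over", length(object@cpgs), "CpG(s)\n")
  cat("  transforms:", paste(sprintf("%s=%s", names(tr), tr), collapse = ", "), "\n")
})
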