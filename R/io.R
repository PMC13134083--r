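## Versioned JSON model files and cohort CSV helpers.

.MODEL_FORMAT_VERSION <- "1.0"

#' Write a trained clock to a versioned JSON model file
#'
#' Serializes the family, CpG subset, preprocessing state and all model
#' parameters (coefficients, support vectors, boosted-tree dump, or
#' Klemera-Doubal parameters) at full numeric precision, so that
#' [readClock()] restores a clock with bit-identical predictions.
#'
#' @param clock A [TrainedClock-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeClock <- function(clock, path) {
  stopifnot(is(clock, "TrainedClock"))
  prep <- clock@preprocessor
  fit <- clock@fit
  payload <- switch(clock@family,
    enr = list(a0 = fit$a0, beta = as.list(fit$beta), alpha = fit$alpha,
               lambda = fit$lambda),
    gbr = list(rawJson = fit$rawJson, maxDepth = fit$maxDepth, eta = fit$eta,
               nrounds = fit$nrounds),
    svml = ,
    svmr = list(kernel = fit$kernel, cost = fit$cost, gamma = fit$gamma,
                rho = fit$rho, coefs = fit$coefs, SV = fit$SV,
                svColumns = fit$svColumns),
    kdr = {
      p <- fit$params
      list(cpgs = p@cpgs, q = as.list(p@q), k = as.list(p@k),
           s = as.list(p@s), sBA = p@sBA, variant = p@variant)
    })
  obj <- list(
    format = "ddPCRclock-model", version = .MODEL_FORMAT_VERSION,
    family = clock@family, cpgSubset = clock@cpgSubset, seed = clock@seed,
    preprocessor = list(
      cpgs = prep@cpgs, transformSet = prep@transformSet,
      transforms = lapply(prep@transforms, `[[`, "name"),
      center = as.list(prep@center), scale = as.list(prep@scale)),
    fit = payload)
  ## 17 significant digits: doubles survive the text round trip exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' Read a trained clock from a JSON model file
#'
#' @param path Model file written by [writeClock()].
#' @return A [TrainedClock-class].
#' @export
readClock <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ddPCRclock-model"))
    stop("not a ddPCRclock model file: ", path)
  if (!identical(obj$version, .MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", obj$version)
  pr <- obj$preprocessor
  prep <- new("Preprocessor", cpgs = pr$cpgs, transformSet = pr$transformSet,
              transforms = lapply(pr$transforms, function(nm) list(name = nm)),
              center = unlist(pr$center), scale = unlist(pr$scale))
  fit <- switch(obj$family,
    enr = list(a0 = obj$fit$a0, beta = unlist(obj$fit$beta),
               alpha = obj$fit$alpha, lambda = obj$fit$lambda),
    gbr = list(rawJson = obj$fit$rawJson, maxDepth = obj$fit$maxDepth,
               eta = obj$fit$eta, nrounds = obj$fit$nrounds,
               booster = xgboost::xgb.load.raw(charToRaw(obj$fit$rawJson))),
    svml = ,
    svmr = list(kernel = obj$fit$kernel, cost = obj$fit$cost,
                gamma = obj$fit$gamma, rho = obj$fit$rho,
                coefs = obj$fit$coefs, SV = as.matrix(obj$fit$SV),
                svColumns = obj$fit$svColumns),
    kdr = list(params = new("KDRParameters", cpgs = obj$fit$cpgs,
                            q = unlist(obj$fit$q), k = unlist(obj$fit$k),
                            s = unlist(obj$fit$s), sBA = obj$fit$sBA,
                            variant = obj$fit$variant)))
  new("TrainedClock", family = obj$family, cpgSubset = obj$cpgSubset,
      preprocessor = prep, fit = fit, seed = as.integer(obj$seed))
}

#' Read a cohort CSV
#'
#' Expects columns \code{sample_id, age} plus one beta column per CpG;
#' \code{sex} is optional. Betas are validated to lie in [0, 1].
#'
#' @param path CSV file path.
#' @param cpgs CpG columns required (default: any panel CpGs present).
#' @return Cohort \code{data.frame}.
#' @export
readCohort <- function(path, cpgs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% names(df)))
    stop("cohort CSV needs 'sample_id' and 'age' columns")
  if (is.null(cpgs)) cpgs <- intersect(cpgPanel(), names(df))
  missing <- setdiff(cpgs, names(df))
  if (length(missing))
    stop("cohort CSV lacks CpG column(s): ", paste(missing, collapse = ", "))
  for (cpg in cpgs) {
    b <- df[[cpg]]
    if (any(!is.finite(b)) || any(b < 0 | b > 1))
      stop("column '", cpg, "' has values outside [0, 1]")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  df
}

#' Write a cohort CSV
#'
#' @param cohort Cohort \code{data.frame}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
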