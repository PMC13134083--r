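#' KDRParameters: fitted Klemera-Doubal estimator
#'
#' Per-marker linear calibrations of (preprocessed) methylation on
#' chronological age, plus the biological-age deviation scale used by the
#' age-anchored variant.
#'
#' @slot cpgs Marker names.
#' @slot q Per-marker intercepts of the marker-on-age regressions.
#' @slot k Per-marker slopes (beta units per year), all nonzero.
#' @slot s Per-marker residual SDs, all positive.
#' @slot sBA SD of the biological-age deviation (years).
#' @slot variant \code{"BA_E"} (age-blind) or \code{"BA_EC"} (uses
#'   chronological age as an additional noisy marker of itself).
#' @export
setClass("KDRParameters",
  representation(cpgs = "character", q = "numeric", k = "numeric",
                 s = "numeric", sBA = "numeric", variant = "character"),
  validity = function(object) {
    msg <- character()
    m <- length(object@cpgs)
    if (length(object@q) != m || length(object@k) != m || length(object@s) != m)
      msg <- c(msg, "q, k, s must have one entry per marker")
    if (any(object@k == 0)) msg <- c(msg, "every slope k must be nonzero")
    if (any(object@s <= 0)) msg <- c(msg, "every residual SD s must be > 0")
    if (!(object@variant %in% c("BA_E", "BA_EC")))
      msg <- c(msg, "variant must be 'BA_E' or 'BA_EC'")
    if (object@variant == "BA_EC" && object@sBA <= 0)
      msg <- c(msg, "sBA must be > 0 for BA_EC")
    if (length(msg)) msg else TRUE
  })

#' Fit the Klemera-Doubal estimator
#'
#' Each marker \eqn{x_j} is regressed on chronological age by ordinary least
#' squares, \eqn{x_j = q_j + k_j \cdot CA + e_j}, yielding intercept
#' \eqn{q_j}, slope \eqn{k_j} and residual SD \eqn{s_j}. Markers with slope
#' exactly zero carry no age information and are rejected. The
#' biological-age deviation scale \eqn{s_{BA}} is estimated from the training
#' variance of \eqn{BA_E - CA} minus the propagated measurement-noise
#' variance of \eqn{BA_E} (which is \eqn{1/\sum_j (k_j/s_j)^2}), floored at a
#' small positive constant (default 0.5 years) to keep the age-anchored
#' variant defined when markers are nearly exact.
#'
#' @param train \code{data.frame} with an \code{age} column and one
#'   (preprocessed) column per marker in \code{cpgSubset}.
#' @param cpgSubset Marker columns to use.
#' @param variant \code{"BA_EC"} (default) or \code{"BA_E"}.
#' @param sBaFloor Positivity floor on \eqn{s_{BA}}, in years.
#' @return A [KDRParameters-class] object.
#' @export
#' @examples
#' cohort <- simulateCohort(n = 200, seed = 3)
#' kdrFit(cohort, c("ELOVL2", "FHL2"))
kdrFit <- function(train, cpgSubset, variant = c("BA_EC", "BA_E"),
                   sBaFloor = 0.5) {
  variant <- match.arg(variant)
  missing <- setdiff(c("age", cpgSubset), names(train))
  if (length(missing))
    stop("training data lacks column(s): ", paste(missing, collapse = ", "))
  m <- length(cpgSubset)
  q <- k <- s <- setNames(numeric(m), cpgSubset)
  for (cpg in cpgSubset) {
    fit <- lm(train[[cpg]] ~ train$age)
    cf <- coef(fit)
    if (!is.finite(cf[2L]) || abs(cf[2L]) < 1e-12)
      stop("marker '", cpg, "' is uninformative (zero slope on age)")
    q[cpg] <- cf[1L]
    k[cpg] <- cf[2L]
    rs <- sqrt(sum(residuals(fit)^2) / max(1L, fit$df.residual))
    s[cpg] <- max(rs, 1e-8)  # guard exact markers
  }
  params <- new("KDRParameters", cpgs = cpgSubset, q = q, k = k, s = s,
                sBA = sBaFloor, variant = "BA_E")
  baE <- kdrPredict(params, train)
  noiseVar <- 1 / sum((k / s)^2)
  sBA <- sqrt(max(var(baE - train$age) - noiseVar, sBaFloor^2))
  new("KDRParameters", cpgs = cpgSubset, q = q, k = k, s = s, sBA = sBA,
      variant = variant)
}

#' Predict biological age with the Klemera-Doubal estimator
#'
#' The age-blind estimate is the precision-weighted combination of the
#' per-marker age readings,
#' \deqn{BA_E = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j (k_j/s_j)^2};}
#' the age-anchored variant additionally treats chronological age as a
#' marker of biological age with SD \eqn{s_{BA}},
#' \deqn{BA_{EC} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2 + CA/s_{BA}^2}
#'                      {\sum_j (k_j/s_j)^2 + 1/s_{BA}^2}.}
#' As \eqn{s_{BA} \to \infty} the anchored estimate tends to \eqn{BA_E}; as
#' \eqn{s_{BA} \to 0} it tends to \eqn{CA}.
#'
#' @param params A [KDRParameters-class] object.
#' @param data \code{data.frame} (or single named vector) with the marker
#'   columns; the \code{BA_EC} variant additionally requires
#'   \code{chronologicalAge} (or an \code{age} column).
#' @param chronologicalAge Optional numeric vector of chronological ages,
#'   overriding \code{data$age}.
#' @return Numeric vector of predicted ages in years.
#' @export
kdrPredict <- function(params, data, chronologicalAge = NULL) {
  stopifnot(is(params, "KDRParameters"))
  if (!is.data.frame(data)) data <- as.data.frame(as.list(data))
  missing <- setdiff(params@cpgs, names(data))
  if (length(missing))
    stop("data lacks marker column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(data[params@cpgs])
  w <- params@k / params@s^2
  denom <- sum((params@k / params@s)^2)
  num <- as.numeric(sweep(X, 2L, params@q) %*% w)
  if (params@variant == "BA_E") return(num / denom)
  ca <- if (!is.null(chronologicalAge)) chronologicalAge else data[["age"]]
  if (is.null(ca))
    stop("the BA_EC variant requires chronological age as input ",
         "(supply 'chronologicalAge' or an 'age' column)")
  (num + ca / params@sBA^2) / (denom + 1 / params@sBA^2)
}

setMethod("show", "KDRParameters", function(object) {
  cat(sprintf("KDRParameters (%s), %d marker(s), sBA=%.3f years\n",
              object@variant, length(object@cpgs), object@sBA))
  print(data.frame(cpg = object@cpgs, q = unname(object@q),
                   k = unname(object@k), s = unname(object@s)))
})
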