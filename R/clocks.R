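#' @include preprocess.R kdr.R
NULL

#' TrainedClock: a fitted age-prediction model
#'
#' One fitted clock of a given family with its preprocessing state and CpG
#' subset. Clocks predict from exactly their subset, and serialize to
#' versioned JSON ([writeClock()]) from which they reload with bit-identical
#' predictions.
#'
#' @slot family One of \code{"enr"}, \code{"gbr"}, \code{"svml"},
#'   \code{"svmr"}, \code{"kdr"}.
#' @slot cpgSubset 2-6 CpG names.
#' @slot preprocessor The training-fitted [Preprocessor-class].
#' @slot fit Family-specific parameter list.
#' @slot seed Fit seed.
#' @export
setClass("TrainedClock",
  representation(family = "character", cpgSubset = "character",
                 preprocessor = "Preprocessor", fit = "list",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@family %in% clockFamilies()))
      msg <- c(msg, paste("family must be one of:",
                          paste(clockFamilies(), collapse = ", ")))
    if (length(object@cpgSubset) < 2L || length(object@cpgSubset) > 6L)
      msg <- c(msg, "cpgSubset must contain 2-6 CpGs")
    if (!all(object@cpgSubset %in% object@preprocessor@cpgs))
      msg <- c(msg, "cpgSubset must be covered by the preprocessor")
    if (length(msg)) msg else TRUE
  })

#' Supported clock families
#'
#' Elastic net regression (\code{enr}), gradient boosting regression
#' (\code{gbr}), support vector regression with linear (\code{svml}) and
#' radial (\code{svmr}) kernels, and the Klemera-Doubal estimator
#' (\code{kdr}).
#'
#' @return Character vector of family codes.
#' @export
clockFamilies <- function() c("enr", "gbr", "svml", "svmr", "kdr")

.cvFolds <- function(n, k, seed) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(k), n))
}

.fitEnr <- function(X, y, seed) {
  foldid <- .cvFolds(nrow(X), 5L, seed)
  ## lambda path extended down to 0 so a noiseless linear signal can be fitted
  ## exactly when cross-validation prefers no penalty
  best <- NULL
  for (alpha in c(0.1, 0.4, 0.7, 1)) {
    path <- glmnet::glmnet(X, y, alpha = alpha)
    lam <- c(path$lambda, path$lambda[length(path$lambda)] / 100, 0)
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, lambda = lam, foldid = foldid)
    err <- min(cv$cvm)
    if (is.null(best) || err < best$err)
      best <- list(err = err, alpha = alpha, lambda = cv$lambda.min, cv = cv)
  }
  cf <- as.numeric(coef(best$cv, s = best$lambda))
  list(a0 = cf[1L], beta = setNames(cf[-1L], colnames(X)),
       alpha = best$alpha, lambda = best$lambda)
}

.predictEnr <- function(fit, X) as.numeric(fit$a0 + X %*% fit$beta[colnames(X)])

.fitGbr <- function(X, y, seed) {
  foldid <- .cvFolds(nrow(X), 5L, seed)
  grid <- expand.grid(max_depth = c(2L, 3L), eta = 0.1)
  nrounds <- 400L
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                   objective = "reg:squarederror", nthread = 1L,
                   seed = as.integer(seed))
    err <- 0
    for (f in 1:5) {
      tr <- foldid != f
      d <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
      m <- xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                              verbose = 0)
      pred <- predict(m, X[!tr, , drop = FALSE])
      err <- err + sum((pred - y[!tr])^2)
    }
    if (is.null(best) || err < best$err)
      best <- list(err = err, params = params)
  }
  d <- xgboost::xgb.DMatrix(X, label = y)
  model <- xgboost::xgb.train(params = best$params, data = d,
                              nrounds = nrounds, verbose = 0)
  raw <- rawToChar(xgboost::xgb.save.raw(model, raw_format = "json"))
  list(rawJson = raw, maxDepth = best$params$max_depth,
       eta = best$params$eta, nrounds = nrounds, booster = model)
}

.gbrBooster <- function(fit) {
  if (!is.null(fit$booster)) fit$booster
  else xgboost::xgb.load.raw(charToRaw(fit$rawJson))
}

.predictGbr <- function(fit, X) as.numeric(predict(.gbrBooster(fit), X))

.fitSvm <- function(X, y, seed, kernel) {
  foldid <- .cvFolds(nrow(X), 5L, seed)
  gammas <- if (kernel == "radial") c(0.5, 1, 2) / ncol(X) else 1 / ncol(X)
  best <- NULL
  for (cost in c(1, 10, 100)) for (gamma in gammas) {
    err <- 0
    for (f in 1:5) {
      tr <- foldid != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], scale = FALSE,
                      kernel = kernel, cost = cost, gamma = gamma,
                      epsilon = 0.1, type = "eps-regression")
      pred <- .svmDecision(m, X[!tr, , drop = FALSE], kernel, gamma)
      err <- err + sum((pred - y[!tr])^2)
    }
    if (is.null(best) || err < best$err)
      best <- list(err = err, cost = cost, gamma = gamma)
  }
  m <- e1071::svm(X, y, scale = FALSE, kernel = kernel, cost = best$cost,
                  gamma = best$gamma, epsilon = 0.1, type = "eps-regression")
  list(kernel = kernel, cost = best$cost, gamma = best$gamma,
       rho = m$rho, coefs = as.numeric(m$coefs),
       SV = unname(as.matrix(m$SV)), svColumns = colnames(X))
}

## decision function of an eps-regression SVM, evaluated from its support
## vectors so serialized models reload bit-identically
.svmDecision <- function(m, X, kernel, gamma) {
  SV <- unname(as.matrix(m$SV))
  K <- if (kernel == "linear") X %*% t(SV)
  else {
    d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * X %*% t(SV)
    exp(-gamma * pmax(d2, 0))
  }
  as.numeric(K %*% as.numeric(m$coefs) - m$rho)
}

.predictSvm <- function(fit, X) {
  X <- X[, fit$svColumns, drop = FALSE]
  .svmDecision(list(SV = fit$SV, coefs = fit$coefs, rho = fit$rho),
               X, fit$kernel, fit$gamma)
}

#' Fit an epigenetic clock
#'
#' Preprocesses the training cohort (transform + standardization fitted on
#' training data only), then fits the requested family on the chosen CpG
#' subset. ENR, GBR and the two SVMs select hyperparameters by seeded 5-fold
#' cross-validation on the training set; KDR is fitted in closed form by
#' [kdrFit()]. All fitting is deterministic under \code{seed}.
#'
#' @param family One of [clockFamilies()].
#' @param train Training cohort with \code{age} and beta columns.
#' @param cpgSubset 2-6 CpG names (default: the full panel).
#' @param transform Search the nonlinearity-correcting transform family?
#'   (\code{FALSE} = "raw" mode, standardization only.)
#' @param preprocessor Optional pre-fitted [Preprocessor-class]; fitted on
#'   \code{train} when \code{NULL}.
#' @param kdrVariant KDR variant, \code{"BA_EC"} (default; requires
#'   chronological age at prediction) or \code{"BA_E"}.
#' @param seed Integer fit seed.
#' @return A [TrainedClock-class] object.
#' @export
#' @examples
#' cohort <- simulateCohort(n = 120, seed = 11)
#' clock <- fitClock("kdr", cohort, seed = 11)
#' evaluateClock(clock, cohort)
fitClock <- function(family = clockFamilies(), train, cpgSubset = cpgPanel(),
                     transform = TRUE, preprocessor = NULL,
                     kdrVariant = c("BA_EC", "BA_E"), seed = 1L) {
  family <- match.arg(family)
  kdrVariant <- match.arg(kdrVariant)
  if (length(cpgSubset) < 2L || length(cpgSubset) > 6L)
    stop("cpgSubset must contain 2-6 CpGs")
  missing <- setdiff(cpgSubset, names(train))
  if (length(missing))
    stop("training data lacks CpG column(s): ", paste(missing, collapse = ", "))
  if (is.null(preprocessor))
    preprocessor <- fitPreprocessor(train, transform = transform,
                                    cpgs = cpgSubset)
  pt <- applyPreprocessor(preprocessor, train)
  X <- as.matrix(pt[cpgSubset])
  y <- pt$age
  if (family != "kdr" && nrow(X) < 10L)
    stop("too few samples for 5-fold cross-validation")
  fit <- switch(family,
    enr = .fitEnr(X, y, seed),
    gbr = .fitGbr(X, y, seed),
    svml = .fitSvm(X, y, seed, "linear"),
    svmr = .fitSvm(X, y, seed, "radial"),
    kdr = list(params = kdrFit(pt, cpgSubset, variant = kdrVariant)))
  new("TrainedClock", family = family, cpgSubset = cpgSubset,
      preprocessor = preprocessor, fit = fit, seed = as.integer(seed))
}

#' Predict ages with a trained clock
#'
#' @param clock A [TrainedClock-class].
#' @param data Cohort \code{data.frame} with the clock's CpG columns; KDR
#'   clocks of the \code{BA_EC} variant additionally require the \code{age}
#'   column (chronological age is an input of that estimator).
#' @return Numeric vector of predicted ages (years).
#' @export
predictAge <- function(clock, data) {
  stopifnot(is(clock, "TrainedClock"))
  pd <- applyPreprocessor(clock@preprocessor, data)
  X <- as.matrix(pd[clock@cpgSubset])
  switch(clock@family,
    enr = .predictEnr(clock@fit, X),
    gbr = .predictGbr(clock@fit, X),
    svml = ,
    svmr = .predictSvm(clock@fit, X),
    kdr = kdrPredict(clock@fit$params, pd))
}

#' Prediction-accuracy metrics of a clock
#'
#' Computes Pearson's r, the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (negative out of sample is possible),
#' mean absolute error and root mean square error between predicted and
#' chronological ages. r is reported as \code{NA} (flagged) when either
#' vector has zero variance, as happens for constant predictions or a
#' zero-age-variance cohort.
#'
#' @param predicted,age Numeric vectors (years).
#' @return Named list with \code{r}, \code{R2}, \code{MAE}, \code{RMSE}.
#' @export
clockMetrics <- function(predicted, age) {
  stopifnot(length(predicted) == length(age), length(age) >= 1L)
  ssTot <- sum((age - mean(age))^2)
  r <- if (sd(predicted) == 0 || sd(age) == 0) NA_real_ else cor(predicted, age)
  list(r = r,
       R2 = if (ssTot == 0) NA_real_ else 1 - sum((age - predicted)^2) / ssTot,
       MAE = mean(abs(predicted - age)),
       RMSE = sqrt(mean((predicted - age)^2)))
}

#' Evaluate a clock on a cohort
#'
#' @param clock A [TrainedClock-class].
#' @param data Cohort with \code{age} and the clock's CpG columns.
#' @return Named list with \code{r}, \code{R2}, \code{MAE}, \code{RMSE}.
#' @export
evaluateClock <- function(clock, data) {
  if (nrow(data) < 1L) stop("empty evaluation data")
  clockMetrics(predictAge(clock, data), data$age)
}

#' Epigenetic age acceleration
#'
#' Absolute acceleration is predicted minus chronological age. Relative
#' acceleration is the residual of predicted age regressed on chronological
#' age within \code{data}, which removes the regression-to-the-mean slope
#' bias shared by most clock families and is therefore usually preferred for
#' group comparisons (KDR's age-anchored variant being the main exception,
#' as it does not regress to the mean).
#'
#' @param clock A [TrainedClock-class].
#' @param data Cohort with \code{age} and the clock's CpG columns.
#' @param mode \code{"absolute"} or \code{"relative"}.
#' @return Numeric vector of per-sample accelerations (years); relative
#'   accelerations sum to zero.
#' @export
ageAcceleration <- function(clock, data, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  pred <- predictAge(clock, data)
  if (mode == "absolute") return(pred - data$age)
  if (nrow(data) < 3L)
    stop("relative acceleration needs at least 3 samples")
  as.numeric(residuals(lm(pred ~ data$age)))
}

#' Exhaustive CpG-subset search
#'
#' Fits every CpG combination of the requested sizes (all 57 combinations of
#' 2-6 CpGs from the six-CpG panel by default) for each requested family,
#' evaluating each on the training and test cohorts. Per-fit failures are
#' returned as flagged rows, not errors. Rows are ranked by test MAE, with
#' ties broken by fewer CpGs then lexicographic subset name.
#'
#' @param families Character vector of [clockFamilies()] codes.
#' @param train,test Cohort \code{data.frame}s.
#' @param transform Transform mode passed to [fitClock()].
#' @param sizes Subset sizes to enumerate (default 2:6).
#' @param cpgs CpG pool (default: the panel).
#' @param seed Fit seed.
#' @return \code{data.frame} with one row per (family, subset): family,
#'   subset, size, train/test metrics, and an \code{error} column.
#' @export
subsetSearch <- function(families, train, test, transform = TRUE,
                         sizes = 2:6, cpgs = cpgPanel(), seed = 1L) {
  stopifnot(all(families %in% clockFamilies()))
  combos <- unlist(lapply(sizes, function(k)
    utils::combn(sort(cpgs), k, simplify = FALSE)), recursive = FALSE)
  rows <- list()
  for (family in families) for (subset in combos) {
    row <- data.frame(family = family, subset = paste(subset, collapse = ","),
                      size = length(subset), train_r = NA_real_,
                      train_R2 = NA_real_, train_MAE = NA_real_,
                      train_RMSE = NA_real_, test_r = NA_real_,
                      test_R2 = NA_real_, test_MAE = NA_real_,
                      test_RMSE = NA_real_, error = NA_character_)
    res <- tryCatch({
      clock <- fitClock(family, train, cpgSubset = subset,
                        transform = transform, seed = seed)
      list(tr = evaluateClock(clock, train), te = evaluateClock(clock, test))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row[c("train_r", "train_R2", "train_MAE", "train_RMSE")] <- res$tr
      row[c("test_r", "test_R2", "test_MAE", "test_RMSE")] <- res$te
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$test_MAE, out$size, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "TrainedClock", function(object) {
  cat(sprintf("TrainedClock [%s] on %d CpG(s): %s (seed %d)\n",
              object@family, length(object@cpgSubset),
              paste(object@cpgSubset, collapse = ", "), object@seed))
})
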