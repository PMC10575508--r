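#' Construct a learner specification
#'
#' @param name learner identifier.
#' @param fitFun function(x, y, seed) returning a fitted object; `x` is a
#'   numeric matrix of covariate rows, `y` a 0/1 vector.
#' @param predictFun function(fit, x) returning scores in \[0, 1\].
#' @param hyper optional list of hyperparameters, recorded on the spec.
#' @return a [LearnerSpec-class].
#' @export
learnerSpec <- function(name, fitFun, predictFun, hyper = list()) {
  new("LearnerSpec", name = name, fitFun = fitFun,
      predictFun = predictFun, hyper = hyper)
}

setMethod("show", "LearnerSpec", function(object) {
  cat(sprintf("LearnerSpec \"%s\"\n", object@name))
})

.clamp01 <- function(p) pmin(1, pmax(0, p))

#' Default learner set for the suitability ensemble
#'
#' Four presence/pseudo-absence scorers spanning the algorithm families
#' commonly combined in distribution-model ensembles:
#' `rlr` -- ridge-regularized logistic regression (a maximum-entropy-like
#' linear scorer; glmnet); `brt` -- boosted regression trees (xgboost);
#' `gam` -- additive logistic model on natural-spline bases (splines +
#' glm); `rf` -- random forest (ranger, probability trees). All return
#' probabilities in \[0, 1\] and are deterministic given the seed passed
#' at fit time.
#'
#' @param rfTrees number of forest trees (default 100).
#' @param brtRounds boosting rounds (default 40).
#' @param gamDf spline degrees of freedom per covariate (default 3).
#' @return list of four [LearnerSpec-class] objects.
#' @export
defaultLearners <- function(rfTrees = 100, brtRounds = 40, gamDf = 3) {
  list(
    learnerSpec("rlr",
      fitFun = function(x, y, seed) {
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = 0.01, standardize = TRUE)
      },
      predictFun = function(fit, x) {
        .clamp01(as.numeric(predict(fit, newx = x, type = "response")))
      },
      hyper = list(alpha = 0, lambda = 0.01)),
    learnerSpec("brt",
      fitFun = function(x, y, seed) {
        xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                         nrounds = brtRounds, max_depth = 2,
                         learning_rate = 0.3, nthreads = 1,
                         seed = seed %% 2147483647, verbosity = 0)
      },
      predictFun = function(fit, x) {
        .clamp01(as.numeric(predict(fit, x, type = "response")))
      },
      hyper = list(nrounds = brtRounds, max_depth = 2,
                   learning_rate = 0.3)),
    learnerSpec("gam",
      fitFun = function(x, y, seed) {
        basis <- lapply(seq_len(ncol(x)), function(j) {
          xj <- x[, j]
          if (length(unique(xj)) < gamDf + 2) cbind(xj)
          else splines::ns(xj, df = gamDf)
        })
        X <- do.call(cbind, basis)
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, X), y, family = binomial()))
        list(coef = fit$coefficients, basis = basis)
      },
      predictFun = function(fit, x) {
        X <- do.call(cbind, lapply(seq_along(fit$basis), function(j) {
          b <- fit$basis[[j]]
          if (is.null(attr(b, "knots")) && ncol(b) == 1L) cbind(x[, j])
          else predict(b, x[, j])
        }))
        beta <- fit$coef
        beta[is.na(beta)] <- 0
        eta <- as.numeric(cbind(1, X) %*% beta)
        .clamp01(1 / (1 + exp(-eta)))
      },
      hyper = list(df = gamDf)),
    learnerSpec("rf",
      fitFun = function(x, y, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       num.trees = rfTrees, probability = TRUE,
                       seed = seed, num.threads = 1,
                       min.node.size = 10)
      },
      predictFun = function(fit, x) {
        .clamp01(predict(fit, data = x, num.threads = 1)$predictions[, "1"])
      },
      hyper = list(num.trees = rfTrees, min.node.size = 10))
  )
}
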