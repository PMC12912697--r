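#' Specification of a boosted Poisson rate learner
#'
#' The learner contract is: target = observed rate `deaths/exposure`,
#' observation weights = exposure, Poisson objective, optional per-record
#' initial log-rate score. This weighted-rate device is mathematically
#' equivalent to a Poisson count model with `log(exposure)` offset, which is
#' what makes boosted trees usable for mortality rate modelling.
#'
#' Leaf-size thresholds guard against leaves supported by too little
#' experience: both are translated into the backend's minimum hessian per
#' leaf, which for the Poisson objective equals the expected deaths in the
#' leaf — the effective constraint is
#' `max(min_deaths_per_leaf, min_exposure_per_leaf * portfolio rate)`.
#'
#' @param n_trees number of boosting rounds `K` (>= 0; `K = 0` gives the
#'   intercept-only model).
#' @param learning_rate shrinkage per round (> 0).
#' @param max_leaves maximum leaves per tree (leaf-wise growth).
#' @param min_exposure_per_leaf minimum life-years of exposure per leaf.
#' @param min_deaths_per_leaf minimum (expected) deaths per leaf.
#' @param reg_lambda,reg_alpha L2/L1 regularisation of leaf values.
#' @param subsample,colsample row/column subsampling per tree.
#' @param max_delta_step cap on per-leaf steps (stabilises Poisson boosting).
#' @param seed integer seed; training is deterministic given it (the backend
#'   runs single-threaded).
#' @return an object of class `learner_spec`.
#' @export
learner_spec <- function(n_trees = 200, learning_rate = 0.1, max_leaves = 31,
                         min_exposure_per_leaf = 100, min_deaths_per_leaf = 5,
                         reg_lambda = 1, reg_alpha = 0,
                         subsample = 1, colsample = 1,
                         max_delta_step = 0.7, seed = 1) {
  stopifnot(n_trees >= 0, learning_rate > 0, max_leaves >= 2,
            min_exposure_per_leaf >= 0, min_deaths_per_leaf >= 0,
            reg_lambda >= 0, reg_alpha >= 0,
            subsample > 0, subsample <= 1, colsample > 0, colsample <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate, max_leaves = as.integer(max_leaves),
                 min_exposure_per_leaf = min_exposure_per_leaf,
                 min_deaths_per_leaf = min_deaths_per_leaf,
                 reg_lambda = reg_lambda, reg_alpha = reg_alpha,
                 subsample = subsample, colsample = colsample,
                 max_delta_step = max_delta_step, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Fit a boosted-tree Poisson rate model
#'
#' Trains a gradient-boosted tree ensemble with Poisson objective on the
#' observed rates `D/E` with observation weights `E` and per-record initial
#' score `init_log_rate`. Without an initial score, the base score `b0` is
#' the log of the portfolio rate `log(sum(D)/sum(E))`, so the zero-tree model
#' is exactly the intercept-only Poisson MLE. With an initial score, `b0` is
#' constrained to 0 and the ensemble models the residual factor around
#' `exp(init_log_rate)`.
#'
#' @param spec a [learner_spec()].
#' @param X numeric feature matrix (already encoded), one row per record.
#' @param D non-negative integer death counts.
#' @param E positive exposures in life-years.
#' @param init_log_rate optional per-record initial log-rate score.
#' @return an object of class `rate_learner`.
#' @export
fit_rate <- function(spec, X, D, E, init_log_rate = NULL) {
  stopifnot(inherits(spec, "learner_spec"), is.matrix(X))
  n <- nrow(X)
  if (length(D) != n || length(E) != n) stop("X, D, E must be aligned")
  if (any(!is.finite(E)) || any(E <= 0)) stop("exposures must be positive")
  if (any(!is.finite(D)) || any(D < 0)) stop("negative or non-finite deaths")
  if (!is.null(init_log_rate) && length(init_log_rate) != n) {
    stop("init_log_rate must align with the records")
  }
  rate0 <- sum(D) / sum(E)
  b0 <- if (is.null(init_log_rate)) log(max(rate0, 1e-12)) else 0
  k <- spec$n_trees
  if (sum(D) == 0 && k > 0) {
    warning("all death counts are zero; returning the floored ",
            "intercept-only learner")
    k <- 0L
  }
  booster <- NULL
  if (k > 0) {
    margin <- b0 + (init_log_rate %||% 0)
    if (length(margin) == 1L) margin <- rep(margin, n)
    min_cw <- max(spec$min_deaths_per_leaf,
                  spec$min_exposure_per_leaf * rate0)
    dtrain <- xgboost::xgb.DMatrix(X, label = D / E, weight = E,
                                   base_margin = margin, nthread = 1)
    params <- list(objective = "count:poisson",
                   eta = spec$learning_rate,
                   max_depth = 0, grow_policy = "lossguide",
                   max_leaves = spec$max_leaves,
                   tree_method = "hist",
                   min_child_weight = min_cw,
                   lambda = spec$reg_lambda, alpha = spec$reg_alpha,
                   subsample = spec$subsample,
                   colsample_bytree = spec$colsample,
                   max_delta_step = spec$max_delta_step,
                   nthread = 1, seed = spec$seed)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = k, verbose = 0)
  }
  structure(list(booster = booster, b0 = b0, features = colnames(X),
                 spec = spec, rate0 = rate0, n_trees = k),
            class = "rate_learner")
}

# raw log-rate score: b0 + init + tree ensemble contribution
score_rate <- function(model, X, init_log_rate = NULL) {
  stopifnot(inherits(model, "rate_learner"), is.matrix(X))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss)) {
    stop("feature column(s) missing from X: ", paste(miss, collapse = ", "))
  }
  X <- X[, model$features, drop = FALSE]
  n <- nrow(X)
  s <- rep(model$b0, n) + (init_log_rate %||% 0)
  if (!is.null(model$booster)) {
    # explicit zero base_margin: the stored ensemble contribution only
    dm <- xgboost::xgb.DMatrix(X, base_margin = rep(0, n), nthread = 1)
    s <- s + stats::predict(model$booster, dm, outputmargin = TRUE)
  }
  s
}

#' Predict mortality rates from a fitted rate learner
#'
#' @param model a [fit_rate()] result.
#' @param X numeric feature matrix with the model's feature columns.
#' @param init_log_rate optional per-record initial score, as used at fit
#'   time (0 if absent).
#' @return per-record predicted rates `exp(b0 + init + ensemble score)`,
#'   strictly positive (floored at 1e-12).
#' @export
predict_rate <- function(model, X, init_log_rate = NULL) {
  pmax(exp(score_rate(model, X, init_log_rate)), 1e-12)
}

#' @export
predict.rate_learner <- function(object, newdata,
                                 type = c("rate", "link"),
                                 init_log_rate = NULL, ...) {
  type <- match.arg(type)
  s <- score_rate(object, newdata, init_log_rate)
  if (type == "link") s else pmax(exp(s), 1e-12)
}

#' @export
print.rate_learner <- function(x, ...) {
  cat("Boosted Poisson rate learner:", x$n_trees, "trees,",
      length(x$features), "features, b0 =", signif(x$b0, 6), "\n")
  invisible(x)
}

#' Poisson log-likelihood of predicted death counts
#'
#' `sum(D * log(D_hat) - D_hat)`, the Poisson log-likelihood up to the
#' data-only `log(D!)` term; larger is better.
#'
#' @param D observed death counts.
#' @param D_hat predicted death counts, strictly positive.
#' @return a single number.
#' @export
poisson_loglik <- function(D, D_hat) {
  if (length(D) != length(D_hat)) stop("D and D_hat must be aligned")
  if (any(!is.finite(D_hat)) || any(D_hat <= 0)) {
    stop("D_hat must be strictly positive (log undefined otherwise)")
  }
  sum(D * log(D_hat) - D_hat)
}

#' Root-mean-square error of predicted death counts
#'
#' `sqrt(mean((D_hat - D)^2))` over a country's records.
#'
#' @inheritParams poisson_loglik
#' @return a single non-negative number.
#' @export
rmse <- function(D, D_hat) {
  if (length(D) == 0L) stop("rmse of an empty vector is undefined")
  if (length(D) != length(D_hat)) stop("D and D_hat must be aligned")
  sqrt(mean((D_hat - D)^2))
}

#' Actual-over-expected ratios by group
#'
#' The actuarial calibration diagnostic: per group, the ratio of total actual
#' to total expected deaths. A group with zero expected deaths gets `NA`
#' (undefined), never infinity.
#'
#' @inheritParams poisson_loglik
#' @param groups per-record group labels (e.g. age band, gender).
#' @return a list with `by_group` (named vector of ratios) and `overall`.
#' @export
ae_by_group <- function(D, D_hat, groups) {
  stopifnot(length(D) == length(D_hat), length(D) == length(groups))
  if (length(D) == 0L) stop("groups must be non-empty")
  a <- tapply(D, groups, sum)
  e <- tapply(D_hat, groups, sum)
  r <- ifelse(e > 0, a / e, NA_real_)
  total_e <- sum(D_hat)
  list(by_group = r,
       overall = if (total_e > 0) sum(D) / total_e else NA_real_)
}
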