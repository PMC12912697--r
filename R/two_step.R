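#' Fit the global stage of the two-step mortality model
#'
#' Step 1 pools the training data of all countries and fits a boosted
#' Poisson rate learner on the global features only, so it captures the
#' patterns (age, gender, calendar year, ...) that are comparable across
#' countries. Categorical features are target-encoded out-of-fold
#' (exposure-weighted rate target); the fold assignment groups records by
#' country-year so encoding and tuning share one fold structure.
#'
#' @param train training portfolio data frame (all countries).
#' @param schema a [feature_schema()].
#' @param spec a [learner_spec()].
#' @param k number of encoding folds (default 5).
#' @return an object of class `global_model`.
#' @export
fit_global <- function(train, schema, spec = learner_spec(), k = 5) {
  validate_portfolio(train, schema)
  features <- feature_names(schema, scope = "global")
  if (length(features) == 0L) stop("schema has no global features")
  encoders <- fit_feature_encoders(train, schema, features, k,
                                   seed = spec$seed)
  # final fits use full-training-mean encodings so fit-time and predict-time
  # features agree (exact Poisson balance); the out-of-fold mode is used
  # where held-out evaluation demands leakage-safety (tuning)
  X <- build_matrix(train, schema, features, encoders, mode = "apply")
  learner <- fit_rate(spec, X, train$deaths, train$exposure)
  structure(list(learner = learner, encoders = encoders,
                 features = features, k = k, spec = spec),
            class = "global_model")
}

# global rate q(x_global) on any table (apply-mode encoding)
predict_global <- function(gm, table, schema) {
  X <- build_matrix(table, schema, gm$features, gm$encoders, mode = "apply")
  predict_rate(gm$learner, X)
}

#' Fit a country's local stage on the global model's residual scale
#'
#' Step 2 takes one country's training data and continues boosting from the
#' global model: each record's initial score is `log q(x_global)`, the base
#' score is fixed at 0, and the ensemble is trained on the same
#' exposure-weighted rate target. The fitted ensemble therefore models the
#' country's residual factor `h_j`; with zero trees, `h_j == 1` exactly and
#' the combined prediction equals the global one. Features are the global
#' features plus the country's available local features; a local feature
#' that is entirely missing for the country is dropped before fitting.
#'
#' @param train_j training records of a single country.
#' @param global_model a fitted [fit_global()] object.
#' @param schema a [feature_schema()].
#' @param spec a [learner_spec()].
#' @param k number of encoding folds.
#' @param refit_encoders if `TRUE` (default) all encoders are refitted on
#'   the country's training data; if `FALSE`, global-stage encoders are
#'   reused for global features and only local-feature encoders are fitted.
#' @return an object of class `local_model`.
#' @export
fit_local <- function(train_j, global_model, schema, spec = learner_spec(),
                      k = 5, refit_encoders = TRUE) {
  validate_portfolio(train_j, schema)
  country <- unique(as.character(train_j$country))
  if (length(country) != 1L) {
    stop("fit_local expects records of a single country, got: ",
         paste(country, collapse = ", "))
  }
  if (sum(train_j$deaths) == 0) {
    warning("country '", country, "' has zero deaths in training; ",
            "the local factor will default towards 1")
  }
  local_feats <- feature_names(schema, scope = "local")
  keep <- vapply(local_feats, function(f) {
    feature_available(schema, f, country) && !all(is.na(train_j[[f]]))
  }, logical(1))
  features <- c(global_model$features, local_feats[keep])

  folds <- make_folds(fold_group_labels(train_j), k, spec$seed)
  if (refit_encoders) {
    encoders <- fit_feature_encoders(train_j, schema, features, k,
                                     seed = spec$seed, folds = folds)
  } else {
    encoders <- fit_feature_encoders(train_j, schema, local_feats[keep], k,
                                     seed = spec$seed, folds = folds)
    encoders <- c(global_model$encoders, encoders)
  }
  X <- build_matrix(train_j, schema, features, encoders, mode = "apply")
  init <- log(predict_global(global_model, train_j, schema))
  learner <- fit_rate(spec, X, train_j$deaths, train_j$exposure,
                      init_log_rate = init)
  structure(list(learner = learner, encoders = encoders,
                 features = features, country = country, k = k, spec = spec),
            class = "local_model")
}

# residual factor h_j(x_all) on any table of that country
predict_local_factor <- function(lm_j, table, schema) {
  X <- build_matrix(table, schema, lm_j$features, lm_j$encoders,
                    mode = "apply")
  # b0 is 0 and no init is added, so this is exp(ensemble score) = h_j
  predict_rate(lm_j$learner, X)
}

#' Fit the two-step hierarchical mortality model
#'
#' Fits the global model on the pooled training data, then one local model
#' per country present. The fitted object predicts expected deaths as the
#' product `q(x_global) * h_j(x_all) * E`: a global rate, a country-specific
#' residual factor, and exposure.
#'
#' @param train training portfolio data frame spanning one or more countries.
#' @param schema a [feature_schema()].
#' @param global_spec a [learner_spec()] for the global stage.
#' @param local_specs a single [learner_spec()] shared by all local models,
#'   or a named list (country id -> spec) for per-country settings (e.g.
#'   stronger regularisation for data-scarce countries). Defaults to
#'   `global_spec`.
#' @param k number of encoding folds.
#' @param refit_encoders passed to [fit_local()].
#' @return an object of class `two_step` with components `global` and
#'   `locals` (named list of local models).
#' @seealso [predict.two_step()], [onboard_country()]
#' @export
fit_two_step <- function(train, schema, global_spec = learner_spec(),
                         local_specs = NULL, k = 5, refit_encoders = TRUE) {
  gm <- fit_global(train, schema, global_spec, k = k)
  countries <- unique(as.character(train$country))
  get_spec <- function(cty) {
    if (is.null(local_specs)) return(global_spec)
    if (inherits(local_specs, "learner_spec")) return(local_specs)
    local_specs[[cty]] %||% global_spec
  }
  locals <- lapply(countries, function(cty) {
    fit_local(train[train$country == cty, , drop = FALSE], gm, schema,
              spec = get_spec(cty), k = k, refit_encoders = refit_encoders)
  })
  names(locals) <- countries
  structure(list(global = gm, locals = locals, schema = schema,
                 global_spec = global_spec, local_specs = local_specs, k = k),
            class = "two_step")
}

#' Predict from a two-step model
#'
#' @param object a fitted [fit_two_step()] model.
#' @param newdata a portfolio data frame; every country present must have a
#'   local model (otherwise an error names the country -- onboard it first
#'   with [onboard_country()]).
#' @param type `"deaths"` (default) returns predicted death counts
#'   `q * h_j * E`; `"rate"` returns the rate `q * h_j`; `"scores"` returns
#'   a data frame with the additive log decomposition (`log_global`,
#'   `log_local`).
#' @param ... unused.
#' @return a numeric vector, or a data frame for `type = "scores"`.
#' @export
predict.two_step <- function(object, newdata,
                             type = c("deaths", "rate", "scores"), ...) {
  type <- match.arg(type)
  countries <- unique(as.character(newdata$country))
  unknown <- setdiff(countries, names(object$locals))
  if (length(unknown)) {
    stop("no local model for country/countries: ",
         paste(unknown, collapse = ", "),
         " -- onboard them first with onboard_country()")
  }
  n <- nrow(newdata)
  lq <- log(predict_global(object$global, newdata, object$schema))
  lh <- numeric(n)
  for (cty in countries) {
    rows <- newdata$country == cty
    lh[rows] <- log(predict_local_factor(
      object$locals[[cty]], newdata[rows, , drop = FALSE], object$schema))
  }
  switch(type,
         scores = data.frame(log_global = lq, log_local = lh),
         rate = exp(lq + lh),
         deaths = exp(lq + lh) * newdata$exposure)
}

#' Onboard a new country into a fitted two-step model
#'
#' Retains the existing global model untouched and fits one additional local
#' model on the new country's training data, so predictions for all
#' previously fitted countries are bit-identical to before.
#'
#' @param model a fitted [fit_two_step()] model.
#' @param train_new training records of one country absent from `model`.
#' @param spec a [learner_spec()] for the new local model.
#' @param k number of encoding folds.
#' @return the extended `two_step` model.
#' @export
onboard_country <- function(model, train_new, spec = learner_spec(), k = 5) {
  stopifnot(inherits(model, "two_step"))
  cty <- unique(as.character(train_new$country))
  if (length(cty) != 1L) stop("train_new must hold a single country")
  if (cty %in% names(model$locals)) {
    stop("country '", cty, "' is already part of the model")
  }
  model$locals[[cty]] <- fit_local(train_new, model$global, model$schema,
                                   spec = spec, k = k)
  model
}

#' @export
print.two_step <- function(x, ...) {
  cat("Two-step hierarchical mortality model\n")
  cat("  global stage :", x$global$learner$n_trees, "trees on",
      length(x$global$features), "global features\n")
  cat("  local stage  :", length(x$locals), "country model(s):",
      paste(names(x$locals), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.two_step <- function(object, ...) {
  loc <- data.frame(
    country = names(object$locals),
    n_features = vapply(object$locals, function(l) length(l$features), 0L),
    n_trees = vapply(object$locals, function(l) l$learner$n_trees, 0L),
    row.names = NULL)
  out <- list(n_countries = length(object$locals),
              global_features = object$global$features, locals = loc)
  class(out) <- "summary.two_step"
  out
}

#' @export
print.summary.two_step <- function(x, ...) {
  cat("Two-step model over", x$n_countries, "countries\n")
  cat("Global features:", paste(x$global_features, collapse = ", "), "\n")
  print(x$locals)
  invisible(x)
}
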