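#' Configuration of bootstrapped decision-tree multiple imputation
#'
#' @param n_bootstrap number of bootstrap resamples (and hence completed
#'   tables / pooled models), default 4.
#' @param n_iterations sequential refinement passes over the variables with
#'   missing values, default 2.
#' @param mincut,minsize,mindev controls of the per-variable imputation
#'   trees (see [tree::tree.control()]); `mindev` is the minimum deviance
#'   reduction for a split relative to the root.
#' @param seed integer seed.
#' @return an object of class `mice_config`.
#' @export
mice_config <- function(n_bootstrap = 4, n_iterations = 2,
                        mincut = 5, minsize = 10, mindev = 0.001, seed = 1) {
  stopifnot(n_bootstrap >= 1, n_iterations >= 1, mincut >= 1,
            minsize >= 2, mindev >= 0)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_iterations = as.integer(n_iterations),
                 mincut = as.integer(mincut), minsize = as.integer(minsize),
                 mindev = mindev, seed = as.integer(seed)),
            class = "mice_config")
}

# Build the predictor frame for the imputation tree of variable `v`:
# all other schema features (current working values) plus country.
# Low-cardinality categorical predictors become factors with fixed level
# sets; higher-cardinality ones become ordered integer codes (full subset
# search over many-level factors is exponential in the backend, and sorted
# codes still cluster country-qualified categories contiguously).
mice_predictor_frame <- function(W, schema, v, level_sets) {
  feats <- setdiff(feature_names(schema), v)
  out <- list(country = factor(as.character(W$country),
                               levels = level_sets$country))
  for (f in feats) {
    if (feature_kind(schema, f) == "categorical") {
      lv <- level_sets[[f]]
      out[[f]] <- if (length(lv) > 10L) {
        as.integer(factor(as.character(W[[f]]), levels = lv))
      } else {
        factor(as.character(W[[f]]), levels = lv)
      }
    } else {
      out[[f]] <- as.numeric(W[[f]])
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

# Fit the imputation tree for variable `v` on the bootstrap rows where the
# ORIGINAL value is observed, then draw imputations for the missing cells of
# `frames` (a list of predictor frames) uniformly from the observed values
# in the leaf the record falls into. Returns a list of drawn value vectors.
mice_draw <- function(resp, train_frame, pred_frames, categorical, control) {
  fit <- NULL
  y <- if (categorical) factor(resp) else as.numeric(resp)
  if (length(resp) >= control$minsize &&
      (!categorical || nlevels(y) >= 2) &&
      (categorical || stats::var(as.numeric(resp)) > 0)) {
    dat <- cbind(data.frame(.y = y), train_frame)
    fit <- tryCatch(
      tree::tree(.y ~ ., data = dat,
                 control = tree::tree.control(
                   nobs = nrow(dat), mincut = control$mincut,
                   minsize = control$minsize, mindev = control$mindev)),
      error = function(e) NULL)
    if (!is.null(fit) && !inherits(fit, "tree")) fit <- NULL
  }
  draw_for <- function(frame) {
    m <- nrow(frame)
    if (m == 0L) return(resp[0])
    if (is.null(fit) || sum(fit$frame$var == "<leaf>") < 2L) {
      # root-only model: draw from all observed values
      return(resp[sample.int(length(resp), m, replace = TRUE)])
    }
    wh <- tryCatch(stats::predict(fit, frame, type = "where"),
                   error = function(e) NULL)
    if (is.null(wh)) {
      return(resp[sample.int(length(resp), m, replace = TRUE)])
    }
    out <- resp[rep(1L, m)]
    for (leaf in unique(wh)) {
      pool <- resp[fit$where == leaf]
      if (length(pool) == 0L) pool <- resp
      rows <- which(wh == leaf)
      out[rows] <- pool[sample.int(length(pool), length(rows),
                                   replace = TRUE)]
    }
    out
  }
  lapply(pred_frames, draw_for)
}

# Shared engine: completes `table` (and optionally `extra`, e.g. a test
# split, using the same fitted trees -- no refitting on the extra table)
# once per bootstrap sample.
mice_engine <- function(table, schema, config, extra = NULL) {
  stopifnot(inherits(schema, "feature_schema"),
            inherits(config, "mice_config"))
  if (nrow(table) < 1L) stop("table must have at least one record")
  feats <- feature_names(schema)
  miss_any <- vapply(feats, function(f) anyNA(table[[f]]), logical(1))
  # variables missing everywhere cannot be imputed from data: sentinel-fill
  all_missing <- feats[vapply(feats, function(f) {
    all(is.na(table[[f]]))
  }, logical(1))]
  visit <- setdiff(feats[miss_any], all_missing) # schema order, fixed
  if (!any(miss_any) && (is.null(extra) ||
                         !anyNA(extra[, feats, drop = FALSE]))) {
    tables <- replicate(config$n_bootstrap, table, simplify = FALSE)
    extras <- if (is.null(extra)) NULL
              else replicate(config$n_bootstrap, extra, simplify = FALSE)
    return(list(tables = tables, extras = extras,
                sentinel_filled = character(0)))
  }
  n <- nrow(table)
  # level sets fixed up front so fit and predict frames always agree
  level_sets <- list(country = sort(unique(c(
    as.character(table$country),
    if (!is.null(extra)) as.character(extra$country)))))
  for (f in feats) {
    if (feature_kind(schema, f) == "categorical") {
      level_sets[[f]] <- sort(unique(c("Missing",
                                       as.character(table[[f]]),
                                       if (!is.null(extra))
                                         as.character(extra[[f]]))))
      level_sets[[f]] <- level_sets[[f]][!is.na(level_sets[[f]])]
    }
  }
  tables <- vector("list", config$n_bootstrap)
  extras <- if (is.null(extra)) NULL else vector("list", config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    with_seed(derive_seed(config$seed, paste0("bootstrap", b)), {
      idx <- sample.int(n, n, replace = TRUE)
      # working copies start sentinel-filled; cells are replaced as the
      # variables are visited
      W <- impute_sentinels(table, schema)
      Wt <- if (is.null(extra)) NULL else impute_sentinels(extra, schema)
      for (iter in seq_len(config$n_iterations)) {
        for (v in visit) {
          obs_b <- which(!is.na(table[[v]][idx]))
          resp <- table[[v]][idx][obs_b]
          if (length(resp) == 0L) next
          train_frame <- mice_predictor_frame(
            W[idx[obs_b], , drop = FALSE], schema, v, level_sets)
          miss_o <- which(is.na(table[[v]]))
          miss_t <- if (is.null(extra)) integer(0)
                    else which(is.na(extra[[v]]))
          frames <- list(
            mice_predictor_frame(W[miss_o, , drop = FALSE], schema, v,
                                 level_sets),
            if (is.null(extra)) NULL
            else mice_predictor_frame(Wt[miss_t, , drop = FALSE], schema,
                                      v, level_sets))
          drawn <- mice_draw(resp, train_frame,
                             frames[!vapply(frames, is.null, logical(1))],
                             feature_kind(schema, v) == "categorical",
                             config)
          W[[v]][miss_o] <- drawn[[1L]]
          if (!is.null(extra) && length(miss_t)) {
            Wt[[v]][miss_t] <- drawn[[length(drawn)]]
          }
        }
      }
      tables[[b]] <- W
      if (!is.null(extra)) extras[[b]] <- Wt
    })
  }
  list(tables = tables, extras = extras, sentinel_filled = all_missing)
}

#' Multiple imputation with bootstrapped decision trees
#'
#' For each of `n_bootstrap` bootstrap resamples of the table, iterates
#' `n_iterations` times over the variables with missing values (in schema
#' order). For each variable a classification tree (categorical) or
#' regression tree (metric) is fitted by recursive partitioning on the
#' bootstrap rows where the variable is observed, predicting it from the
#' other variables' current working values; every missing cell is then sent
#' down the tree and filled with a value drawn uniformly at random from the
#' observed values in its leaf, which induces between-imputation variation
#' beyond the leaf assignment itself. Cells start sentinel-filled and are
#' replaced as the variables are visited. A variable that is missing in
#' every record cannot be imputed from data: it stays sentinel-filled and is
#' flagged.
#'
#' Only originally-missing cells are ever changed: observed cells are
#' bit-identical across all returned tables.
#'
#' @param table a portfolio data frame.
#' @param schema a [feature_schema()].
#' @param config a [mice_config()].
#' @return a list of `n_bootstrap` completed copies of the original table,
#'   with attribute `"sentinel_filled"` naming any variables that had to be
#'   sentinel-filled.
#' @export
mice_impute <- function(table, schema, config = mice_config()) {
  res <- mice_engine(table, schema, config)
  structure(res$tables, sentinel_filled = res$sentinel_filled)
}

#' One-step pooled model with single-value (sentinel) imputation
#'
#' Pools all countries into one table, sentinel-imputes every missing cell,
#' and fits a single boosted Poisson rate learner on the global plus all
#' local features. Features entirely missing within a country are retained:
#' their cells simply carry sentinels for that country's records.
#'
#' @param train,test portfolio data frames.
#' @param schema a [feature_schema()].
#' @param spec a [learner_spec()].
#' @param k number of encoding folds.
#' @return a list with per-record predicted deaths `train` and `test`, and
#'   the fitted `model`.
#' @export
one_step_single_value <- function(train, test, schema,
                                  spec = learner_spec(), k = 5) {
  features <- feature_names(schema)
  encoders <- fit_feature_encoders(train, schema, features, k,
                                   seed = spec$seed)
  X_tr <- build_matrix(train, schema, features, encoders, mode = "apply")
  X_te <- build_matrix(test, schema, features, encoders, mode = "apply")
  model <- fit_rate(spec, X_tr, train$deaths, train$exposure)
  list(train = predict_rate(model, X_tr) * train$exposure,
       test = predict_rate(model, X_te) * test$exposure,
       model = model, encoders = encoders)
}

#' One-step pooled model with bootstrapped multiple imputation
#'
#' Completes the pooled training table `n_bootstrap` times with
#' [mice_impute()]'s engine; the imputation trees fitted on each bootstrap
#' training sample also complete the test table (no refitting on test, so no
#' leakage). One pooled learner is fitted per completed training table and
#' the per-record predicted death counts are pooled by arithmetic averaging.
#'
#' @inheritParams one_step_single_value
#' @param config a [mice_config()].
#' @return a list with pooled per-record predicted deaths `train` and
#'   `test`, and `n_models` (the number of fitted learners, equal to
#'   `n_bootstrap`).
#' @export
one_step_mice <- function(train, test, schema, spec = learner_spec(),
                          config = mice_config(), k = 5) {
  res <- mice_engine(train, schema, config, extra = test)
  features <- feature_names(schema)
  pred_tr <- matrix(0, nrow(train), config$n_bootstrap)
  pred_te <- matrix(0, nrow(test), config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    tr_b <- res$tables[[b]]
    te_b <- res$extras[[b]]
    encoders <- fit_feature_encoders(tr_b, schema, features, k,
                                     seed = derive_seed(spec$seed,
                                                        paste0("mice", b)))
    X_tr <- build_matrix(tr_b, schema, features, encoders, mode = "apply")
    model <- fit_rate(spec, X_tr, tr_b$deaths, tr_b$exposure)
    X_te <- build_matrix(te_b, schema, features, encoders, mode = "apply")
    pred_tr[, b] <- predict_rate(model, X_tr) * tr_b$exposure
    pred_te[, b] <- predict_rate(model, X_te) * te_b$exposure
  }
  list(train = rowMeans(pred_tr), test = rowMeans(pred_te),
       n_models = config$n_bootstrap,
       sentinel_filled = res$sentinel_filled)
}
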