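#' Tune learner specifications by grouped cross-validation
#'
#' Builds k folds grouping records by country-year combination (no
#' combination straddles folds), then tunes the global spec by mean
#' out-of-fold Poisson log-likelihood over seeded random draws from the
#' search space. The global model is tuned first; its out-of-fold
#' predictions are then held fixed as initial scores while each country's
#' local spec is tuned the same way, so no information leaks between the
#' modelling stages. Ties keep the earlier candidate.
#'
#' @param train training portfolio data frame with `country` (and ideally
#'   `year`) columns.
#' @param schema a [feature_schema()].
#' @param search_space named list; each entry is a vector of candidate
#'   values for one [learner_spec()] argument (e.g. `list(learning_rate =
#'   c(0.05, 0.1), max_leaves = c(15, 31))`).
#' @param budget number of candidate specs evaluated (default 25). When the
#'   search space is an exhaustible grid smaller than the budget, the whole
#'   grid is enumerated.
#' @param base_spec the [learner_spec()] whose unsearched arguments are kept.
#' @param k number of folds (default 5; an error suggests fewer folds when
#'   there are fewer distinct country-year combinations).
#' @param seed integer seed driving candidate sampling.
#' @return a list with `global_spec`, `local_specs` (named list per
#'   country), and `trace` (a data frame of candidates and their scores).
#' @export
tune <- function(train, schema, search_space, budget = 25,
                 base_spec = learner_spec(), k = 5, seed = 1) {
  stopifnot(is.list(search_space), length(search_space) >= 1L)
  groups <- fold_group_labels(train)
  if (length(unique(groups)) < k) {
    stop("fewer than ", k, " distinct country-year combinations; ",
         "use fewer folds")
  }
  folds <- make_folds(groups, k, derive_seed(seed, "tune-folds"))

  grid_size <- prod(vapply(search_space, length, 0L))
  cands <- if (grid_size <= budget) {
    do.call(expand.grid,
            c(search_space, list(stringsAsFactors = FALSE,
                                 KEEP.OUT.ATTRS = FALSE)))
  } else {
    with_seed(derive_seed(seed, "tune-draw"), {
      as.data.frame(lapply(search_space, function(v) {
        v[sample.int(length(v), budget, replace = TRUE)]
      }), stringsAsFactors = FALSE)
    })
  }
  make_spec <- function(row) {
    do.call(learner_spec,
            utils::modifyList(unclass(base_spec), as.list(row)))
  }

  # --- stage 1: global spec ----------------------------------------------
  oof_global <- function(spec) {
    ll <- 0
    pred <- numeric(nrow(train))
    for (f in seq_len(k)) {
      tr <- train[folds != f, , drop = FALSE]
      ho <- train[folds == f, , drop = FALSE]
      gm <- fit_global(tr, schema, spec, k = k)
      q <- predict_global(gm, ho, schema)
      ll <- ll + poisson_loglik(ho$deaths, q * ho$exposure)
      pred[folds == f] <- q
    }
    list(ll = ll, pred = pred)
  }
  scores <- numeric(nrow(cands))
  best <- NULL; best_ll <- -Inf; best_pred <- NULL
  for (i in seq_len(nrow(cands))) {
    spec_i <- make_spec(cands[i, , drop = FALSE])
    res <- oof_global(spec_i)
    scores[i] <- res$ll
    if (res$ll > best_ll) { # strict: ties keep the earlier candidate
      best_ll <- res$ll; best <- spec_i; best_pred <- res$pred
    }
  }
  trace <- cbind(cands, oof_loglik_global = scores)

  # --- stage 2: local specs, with global OOF predictions held fixed ------
  init_all <- log(best_pred)
  local_specs <- list()
  for (cty in unique(as.character(train$country))) {
    rows <- which(train$country == cty)
    tr_j <- train[rows, , drop = FALSE]
    init_j <- init_all[rows]
    folds_j <- folds[rows]
    best_l <- NULL; best_ll_l <- -Inf
    for (i in seq_len(nrow(cands))) {
      spec_i <- make_spec(cands[i, , drop = FALSE])
      ll <- 0
      ok <- TRUE
      for (f in unique(folds_j)) {
        tr_f <- tr_j[folds_j != f, , drop = FALSE]
        ho_f <- tr_j[folds_j == f, , drop = FALSE]
        if (nrow(tr_f) == 0L || nrow(ho_f) == 0L) next
        feats <- local_tune_features(tr_f, schema)
        encs <- fit_feature_encoders(tr_f, schema, feats,
                                     k = min(k, max(2L, nrow(tr_f))),
                                     seed = spec_i$seed)
        X_tr <- build_matrix(tr_f, schema, feats, encs, mode = "apply")
        m <- tryCatch(
          fit_rate(spec_i, X_tr, tr_f$deaths, tr_f$exposure,
                   init_log_rate = init_j[folds_j != f]),
          warning = function(w) suppressWarnings(
            fit_rate(spec_i, X_tr, tr_f$deaths, tr_f$exposure,
                     init_log_rate = init_j[folds_j != f])),
          error = function(e) NULL)
        if (is.null(m)) { ok <- FALSE; break }
        X_ho <- build_matrix(ho_f, schema, feats, encs, mode = "apply")
        h <- predict_rate(m, X_ho, init_log_rate = init_j[folds_j == f])
        ll <- ll + poisson_loglik(ho_f$deaths, h * ho_f$exposure)
      }
      if (ok && ll > best_ll_l) { best_ll_l <- ll; best_l <- spec_i }
    }
    local_specs[[cty]] <- best_l %||% best
  }
  list(global_spec = best, local_specs = local_specs, trace = trace)
}

# features a local model would use for a country's training slice
local_tune_features <- function(tr_j, schema) {
  cty <- unique(as.character(tr_j$country))[1]
  loc <- feature_names(schema, scope = "local")
  keep <- vapply(loc, function(f) {
    feature_available(schema, f, cty) && !all(is.na(tr_j[[f]]))
  }, logical(1))
  c(feature_names(schema, scope = "global"), loc[keep])
}

# fit a standalone per-country learner on global + available local features
fit_local_only <- function(train_j, schema, spec, k = 5) {
  feats <- local_tune_features(train_j, schema)
  encoders <- fit_feature_encoders(train_j, schema, feats, k,
                                   seed = spec$seed)
  X <- build_matrix(train_j, schema, feats, encoders, mode = "apply")
  model <- fit_rate(spec, X, train_j$deaths, train_j$exposure)
  list(model = model, encoders = encoders, features = feats)
}

predict_local_only <- function(fit, table, schema) {
  X <- build_matrix(table, schema, fit$features, fit$encoders,
                    mode = "apply")
  predict_rate(fit$model, X) * table$exposure
}

#' Run the four-strategy benchmark
#'
#' Fits each requested strategy on the training fold and evaluates RMSE and
#' Poisson log-likelihood per country on both folds. The `local` strategy
#' fits one standalone learner per country on that country's data alone;
#' `two_step` is the hierarchical model; `one_step_single` and
#' `one_step_mice` are the pooled early-fusion competitors. A strategy that
#' fails for a country (e.g. no deaths at all) is recorded as not applicable
#' and the run continues.
#'
#' @param table a portfolio data frame with `fold` labels (`"train"`,
#'   `"test"`); see [assign_folds()].
#' @param schema a [feature_schema()].
#' @param strategies subset of `c("local", "two_step", "one_step_single",
#'   "one_step_mice")`.
#' @param global_spec,local_spec [learner_spec()]s for the pooled/global and
#'   the per-country stages.
#' @param mice a [mice_config()] for the `one_step_mice` strategy.
#' @param k number of encoding folds.
#' @param keep_predictions if `TRUE`, per-record predictions are kept in the
#'   report (for diagnostics).
#' @return an object of class `evaluation_report`: a metrics data frame
#'   (`country`, `strategy`, `metric`, `split`, `value`, `best`) plus
#'   metadata. Best markers are computed from unrounded values (max
#'   log-likelihood, min RMSE).
#' @export
run_benchmark <- function(table, schema,
                          strategies = c("local", "two_step",
                                         "one_step_single", "one_step_mice"),
                          global_spec = learner_spec(),
                          local_spec = global_spec,
                          mice = mice_config(), k = 5,
                          keep_predictions = FALSE) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (!"fold" %in% names(table)) {
    stop("table needs train/test fold labels; see assign_folds()")
  }
  validate_portfolio(table, schema)
  train <- table[table$fold == "train", , drop = FALSE]
  test <- table[table$fold == "test", , drop = FALSE]
  countries <- sort(unique(as.character(table$country)))

  preds <- list() # strategy -> list(train=, test=) per-record deaths
  for (s in strategies) {
    preds[[s]] <- tryCatch(switch(
      s,
      local = {
        ptr <- rep(NA_real_, nrow(train)); pte <- rep(NA_real_, nrow(test))
        for (cty in countries) {
          rtr <- train$country == cty; rte <- test$country == cty
          fit <- tryCatch(
            fit_local_only(train[rtr, , drop = FALSE], schema, local_spec,
                           k = k),
            error = function(e) NULL, warning = function(w) NULL)
          if (is.null(fit)) next
          ptr[rtr] <- predict_local_only(fit, train[rtr, , drop = FALSE],
                                         schema)
          pte[rte] <- predict_local_only(fit, test[rte, , drop = FALSE],
                                         schema)
        }
        list(train = ptr, test = pte)
      },
      two_step = {
        m <- fit_two_step(train, schema, global_spec, local_spec, k = k)
        list(train = predict(m, train), test = predict(m, test))
      },
      one_step_single = {
        r <- one_step_single_value(train, test, schema, global_spec, k = k)
        list(train = r$train, test = r$test)
      },
      one_step_mice = {
        r <- one_step_mice(train, test, schema, global_spec, mice, k = k)
        list(train = r$train, test = r$test)
      }), error = function(e) {
        warning("strategy '", s, "' failed: ", conditionMessage(e))
        list(train = rep(NA_real_, nrow(train)),
             test = rep(NA_real_, nrow(test)))
      })
  }

  rows <- list()
  for (s in strategies) {
    for (cty in countries) {
      for (split in c("train", "test")) {
        tab_s <- if (split == "train") train else test
        p <- preds[[s]][[split]][tab_s$country == cty]
        d <- tab_s$deaths[tab_s$country == cty]
        ok <- length(d) > 0 && !anyNA(p)
        rows[[length(rows) + 1L]] <- data.frame(
          country = cty, strategy = s, split = split,
          rmse = if (ok) rmse(d, p) else NA_real_,
          loglik = if (ok) poisson_loglik(d, pmax(p, 1e-12)) else NA_real_)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  long <- rbind(
    data.frame(metrics[c("country", "strategy", "split")],
               metric = "rmse", value = metrics$rmse),
    data.frame(metrics[c("country", "strategy", "split")],
               metric = "loglik", value = metrics$loglik))
  long$best <- FALSE
  for (cty in countries) {
    for (metric in c("rmse", "loglik")) {
      for (split in c("train", "test")) {
        sel <- long$country == cty & long$metric == metric &
          long$split == split
        v <- long$value[sel]
        if (all(is.na(v))) next
        i_best <- if (metric == "rmse") which.min(v) else which.max(v)
        long$best[sel][i_best] <- TRUE
      }
    }
  }
  out <- list(metrics = long, strategies = strategies,
              countries = countries,
              n_train = nrow(train), n_test = nrow(test))
  if (keep_predictions) out$predictions <- preds
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("Benchmark over", length(x$countries), "countries,",
      x$n_train, "train /", x$n_test, "test records\n")
  lab <- c(rmse.train = "RMSE (Train)", rmse.test = "RMSE (Test)",
           loglik.train = "Log Likelihood (Train)",
           loglik.test = "Log Likelihood (Test)")
  for (cty in x$countries) {
    cat("\nCountry ", cty, ":\n", sep = "")
    m <- x$metrics[x$metrics$country == cty, ]
    tab <- matrix("", nrow = 4, ncol = length(x$strategies),
                  dimnames = list(unname(lab), x$strategies))
    for (i in seq_len(nrow(m))) {
      key <- paste(m$metric[i], m$split[i], sep = ".")
      cell <- if (is.na(m$value[i])) "n/a"
              else formatC(m$value[i], digits = digits, format = "g")
      if (isTRUE(m$best[i])) cell <- paste0(cell, " *")
      tab[lab[key], m$strategy[i]] <- cell
    }
    print(tab, quote = FALSE)
  }
  cat("\n(* best per row, from unrounded values)\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path optional output path; if `NULL`, the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  out <- list(countries = report$countries, strategies = report$strategies,
              n_train = report$n_train, n_test = report$n_test,
              metrics = report$metrics)
  if (is.null(path)) {
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(path)
  }
}

#' Model diagnostics: fit gaps, correlation, A/E ratios, age smoothness
#'
#' @param table a portfolio data frame; `age` and `gender` columns, when
#'   present, drive the actual-over-expected breakdowns, and a `fold` column
#'   drives the train-test gap computation.
#' @param D_hat per-record predicted deaths aligned with `table`.
#' @param truth optional ground-truth data frame (from
#'   [simulate_portfolio()]); when given, the age-smoothness score of the
#'   true rates is reported alongside the predictions' score.
#' @param age_band width of the age bands (years) for A/E and smoothness.
#' @return a list with `correlation` (Pearson, of predicted vs observed
#'   deaths; `NA` with an explanatory `note` when undefined), `gaps`
#'   (train-test RMSE and log-likelihood gaps, when folds are present),
#'   `ae_age`, `ae_gender`, `smoothness` (mean absolute second difference
#'   of the exposure-weighted mean log predicted rate across age bands) and
#'   optionally `smoothness_truth`.
#' @export
diagnostics <- function(table, D_hat, truth = NULL, age_band = 5) {
  stopifnot(nrow(table) == length(D_hat))
  D <- table$deaths
  out <- list()
  if (stats::sd(D_hat) == 0 || stats::sd(D) == 0) {
    out$correlation <- NA_real_
    out$note <- "correlation undefined: constant predictions or outcomes"
  } else {
    out$correlation <- stats::cor(D, D_hat)
  }
  if ("fold" %in% names(table) &&
      all(c("train", "test") %in% table$fold)) {
    tr <- table$fold == "train"
    out$gaps <- c(
      rmse = rmse(D[tr], D_hat[tr]) - rmse(D[!tr], D_hat[!tr]),
      loglik = poisson_loglik(D[tr], pmax(D_hat[tr], 1e-12)) -
        poisson_loglik(D[!tr], pmax(D_hat[!tr], 1e-12)))
  }
  smooth_score <- function(log_rate) {
    band <- floor(table$age / age_band) * age_band
    w <- table$exposure
    m <- tapply(w * log_rate, band, sum) / tapply(w, band, sum)
    m <- m[order(as.numeric(names(m)))]
    if (length(m) < 3) return(NA_real_)
    mean(abs(diff(m, differences = 2)))
  }
  if ("age" %in% names(table)) {
    band <- paste0("[", floor(table$age / age_band) * age_band, ",",
                   floor(table$age / age_band) * age_band + age_band, ")")
    out$ae_age <- ae_by_group(D, D_hat, band)
    out$smoothness <- smooth_score(log(pmax(D_hat, 1e-300) / table$exposure))
    if (!is.null(truth)) {
      out$smoothness_truth <- smooth_score(log(truth$mu_true))
    }
  }
  if ("gender" %in% names(table)) {
    out$ae_gender <- ae_by_group(D, D_hat, table$gender)
  }
  out
}
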