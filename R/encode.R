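#' Sentinel imputation of missing feature values
#'
#' Replaces every missing categorical cell by the literal category
#' `"Missing"` and every missing metric cell by `-1`. The sentinel then
#' participates in target encoding and tree splits as an ordinary value, so
#' the models can pick up missingness patterns through interactions.
#' Non-missing cells are untouched; `deaths`, `exposure`, `country`, and
#' `fold` are never modified.
#'
#' @param table a portfolio data frame.
#' @param schema a [feature_schema()].
#' @return the table with all feature columns complete.
#' @export
impute_sentinels <- function(table, schema) {
  for (f in feature_names(schema)) {
    if (!f %in% names(table)) next
    miss <- is.na(table[[f]])
    if (!any(miss)) next
    if (feature_kind(schema, f) == "categorical") {
      table[[f]][miss] <- "Missing"
    } else {
      table[[f]][miss] <- -1
    }
  }
  table
}

#' Fit a leakage-safe out-of-fold target encoder for one categorical feature
#'
#' Each category is mapped to the (weighted) mean of the target conditional
#' on that category. Two encodings are stored: full-training-set category
#' means, used for transforming new data (`apply` mode), and per-fold
#' fold-complement means, used for transforming the training data itself
#' (`train_oof` mode) so that a record's encoded value never depends on its
#' own target. Unseen categories fall back to the overall mean; in
#' `train_oof` mode the fallback is the fold-complement overall mean, so the
#' zero-self-dependence guarantee also holds on fallback.
#'
#' @param train training portfolio data frame (or any data frame holding the
#'   feature column).
#' @param feature name of a categorical feature column.
#' @param target per-record numeric target, aligned to `train`. For rate
#'   models this is the observed rate `deaths/exposure`.
#' @param k number of folds, at least 2.
#' @param seed integer seed for the internal fold assignment.
#' @param weights optional per-record weights for the category means (for
#'   rate targets, the exposures); default unweighted.
#' @param folds optional explicit integer fold assignment in `1..k`,
#'   overriding the seeded assignment.
#' @param smoothing additive smoothing weight towards the overall mean
#'   (default 0, i.e. raw conditional means).
#' @return an object of class `target_encoder`.
#' @export
#' @examples
#' tr <- data.frame(x = c("A", "A", "B", "B"))
#' enc <- fit_target_encoder(tr, "x", target = c(1, 0, 1, 1), k = 2,
#'                           folds = c(1, 2, 1, 2))
#' te_transform(enc, tr, mode = "train_oof")$x  # c(0, 1, 1, 1)
fit_target_encoder <- function(train, feature, target, k = 5, seed = 1,
                               weights = NULL, folds = NULL, smoothing = 0) {
  stopifnot(is.data.frame(train), feature %in% names(train))
  n <- nrow(train)
  if (length(target) != n) stop("target must align with train records")
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of training records")
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(folds)) {
    folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  }
  stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
  x <- as.character(train[[feature]])

  wmean_by <- function(idx) {
    sw <- tapply(weights[idx] * target[idx], x[idx], sum)
    w <- tapply(weights[idx], x[idx], sum)
    overall <- sum(weights[idx] * target[idx]) / sum(weights[idx])
    m <- (sw + smoothing * overall) / (w + smoothing)
    list(map = c(m), fallback = overall) # drop tapply's array dim
  }

  full <- wmean_by(seq_len(n))
  fold_maps <- lapply(seq_len(k), function(f) wmean_by(which(folds != f)))
  structure(list(feature = feature, k = k, seed = seed, smoothing = smoothing,
                 levels = full$map, fallback = full$fallback,
                 fold_maps = fold_maps, folds = folds),
            class = "target_encoder")
}

#' Apply a target encoder to a table
#'
#' @param encoder a fitted [fit_target_encoder()] object.
#' @param table a data frame carrying the encoder's feature column.
#' @param mode `"apply"` uses full-training-set category means (for new
#'   data); `"train_oof"` uses fold-complement means and requires `table` to
#'   be the training table the encoder was fitted on (same record order), so
#'   the stored fold assignment applies.
#' @return the table with the feature column replaced by its numeric
#'   encoding.
#' @export
te_transform <- function(encoder, table, mode = c("apply", "train_oof")) {
  stopifnot(inherits(encoder, "target_encoder"))
  mode <- match.arg(mode)
  x <- as.character(table[[encoder$feature]])
  if (mode == "apply") {
    v <- unname(encoder$levels[x])
    v[is.na(v)] <- encoder$fallback
  } else {
    if (nrow(table) != length(encoder$folds)) {
      stop("train_oof mode requires the training table the encoder was ",
           "fitted on (fold assignment does not align)")
    }
    v <- numeric(nrow(table))
    for (f in seq_len(encoder$k)) {
      rows <- encoder$folds == f
      fm <- encoder$fold_maps[[f]]
      vv <- unname(fm$map[x[rows]])
      vv[is.na(vv)] <- fm$fallback
      v[rows] <- vv
    }
  }
  table[[encoder$feature]] <- v
  table
}

#' Serialize a target encoder to JSON and back
#'
#' @param encoder a `target_encoder`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `encoder_to_json()` returns the path (invisibly) or a JSON
#'   string; `encoder_from_json()` returns a `target_encoder`.
#' @export
encoder_to_json <- function(encoder, path = NULL) {
  stopifnot(inherits(encoder, "target_encoder"))
  out <- list(
    feature = encoder$feature, k = encoder$k, seed = encoder$seed,
    smoothing = encoder$smoothing,
    levels = as.list(encoder$levels), fallback = encoder$fallback,
    fold_maps = lapply(encoder$fold_maps, function(fm) {
      list(map = as.list(fm$map), fallback = fm$fallback)
    }),
    folds = encoder$folds)
  if (is.null(path)) {
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname encoder_to_json
#' @param json a JSON string or file path produced by [encoder_to_json()].
#' @export
encoder_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(
    feature = raw$feature, k = raw$k, seed = raw$seed,
    smoothing = raw$smoothing,
    levels = unlist(raw$levels), fallback = raw$fallback,
    fold_maps = lapply(raw$fold_maps, function(fm) {
      list(map = unlist(fm$map), fallback = fm$fallback)
    }),
    folds = unlist(raw$folds)),
    class = "target_encoder")
}

# ---- internal pipeline helpers ------------------------------------------

# Fit target encoders for the categorical members of `features` on the
# sentinel-imputed training table, with exposure-weighted rate targets and a
# shared fold assignment (grouped by country-year when possible).
fit_feature_encoders <- function(train, schema, features, k, seed,
                                 folds = NULL) {
  if (is.null(folds)) {
    folds <- make_folds(fold_group_labels(train), k, seed)
  }
  train <- impute_sentinels(train, schema) # "Missing" is an ordinary category
  target <- train$deaths / train$exposure
  encs <- list()
  for (f in features) {
    if (feature_kind(schema, f) == "categorical") {
      encs[[f]] <- fit_target_encoder(train, f, target, k = k, seed = seed,
                                      weights = train$exposure, folds = folds)
    }
  }
  encs
}

# Produce the numeric model matrix for `features`, applying sentinel
# imputation and the given encoders ("train_oof" for the fitting table,
# "apply" for anything else).
build_matrix <- function(table, schema, features, encoders,
                         mode = c("apply", "train_oof")) {
  mode <- match.arg(mode)
  table <- impute_sentinels(table, schema)
  cols <- lapply(features, function(f) {
    if (!f %in% names(table)) stop("table lacks feature column '", f, "'")
    if (!is.null(encoders[[f]])) {
      te_transform(encoders[[f]], table, mode = mode)[[f]]
    } else {
      as.numeric(table[[f]])
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m
}
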