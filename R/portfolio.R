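#' Validate an aggregated portfolio table against a schema
#'
#' A portfolio table is a data frame with one record per unique feature
#' combination per country, carrying the columns `country`, `deaths` (a
#' non-negative integer count), `exposure` (positive life-years at risk), one
#' column per schema feature, and optionally `fold` (`"train"`/`"test"`).
#' Missing cells (`NA`) are allowed only in local features, and a local
#' feature that is not collected in a country must be missing for every
#' record of that country.
#'
#' @param table a data frame.
#' @param schema a [feature_schema()].
#' @return `table`, invisibly, if valid; otherwise an error naming the
#'   offending columns or record indices (records are never silently
#'   dropped).
#' @export
validate_portfolio <- function(table, schema) {
  stopifnot(is.data.frame(table), inherits(schema, "feature_schema"))
  needed <- c("country", "deaths", "exposure", feature_names(schema))
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("portfolio table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(table$exposure) | table$exposure <= 0)
  if (length(bad)) {
    stop("exposure must be positive; offending record(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  d <- table$deaths
  bad <- which(!is.finite(d) | d < 0 | d != round(d))
  if (length(bad)) {
    stop("deaths must be non-negative integers; offending record(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  for (f in feature_names(schema, scope = "global")) {
    bad <- which(is.na(table[[f]]))
    if (length(bad)) {
      stop("global feature '", f, "' has missing values (not allowed; ",
           "global features are complete by design); record(s): ",
           paste(utils::head(bad, 20), collapse = ", "))
    }
  }
  for (f in feature_names(schema, scope = "local")) {
    avail <- schema$features[[f]]$available_in
    if (is.null(avail)) next
    off <- !(as.character(table$country) %in% avail)
    bad <- which(off & !is.na(table[[f]]))
    if (length(bad)) {
      stop("local feature '", f, "' has observed values in a country where ",
           "the schema declares it unavailable; record(s): ",
           paste(utils::head(bad, 20), collapse = ", "))
    }
  }
  if ("fold" %in% names(table)) {
    ok <- table$fold %in% c("train", "test")
    if (!all(ok)) {
      stop("fold labels must be 'train' or 'test'; offending record(s): ",
           paste(utils::head(which(!ok), 20), collapse = ", "))
    }
  }
  invisible(table)
}

#' Read and write portfolio CSV files
#'
#' The on-disk format is RFC-4180 CSV (UTF-8, header row) with one row per
#' aggregated record. An empty cell encodes a missing value; no sentinel
#' substitution happens at read time, so raw tables and model-ready tables
#' (see [impute_sentinels()]) remain distinguishable.
#'
#' @param path CSV file path.
#' @param schema a [feature_schema()] describing the feature columns.
#' @return `read_portfolio()` returns a validated portfolio data frame;
#'   `write_portfolio()` returns `path` invisibly.
#' @export
read_portfolio <- function(path, schema) {
  if (!file.exists(path)) stop("portfolio file not found: ", path)
  cls <- c(country = "character", deaths = "numeric", exposure = "numeric")
  for (f in feature_names(schema)) {
    cls[[f]] <- if (feature_kind(schema, f) == "categorical") "character"
                else "numeric"
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE)
  for (nm in intersect(names(cls), names(tab))) {
    tab[[nm]] <- switch(cls[[nm]],
                        character = as.character(tab[[nm]]),
                        numeric = as.numeric(tab[[nm]]))
  }
  validate_portfolio(tab, schema)
  tab
}

#' @rdname read_portfolio
#' @param table a portfolio data frame.
#' @export
write_portfolio <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign train/test folds, stratified by country
#'
#' Every record receives exactly one of the labels `"train"`/`"test"`.
#' Stratification by country guarantees each country is represented in both
#' splits, which per-country out-of-sample evaluation requires. Within a
#' country the number of training records is `round(train_fraction * n)`, so
#' for countries with at least a few hundred records the realised train share
#' is within a fraction of a percentage point of the target.
#'
#' @param table a portfolio data frame.
#' @param train_fraction target train share, strictly between 0 and 1.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return the table with a `fold` column.
#' @export
assign_folds <- function(table, train_fraction = 0.8, seed = 1) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      !is.finite(train_fraction) ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  fold <- character(nrow(table))
  with_seed(seed, {
    for (cty in unique(table$country)) {
      idx <- which(table$country == cty)
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 0L), length(idx))
      tr <- sample(idx, n_train)
      fold[idx] <- "test"
      fold[tr] <- "train"
    }
  })
  table$fold <- fold
  table
}

#' Percentage of missing values per (country, feature) pair
#'
#' @param table a validated portfolio data frame.
#' @param schema a [feature_schema()].
#' @return a numeric matrix, countries in rows and schema features in
#'   columns, holding `100 * #missing / #records` for each country. Global
#'   feature columns are identically 0 in valid tables.
#' @export
missingness_report <- function(table, schema) {
  validate_portfolio(table, schema)
  countries <- sort(unique(as.character(table$country)))
  feats <- feature_names(schema)
  out <- matrix(0, nrow = length(countries), ncol = length(feats),
                dimnames = list(countries, feats))
  for (cty in countries) {
    rows <- table$country == cty
    for (f in feats) {
      out[cty, f] <- 100 * mean(is.na(table[[f]][rows]))
    }
  }
  out
}
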