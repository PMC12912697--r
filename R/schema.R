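#' Feature schema for multi-country portfolio tables
#'
#' A feature schema declares, for every model feature, its kind (categorical
#' or metric), its scope (global or local), and -- for local features -- the
#' set of countries in which it is collected at all. Global features must be
#' available everywhere: the data design guarantees they are free of missing
#' values, and validation enforces that.
#'
#' @param features a list of feature specifications, each a list with entries
#'   `name` (character), `kind` (`"categorical"` or `"metric"`), `scope`
#'   (`"global"` or `"local"`), and optionally `available_in` (character
#'   vector of country ids; `NULL` means all countries). `available_in` may
#'   only be restricted for local features.
#' @return an object of class `feature_schema`.
#' @export
#' @examples
#' sch <- feature_schema(list(
#'   list(name = "age",    kind = "metric",      scope = "global"),
#'   list(name = "gender", kind = "categorical", scope = "global"),
#'   list(name = "region", kind = "categorical", scope = "local",
#'        available_in = c("c1", "c2"))
#' ))
#' feature_names(sch)
#' feature_names(sch, scope = "global")
feature_schema <- function(features) {
  stopifnot(is.list(features), length(features) >= 1L)
  specs <- lapply(features, function(f) {
    stopifnot(is.list(f), !is.null(f$name), !is.null(f$kind), !is.null(f$scope))
    kind <- match.arg(f$kind, c("categorical", "metric"))
    scope <- match.arg(f$scope, c("global", "local"))
    avail <- f$available_in
    if (!is.null(avail)) avail <- as.character(avail)
    if (scope == "global" && !is.null(avail)) {
      stop("global feature '", f$name, "' may not restrict 'available_in': ",
           "global features are available in all countries by design")
    }
    list(name = as.character(f$name), kind = kind, scope = scope,
         available_in = avail)
  })
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (!any(vapply(specs, `[[`, "", "scope") == "global")) {
    stop("a feature schema needs at least one global feature")
  }
  names(specs) <- nms
  structure(list(features = specs), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$features), "features\n")
  for (f in x$features) {
    avail <- if (is.null(f$available_in)) "all countries"
             else paste(f$available_in, collapse = ", ")
    cat(sprintf("  %-16s %-11s %-6s  available: %s\n",
                f$name, f$kind, f$scope, avail))
  }
  invisible(x)
}

#' @rdname feature_schema
#' @param schema a `feature_schema`.
#' @param scope optional scope filter (`"global"` or `"local"`).
#' @param kind optional kind filter (`"categorical"` or `"metric"`).
#' @export
feature_names <- function(schema, scope = NULL, kind = NULL) {
  stopifnot(inherits(schema, "feature_schema"))
  keep <- vapply(schema$features, function(f) {
    (is.null(scope) || f$scope == scope) && (is.null(kind) || f$kind == kind)
  }, logical(1))
  names(schema$features)[keep]
}

feature_kind <- function(schema, name) schema$features[[name]]$kind
feature_scope <- function(schema, name) schema$features[[name]]$scope

# is feature `name` collected at all in country `country`?
feature_available <- function(schema, name, country) {
  f <- schema$features[[name]]
  if (is.null(f)) stop("unknown feature: ", name)
  is.null(f$available_in) || as.character(country) %in% f$available_in
}

#' Read or write a feature schema file
#'
#' Schema files are YAML or JSON (decided by file extension) holding a list
#' of feature specifications with the fields of [feature_schema()].
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_schema()` returns a `feature_schema`; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  feature_schema(raw$features %||% raw)
}

#' @rdname read_schema
#' @param schema a `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  out <- list(features = lapply(unname(schema$features), function(f) {
    f[!vapply(f, is.null, logical(1))]
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
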