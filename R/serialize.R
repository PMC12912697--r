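# Persistence of fitted models: each learner is stored as the backend's
# JSON tree dump plus a JSON sidecar (b0, feature list, spec, seed), and
# encoders as JSON category->value maps, so a bundle is plain text.

save_rate_learner <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(model$booster)) {
    xgboost::xgb.save(model$booster, file.path(dir, "model.json"))
  }
  meta <- list(b0 = model$b0, features = as.list(model$features),
               rate0 = model$rate0, n_trees = model$n_trees,
               spec = unclass(model$spec))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

load_rate_learner <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = TRUE)
  booster <- NULL
  if (file.exists(file.path(dir, "model.json"))) {
    booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  }
  structure(list(booster = booster, b0 = meta$b0,
                 features = unlist(meta$features),
                 spec = do.call(learner_spec, as.list(meta$spec)),
                 rate0 = meta$rate0, n_trees = meta$n_trees),
            class = "rate_learner")
}

save_encoders <- function(encoders, path) {
  out <- lapply(encoders, function(e) {
    jsonlite::fromJSON(encoder_to_json(e), simplifyVector = FALSE)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_encoders <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    encoder_from_json(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
  })
}

#' Save or load a fitted two-step model bundle
#'
#' The bundle is a directory of text files: the global and per-country local
#' learners (backend JSON dumps plus sidecars), all encoders, the schema,
#' and a manifest with seeds and specs.
#'
#' @param model a fitted [fit_two_step()] model.
#' @param dir bundle directory (created if needed).
#' @return `save_two_step()` returns `dir` invisibly; `load_two_step()`
#'   returns the restored `two_step` model.
#' @export
save_two_step <- function(model, dir) {
  stopifnot(inherits(model, "two_step"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_schema(model$schema, file.path(dir, "schema.yaml"))
  gdir <- file.path(dir, "global")
  save_rate_learner(model$global$learner, gdir)
  save_encoders(model$global$encoders, file.path(gdir, "encoders.json"))
  jsonlite::write_json(
    list(features = as.list(model$global$features), k = model$global$k),
    file.path(gdir, "stage.json"), auto_unbox = TRUE)
  for (cty in names(model$locals)) {
    l <- model$locals[[cty]]
    ldir <- file.path(dir, paste0("local_", cty))
    save_rate_learner(l$learner, ldir)
    save_encoders(l$encoders, file.path(ldir, "encoders.json"))
    jsonlite::write_json(
      list(features = as.list(l$features), country = l$country, k = l$k),
      file.path(ldir, "stage.json"), auto_unbox = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mortboost")),
    countries = names(model$locals), k = model$k,
    global_spec = unclass(model$global_spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_two_step
#' @export
load_two_step <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  schema <- read_schema(file.path(dir, "schema.yaml"))
  gdir <- file.path(dir, "global")
  gstage <- jsonlite::fromJSON(file.path(gdir, "stage.json"))
  gspec <- do.call(learner_spec, as.list(manifest$global_spec))
  global <- structure(list(
    learner = load_rate_learner(gdir),
    encoders = load_encoders(file.path(gdir, "encoders.json")),
    features = unlist(gstage$features), k = gstage$k, spec = gspec),
    class = "global_model")
  locals <- list()
  for (cty in manifest$countries) {
    ldir <- file.path(dir, paste0("local_", cty))
    lstage <- jsonlite::fromJSON(file.path(ldir, "stage.json"))
    locals[[as.character(cty)]] <- structure(list(
      learner = load_rate_learner(ldir),
      encoders = load_encoders(file.path(ldir, "encoders.json")),
      features = unlist(lstage$features), country = lstage$country,
      k = lstage$k, spec = gspec), class = "local_model")
  }
  structure(list(global = global, locals = locals, schema = schema,
                 global_spec = gspec, local_specs = NULL, k = manifest$k),
            class = "two_step")
}
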