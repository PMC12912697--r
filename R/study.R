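# End-to-end "simulated study" driver: the functions behind the command-line
# entry point (inst/cli/mortboost.R). Each stage derives its own sub-seed
# from the master seed (stage-name-keyed), logs one line per stage, and
# writes a manifest sufficient to reproduce its outputs.

#' Summarise a portfolio per country
#'
#' @param table a portfolio data frame.
#' @return a data frame with per-country deaths, exposure, record counts,
#'   and (when a `year` column is present) observed year ranges.
#' @export
summarize_portfolio <- function(table) {
  countries <- sort(unique(as.character(table$country)))
  out <- do.call(rbind, lapply(countries, function(cty) {
    rows <- table$country == cty
    data.frame(
      country = cty,
      deaths = sum(table$deaths[rows]),
      exposure = sum(table$exposure[rows]),
      n_groups = sum(rows),
      years = if ("year" %in% names(table)) {
        paste0(min(table$year[rows]), "-", max(table$year[rows]))
      } else NA_character_)
  }))
  rownames(out) <- NULL
  out
}

#' Read a study configuration file
#'
#' Study configs are YAML with optional sections `study` (`scale`, `seed`,
#' `train_fraction`), `paths` (`portfolio`, `truth`, `schema`, `bundle`,
#' `report`), `strategies`, `learner` / `local_learner` ([learner_spec()]
#' arguments), and `mice` ([mice_config()] arguments).
#'
#' @param path YAML file path.
#' @return a named list with defaults filled in.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(list(
    study = list(scale = 0.01, seed = 1, train_fraction = 0.8),
    paths = list(portfolio = "portfolio.csv", truth = "truth.csv",
                 schema = "schema.yaml", bundle = "bundle",
                 report = "report.json"),
    strategies = c("local", "two_step", "one_step_single", "one_step_mice"),
    learner = list(), local_learner = list(), mice = list()),
    raw)
  for (f in c("portfolio", "schema")) {
    if (is.null(cfg$paths[[f]])) {
      stop("config error: missing required field paths$", f)
    }
  }
  cfg
}

study_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

study_specs <- function(cfg) {
  master <- cfg$study$seed %||% 1
  gl <- do.call(learner_spec, utils::modifyList(
    list(seed = derive_seed(master, "global")), cfg$learner))
  lo <- do.call(learner_spec, utils::modifyList(
    list(seed = derive_seed(master, "local")),
    utils::modifyList(cfg$learner, cfg$local_learner)))
  list(global = gl, local = lo)
}

#' Study driver stages
#'
#' `study_simulate()` writes the simulated portfolio, ground truth, and
#' schema files and logs a per-country summary; `study_fit()` reads them,
#' ensures fold labels (auto 80-20 split with a warning when absent), fits
#' the two-step model, and writes the bundle; `study_benchmark()` runs the
#' requested strategies and writes the report JSON. Each stage is
#' deterministic given the config's master seed.
#'
#' @param cfg a config list from [read_study_config()].
#' @return the stage's main artifact, invisibly (the simulation list, the
#'   fitted model, or the evaluation report).
#' @export
study_simulate <- function(cfg) {
  master <- cfg$study$seed %||% 1
  sim_cfg <- default_study_config(scale = cfg$study$scale %||% 0.01,
                                  seed = derive_seed(master, "simulate"))
  sim <- simulate_portfolio(sim_cfg)
  sim$table <- assign_folds(sim$table,
                            cfg$study$train_fraction %||% 0.8,
                            seed = derive_seed(master, "folds"))
  write_portfolio(sim$table, cfg$paths$portfolio)
  utils::write.csv(sim$truth, cfg$paths$truth %||% "truth.csv",
                   row.names = FALSE)
  write_schema(sim$schema, cfg$paths$schema)
  s <- summarize_portfolio(sim$table)
  study_log("simulate", nrow(sim$table), " records, ",
            sum(s$deaths), " deaths, ", round(sum(s$exposure)),
            " life-years")
  for (i in seq_len(nrow(s))) {
    study_log("simulate", sprintf(
      "country %s: D=%d E=%.0f N=%d years=%s",
      s$country[i], s$deaths[i], s$exposure[i], s$n_groups[i], s$years[i]))
  }
  invisible(sim)
}

#' @rdname study_simulate
#' @export
study_fit <- function(cfg) {
  schema <- read_schema(cfg$paths$schema)
  table <- read_portfolio(cfg$paths$portfolio, schema)
  master <- cfg$study$seed %||% 1
  if (!"fold" %in% names(table)) {
    warning("no fold labels found; applying an automatic 80-20 split")
    table <- assign_folds(table, cfg$study$train_fraction %||% 0.8,
                          seed = derive_seed(master, "folds"))
  }
  specs <- study_specs(cfg)
  train <- table[table$fold == "train", , drop = FALSE]
  study_log("fit", "training on ", nrow(train), " records, ",
            length(unique(train$country)), " countries")
  model <- fit_two_step(train, schema, specs$global, specs$local)
  d_hat <- predict(model, train)
  study_log("fit", sprintf("train balance sum(Dhat)/sum(D) = %.4f",
                           sum(d_hat) / sum(train$deaths)))
  if (!is.null(cfg$paths$bundle)) save_two_step(model, cfg$paths$bundle)
  invisible(model)
}

#' @rdname study_simulate
#' @param strategies optional override of the config's strategy list.
#' @export
study_benchmark <- function(cfg, strategies = NULL) {
  schema <- read_schema(cfg$paths$schema)
  table <- read_portfolio(cfg$paths$portfolio, schema)
  master <- cfg$study$seed %||% 1
  if (!"fold" %in% names(table)) {
    warning("no fold labels found; applying an automatic 80-20 split")
    table <- assign_folds(table, cfg$study$train_fraction %||% 0.8,
                          seed = derive_seed(master, "folds"))
  }
  specs <- study_specs(cfg)
  mice <- do.call(mice_config, utils::modifyList(
    list(seed = derive_seed(master, "mice")), cfg$mice))
  strategies <- strategies %||% cfg$strategies
  study_log("benchmark", "strategies: ", paste(strategies, collapse = ", "))
  rep <- run_benchmark(table, schema, strategies = strategies,
                       global_spec = specs$global,
                       local_spec = specs$local, mice = mice)
  if (!is.null(cfg$paths$report)) report_to_json(rep, cfg$paths$report)
  study_log("benchmark", "report written to ", cfg$paths$report %||% "-")
  invisible(rep)
}
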