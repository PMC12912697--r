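# shared fixtures: tiny schemas, tables, and simulation configs built in code

toy_schema <- function() {
  feature_schema(list(
    list(name = "age",    kind = "metric",      scope = "global"),
    list(name = "gender", kind = "categorical", scope = "global"),
    list(name = "region", kind = "categorical", scope = "local",
         available_in = c("c1", "c2")),
    list(name = "loading", kind = "metric", scope = "local")
  ))
}

toy_table <- function() {
  data.frame(
    country = c("c1", "c1", "c2", "c2", "c3", "c3"),
    age = c(30, 40, 50, 60, 35, 45),
    gender = c("M", "F", "M", "F", "M", "F"),
    region = c("a", NA, "b", "b", NA, NA),
    loading = c(0.1, 0.2, NA, 0.4, 0.5, NA),
    deaths = c(1, 0, 2, 1, 0, 3),
    exposure = c(10, 20, 30, 40, 50, 60),
    stringsAsFactors = FALSE)
}

# two-country config with a single local categorical effect; fast to fit
toy_sim_config <- function(n = 3000, seed = 1, exposure_scale = 20,
                           log_level_b = 0, local_effect_b = NULL) {
  generators <- list(
    age    = list(kind = "metric", scope = "global", min = 30, max = 60),
    gender = list(kind = "categorical", scope = "global",
                  levels = c("F", "M"), probs = c(0.5, 0.5)),
    grp    = list(kind = "categorical", scope = "local",
                  levels = c("g1", "g2"))
  )
  simulation_config(
    countries = list(
      list(id = "A", n_groups = n, exposure_scale = exposure_scale,
           exposure_sdlog = 0.5),
      list(id = "B", n_groups = n, exposure_scale = exposure_scale,
           exposure_sdlog = 0.5, log_level = log_level_b,
           local_effects = if (is.null(local_effect_b)) list()
                           else list(grp = local_effect_b))),
    global_effects = list(gender_log_rr = 0.45),
    generators = generators, seed = seed)
}

fast_spec <- function(n_trees = 50, ...) {
  learner_spec(n_trees = n_trees, learning_rate = 0.2, max_leaves = 8,
               min_exposure_per_leaf = 0, min_deaths_per_leaf = 5, ...)
}
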