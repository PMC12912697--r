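bench_sim <- local({
  cfg <- toy_sim_config(n = 2500, seed = 41, log_level_b = 0.3,
                        local_effect_b = c(g1 = -0.3, g2 = 0.3))
  cfg$countries[[2]]$missingness <- c(grp = 0.2)
  simulate_portfolio(cfg)
})
bench_tab <- assign_folds(bench_sim$table, 0.8, seed = 6)

test_that("grouped tuning folds keep country-year combinations together", {
  sim <- simulate_portfolio(default_study_config(scale = 0.0003, seed = 4))
  folds <- mortboost:::make_folds(
    mortboost:::fold_group_labels(sim$table), 5, 1)
  grp <- mortboost:::fold_group_labels(sim$table)
  # no group straddles folds
  expect_true(all(tapply(folds, grp, function(f) length(unique(f))) == 1))
  expect_setequal(unique(folds), 1:5)
})

test_that("tune returns the candidate with the best OOF log-likelihood", {
  train <- bench_tab[bench_tab$fold == "train", ]
  train$year <- sample(2016:2020, nrow(train), replace = TRUE)
  base <- fast_spec(n_trees = 20, seed = 3)
  res <- tune(train, bench_sim$schema,
              search_space = list(n_trees = c(0, 20)),
              base_spec = base, budget = 2, seed = 5)
  # 20 boosting rounds must beat the intercept-only model here
  expect_equal(res$global_spec$n_trees, 20L)
  expect_named(res$local_specs, unique(as.character(train$country)),
               ignore.order = TRUE)
  expect_equal(nrow(res$trace), 2)
  # identical candidates: the first is kept (fixed tie-break)
  res2 <- tune(train, bench_sim$schema,
               search_space = list(learning_rate = c(0.2, 0.2)),
               base_spec = base, budget = 2, seed = 5)
  expect_equal(res2$global_spec$learning_rate, 0.2)
  # too few groups for the requested fold count
  tiny <- train[train$year == 2016 & train$country == "A", ]
  expect_error(tune(tiny, bench_sim$schema,
                    search_space = list(n_trees = c(5, 10)), budget = 2),
               "fewer folds")
})

test_that("the benchmark report has the Table-style shape and sane values", {
  rep <- suppressWarnings(run_benchmark(
    bench_tab, bench_sim$schema,
    strategies = c("local", "two_step", "one_step_single", "one_step_mice"),
    global_spec = fast_spec(n_trees = 40, seed = 2),
    local_spec = fast_spec(n_trees = 20, seed = 3),
    mice = mice_config(n_bootstrap = 2, seed = 4)))
  m <- rep$metrics
  # countries x strategies x metrics x splits
  expect_equal(nrow(m), 2 * 4 * 2 * 2)
  expect_setequal(unique(m$strategy),
                  c("local", "two_step", "one_step_single", "one_step_mice"))
  # exactly one best marker per (country, metric, split) row group
  agg <- aggregate(best ~ country + metric + split, data = m, FUN = sum)
  expect_true(all(agg$best == 1))
  # Poisson balance on the training fold
  train <- bench_tab[bench_tab$fold == "train", ]
  rep2 <- suppressWarnings(run_benchmark(
    bench_tab, bench_sim$schema, strategies = "two_step",
    global_spec = fast_spec(n_trees = 40, seed = 2),
    local_spec = fast_spec(n_trees = 20, seed = 3),
    keep_predictions = TRUE))
  p <- rep2$predictions$two_step$train
  expect_lt(abs(sum(p) / sum(train$deaths) - 1), 0.05)
  expect_output(print(rep), "Country A")
})

test_that("removing a strategy never changes another strategy's metrics", {
  g <- fast_spec(n_trees = 30, seed = 2)
  l <- fast_spec(n_trees = 15, seed = 3)
  all4 <- suppressWarnings(run_benchmark(
    bench_tab, bench_sim$schema,
    strategies = c("local", "two_step"), global_spec = g, local_spec = l))
  solo <- suppressWarnings(run_benchmark(
    bench_tab, bench_sim$schema, strategies = "two_step",
    global_spec = g, local_spec = l))
  m_all <- all4$metrics[all4$metrics$strategy == "two_step",
                        c("country", "split", "metric", "value")]
  m_solo <- solo$metrics[, c("country", "split", "metric", "value")]
  expect_equal(m_all[order(m_all$country, m_all$split, m_all$metric), ],
               m_solo[order(m_solo$country, m_solo$split, m_solo$metric), ],
               ignore_attr = TRUE)
})

test_that("report JSON serialization is deterministic", {
  g <- fast_spec(n_trees = 20, seed = 2)
  r1 <- suppressWarnings(run_benchmark(bench_tab, bench_sim$schema,
                                       strategies = "one_step_single",
                                       global_spec = g))
  r2 <- suppressWarnings(run_benchmark(bench_tab, bench_sim$schema,
                                       strategies = "one_step_single",
                                       global_spec = g))
  expect_identical(as.character(report_to_json(r1)),
                   as.character(report_to_json(r2)))
})

test_that("diagnostics: perfect, imperfect, and degenerate predictions", {
  tab <- bench_tab[bench_tab$fold == "test", ]
  # a perfect model: correlation 1, all defined A/E ratios exactly 1
  d_perfect <- diagnostics(tab, tab$deaths)
  expect_equal(unname(d_perfect$correlation), 1)
  ae <- d_perfect$ae_age$by_group
  expect_true(all(ae[!is.na(ae)] == 1))
  expect_equal(d_perfect$ae_gender$overall, 1)
  # constant predictions: correlation reported as undefined, not an error
  d_const <- diagnostics(tab, rep(1, nrow(tab)))
  expect_true(is.na(d_const$correlation))
  expect_match(d_const$note, "undefined")
})

test_that("the age-smoothness score ranks prediction roughness correctly", {
  cfg <- toy_sim_config(n = 25000, seed = 43, exposure_scale = 100)
  sim <- simulate_portfolio(cfg)
  tab <- assign_folds(sim$table, 0.8, seed = 1)
  train <- tab[tab$fold == "train", ]
  truth <- sim$truth[tab$fold == "train", ]
  # predictions at the true rates reproduce the truth reference score
  d_true <- diagnostics(train, truth$mu_true * train$exposure, truth = truth)
  expect_equal(d_true$smoothness, d_true$smoothness_truth)
  # a fitted model's stepwise age profile is rougher than the generating
  # curve, but far smoother than deliberately jittered predictions
  m <- fit_two_step(train, sim$schema,
                    learner_spec(n_trees = 150, learning_rate = 0.1,
                                 max_leaves = 16, min_exposure_per_leaf = 0,
                                 min_deaths_per_leaf = 20, seed = 2),
                    learner_spec(n_trees = 0))
  d_hat <- predict(m, train)
  d_fit <- diagnostics(train, d_hat, truth = truth)
  expect_gte(d_fit$smoothness, d_true$smoothness_truth)
  set.seed(1)
  jitter <- d_hat * exp(rnorm(length(d_hat), 0, 1))
  d_jit <- diagnostics(train, jitter)
  expect_gt(d_jit$smoothness, d_fit$smoothness)
})
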