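# two-country simulated fixture shared across this file
sim_two <- simulate_portfolio(toy_sim_config(n = 4000, seed = 21,
                                             log_level_b = log(2)))
tab_two <- assign_folds(sim_two$table, 0.8, seed = 1)
train_two <- tab_two[tab_two$fold == "train", ]
test_two <- tab_two[tab_two$fold == "test", ]

test_that("the prediction factorises exactly into global x local x exposure", {
  m <- fit_two_step(train_two, sim_two$schema, fast_spec(seed = 2),
                    fast_spec(n_trees = 30, seed = 3))
  d_hat <- predict(m, test_two)
  sc <- predict(m, test_two, type = "scores")
  dev <- abs(log(d_hat) - log(test_two$exposure) -
               (sc$log_global + sc$log_local))
  expect_lt(max(dev), 1e-10)
  expect_equal(predict(m, test_two, type = "rate") * test_two$exposure,
               d_hat, tolerance = 1e-12)
})

test_that("zero-tree local stage leaves the global prediction untouched", {
  m <- fit_two_step(train_two, sim_two$schema, fast_spec(seed = 2),
                    learner_spec(n_trees = 0))
  sc <- predict(m, test_two, type = "scores")
  expect_true(all(sc$log_local == 0)) # h_j == 1 exactly
  q <- predict(m, test_two, type = "rate")
  g <- exp(sc$log_global)
  expect_equal(q, g, tolerance = 1e-12)
})

test_that("the local stage recovers a constant residual factor", {
  # global fitted on country A only; country B's truth is 2x the A pattern.
  # The local spec is parsimonious (few leaves, high death threshold): the
  # true deviation is a constant factor, so a root-heavy residual model is
  # the appropriate choice and keeps the factor estimate stable.
  cfgA <- toy_sim_config(n = 10000, seed = 31, exposure_scale = 50,
                         log_level_b = log(2))
  sim <- simulate_portfolio(cfgA)
  trA <- sim$table[sim$table$country == "A", ]
  trB <- sim$table[sim$table$country == "B", ]
  gm <- fit_global(trA, sim$schema,
                   learner_spec(n_trees = 150, learning_rate = 0.1,
                                max_leaves = 16, min_exposure_per_leaf = 0,
                                min_deaths_per_leaf = 20, seed = 5))
  lm_b <- fit_local(trB, gm, sim$schema,
                    learner_spec(n_trees = 100, learning_rate = 0.1,
                                 max_leaves = 4, min_exposure_per_leaf = 0,
                                 min_deaths_per_leaf = 50, seed = 6))
  h <- mortboost:::predict_local_factor(lm_b, trB, sim$schema)
  h_bar <- sum(trB$exposure * h) / sum(trB$exposure)
  expect_lt(abs(h_bar / 2 - 1), 0.10)
})

test_that("global model ignores local features entirely", {
  m <- fit_global(train_two, sim_two$schema, fast_spec(seed = 2))
  permuted <- train_two
  permuted$grp <- sample(permuted$grp)
  expect_identical(
    mortboost:::predict_global(m, train_two, sim_two$schema),
    mortboost:::predict_global(m, permuted, sim_two$schema))
})

test_that("pooling over one country equals a single-country global fit", {
  one <- train_two[train_two$country == "A", ]
  m1 <- fit_global(one, sim_two$schema, fast_spec(seed = 4))
  m2 <- fit_global(one, sim_two$schema, fast_spec(seed = 4))
  expect_identical(mortboost:::predict_global(m1, one, sim_two$schema),
                   mortboost:::predict_global(m2, one, sim_two$schema))
})

test_that("refitting with the same seeds is bit-identical", {
  m1 <- fit_two_step(train_two, sim_two$schema, fast_spec(seed = 8),
                     fast_spec(n_trees = 20, seed = 9))
  m2 <- fit_two_step(train_two, sim_two$schema, fast_spec(seed = 8),
                     fast_spec(n_trees = 20, seed = 9))
  expect_identical(predict(m1, test_two), predict(m2, test_two))
})

test_that("onboarding adds a country without touching existing predictions", {
  trA <- train_two[train_two$country == "A", ]
  trB <- train_two[train_two$country == "B", ]
  teA <- test_two[test_two$country == "A", ]
  teB <- test_two[test_two$country == "B", ]
  m <- fit_two_step(trA, sim_two$schema, fast_spec(seed = 2),
                    fast_spec(n_trees = 20, seed = 3))
  before <- predict(m, teA)
  expect_error(predict(m, teB), "country.*B")
  m2 <- onboard_country(m, trB, spec = fast_spec(n_trees = 20, seed = 3))
  expect_identical(predict(m2, teA), before)
  pB <- predict(m2, teB)
  expect_true(all(pB > 0))
  expect_error(onboard_country(m2, trB), "already part")
  # zero-tree onboarding reduces to the global model
  m3 <- onboard_country(m, trB, spec = learner_spec(n_trees = 0))
  scB <- predict(m3, teB, type = "scores")
  expect_true(all(scB$log_local == 0))
})

test_that("local models drop features that are entirely missing", {
  sch <- feature_schema(list(
    list(name = "age", kind = "metric", scope = "global"),
    list(name = "extra", kind = "categorical", scope = "local")))
  set.seed(2)
  tr <- data.frame(country = "X", age = runif(300, 30, 60),
                   extra = NA_character_,
                   deaths = rpois(300, 1), exposure = runif(300, 5, 15),
                   stringsAsFactors = FALSE)
  gm <- fit_global(tr, sch, fast_spec(n_trees = 10, seed = 1))
  lm_x <- fit_local(tr, gm, sch, fast_spec(n_trees = 10, seed = 1))
  expect_false("extra" %in% lm_x$features)
})

test_that("the eight-country study yields one global and eight local models", {
  sim <- simulate_portfolio(default_study_config(scale = 0.0005, seed = 2))
  tab <- assign_folds(sim$table, 0.8, seed = 3)
  tr <- tab[tab$fold == "train", ]
  m <- suppressWarnings(
    fit_two_step(tr, sim$schema, fast_spec(n_trees = 20, seed = 1),
                 fast_spec(n_trees = 10, seed = 1)))
  expect_length(m$locals, 8)
  expect_s3_class(m$global, "global_model")
  s <- summary(m)
  expect_equal(s$n_countries, 8)
  d_hat <- predict(m, tab[tab$fold == "test", ])
  expect_true(all(is.finite(d_hat) & d_hat > 0))
})

test_that("a fitted model survives a bundle round trip", {
  m <- fit_two_step(train_two, sim_two$schema, fast_spec(seed = 2),
                    fast_spec(n_trees = 20, seed = 3))
  dir <- withr::local_tempdir()
  save_two_step(m, dir)
  back <- load_two_step(dir)
  expect_equal(predict(back, test_two), predict(m, test_two),
               tolerance = 1e-7)
})
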