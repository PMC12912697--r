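mice_schema <- function() {
  feature_schema(list(
    list(name = "z", kind = "metric", scope = "global"),
    list(name = "m", kind = "categorical", scope = "local"),
    list(name = "v", kind = "metric", scope = "local")))
}

test_that("a complete table is returned unchanged, n_bootstrap times", {
  sch <- mice_schema()
  tab <- data.frame(country = "c1", z = 1:6, m = rep(c("a", "b"), 3),
                    v = seq(0.1, 0.6, by = 0.1),
                    deaths = 0:5, exposure = rep(10, 6),
                    stringsAsFactors = FALSE)
  out <- mice_impute(tab, sch, mice_config(n_bootstrap = 4, seed = 3))
  expect_length(out, 4)
  for (t in out) expect_identical(t, tab)
})

test_that("pure leaves impute deterministically; observed cells never change", {
  sch <- mice_schema()
  set.seed(1)
  n <- 120
  z <- rep(c(0, 1), each = n / 2)
  m <- ifelse(z == 1, "a", "b") # m perfectly determined by z
  tab <- data.frame(country = "c1", z = z, m = m, v = runif(n),
                    deaths = rpois(n, 1), exposure = rep(5, n),
                    stringsAsFactors = FALSE)
  tab$m[c(3, 70)] <- NA
  out <- mice_impute(tab, sch, mice_config(n_bootstrap = 4, mincut = 2,
                                           minsize = 4, seed = 9))
  for (t in out) {
    # pure-leaf draws have a single support point
    expect_identical(t$m[3], "b")  # z = 0 there
    expect_identical(t$m[70], "a") # z = 1 there
    # only the originally-missing cells may differ
    expect_identical(t$m[-c(3, 70)], tab$m[-c(3, 70)])
    expect_identical(t$z, tab$z)
    expect_identical(t$v, tab$v)
    expect_identical(t$deaths, tab$deaths)
  }
})

test_that("metric variables are imputed from regression-tree leaves", {
  sch <- mice_schema()
  set.seed(2)
  n <- 200
  z <- rep(c(0, 1), each = n / 2)
  v <- ifelse(z == 1, 0.9, 0.1) + runif(n, -0.05, 0.05)
  tab <- data.frame(country = "c1", z = z, m = "a", v = v,
                    deaths = rpois(n, 1), exposure = rep(5, n),
                    stringsAsFactors = FALSE)
  miss <- c(10, 150)
  tab$v[miss] <- NA
  out <- mice_impute(tab, sch, mice_config(n_bootstrap = 2, seed = 4))
  for (t in out) {
    expect_false(anyNA(t$v))
    # draws come from the observed values in the matching leaf
    expect_lt(abs(t$v[10] - 0.1), 0.06)
    expect_lt(abs(t$v[150] - 0.9), 0.06)
  }
})

test_that("a variable missing everywhere is sentinel-filled and flagged", {
  sch <- mice_schema()
  tab <- data.frame(country = "c1", z = 1:10, m = NA_character_,
                    v = runif(10), deaths = rpois(10, 1),
                    exposure = rep(2, 10), stringsAsFactors = FALSE)
  out <- mice_impute(tab, sch, mice_config(n_bootstrap = 2, seed = 5))
  expect_equal(attr(out, "sentinel_filled"), "m")
  for (t in out) expect_true(all(t$m == "Missing"))
})

test_that("imputation is deterministic given the seed", {
  sch <- mice_schema()
  set.seed(6)
  tab <- data.frame(country = "c1", z = runif(80), m = sample(c("a", "b"), 80,
                    replace = TRUE), v = runif(80),
                    deaths = rpois(80, 1), exposure = rep(3, 80),
                    stringsAsFactors = FALSE)
  tab$m[sample(80, 20)] <- NA
  tab$v[sample(80, 20)] <- NA
  a <- mice_impute(tab, sch, mice_config(seed = 11))
  b <- mice_impute(tab, sch, mice_config(seed = 11))
  expect_identical(unclass(a), unclass(b))
})

test_that("one-step single-value equals a plain pooled fit when complete", {
  sim <- simulate_portfolio(toy_sim_config(n = 1500, seed = 13))
  tab <- assign_folds(sim$table, 0.8, seed = 2)
  train <- tab[tab$fold == "train", ]
  test <- tab[tab$fold == "test", ]
  spec <- fast_spec(n_trees = 30, seed = 7)
  r1 <- one_step_single_value(train, test, sim$schema, spec)
  r2 <- one_step_single_value(train, test, sim$schema, spec)
  expect_identical(r1$test, r2$test)
  expect_true(all(r1$test > 0))
  # pooled model predicts both countries with a single prediction function
  expect_length(r1$test, nrow(test))
})

test_that("sentinel fill covers a country's fully-missing feature block", {
  cfg <- toy_sim_config(n = 800, seed = 17)
  cfg$countries[[2]]$available <- character(0) # B collects no local feature
  sim <- simulate_portfolio(cfg)
  tab <- assign_folds(sim$table, 0.8, seed = 2)
  train <- tab[tab$fold == "train", ]
  filled <- impute_sentinels(train, sim$schema)
  expect_true(all(filled$grp[filled$country == "B"] == "Missing"))
  r <- one_step_single_value(train, tab[tab$fold == "test", ], sim$schema,
                             fast_spec(n_trees = 20, seed = 3))
  expect_true(all(is.finite(r$test)))
})

test_that("MICE pooling averages the per-completion predictions", {
  cfg <- toy_sim_config(n = 1200, seed = 19)
  cfg$countries[[1]]$missingness <- c(grp = 0.3)
  cfg$countries[[2]]$missingness <- c(grp = 0.4)
  sim <- simulate_portfolio(cfg)
  tab <- assign_folds(sim$table, 0.8, seed = 5)
  train <- tab[tab$fold == "train", ]
  test <- tab[tab$fold == "test", ]
  r <- one_step_mice(train, test, sim$schema, fast_spec(n_trees = 20, seed = 2),
                     mice_config(n_bootstrap = 4, seed = 8))
  expect_equal(r$n_models, 4)
  expect_length(r$test, nrow(test))
  expect_true(all(r$test > 0))
  # determinism end to end
  r2 <- one_step_mice(train, test, sim$schema,
                      fast_spec(n_trees = 20, seed = 2),
                      mice_config(n_bootstrap = 4, seed = 8))
  expect_identical(r$test, r2$test)
})
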