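test_that("intercept-only fit returns the portfolio rate exactly", {
  set.seed(1)
  n <- 200
  X <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "x"))
  D <- rpois(n, 2)
  E <- runif(n, 5, 50)
  m <- fit_rate(learner_spec(n_trees = 0), X, D, E)
  expect_equal(predict_rate(m, X), rep(sum(D) / sum(E), n),
               tolerance = 1e-12)
})

test_that("zero-tree learner with an initial score passes it through", {
  X <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_rate(learner_spec(n_trees = 0), X, rep(1, 10), rep(10, 10),
                init_log_rate = rep(log(0.05), 10))
  expect_equal(m$b0, 0) # b0 constrained to 0 when an init is given
  expect_equal(predict_rate(m, X, init_log_rate = rep(log(0.05), 10)),
               rep(0.05, 10), tolerance = 1e-12)
})

test_that("per-category fitted rates match an independent Poisson GLM", {
  set.seed(7)
  n <- 3000
  cat <- sample(c("a", "b", "c"), n, replace = TRUE)
  E <- runif(n, 50, 150)
  true_rate <- c(a = 0.01, b = 0.03, c = 0.07)[cat]
  D <- rpois(n, true_rate * E)
  # offset GLM oracle, independent of the boosting backend
  glm_fit <- stats::glm(D ~ cat + offset(log(E)), family = stats::poisson())
  glm_rate <- exp(stats::predict(glm_fit,
                                 newdata = data.frame(cat = c("a", "b", "c"),
                                                      E = 1)))
  # boosted fit on a numeric encoding of the category
  X <- matrix(c(a = 1, b = 2, c = 3)[cat], ncol = 1,
              dimnames = list(NULL, "cat"))
  spec <- learner_spec(n_trees = 400, learning_rate = 0.5, max_leaves = 8,
                       min_exposure_per_leaf = 0, min_deaths_per_leaf = 0,
                       reg_lambda = 0, seed = 1)
  m <- fit_rate(spec, X, D, E)
  boosted <- predict_rate(m, matrix(1:3, ncol = 1,
                                    dimnames = list(NULL, "cat")))
  expect_equal(unname(boosted), unname(glm_rate), tolerance = 1e-4)
})

test_that("a binary split with strong signal recovers the group MLEs", {
  set.seed(3)
  n <- 4000
  g <- rep(0:1, each = n / 2)
  E <- runif(n, 100, 300)
  D <- rpois(n, ifelse(g == 1, 0.03, 0.01) * E)
  mle <- c(sum(D[g == 0]) / sum(E[g == 0]), sum(D[g == 1]) / sum(E[g == 1]))
  X <- matrix(g, ncol = 1, dimnames = list(NULL, "g"))
  m <- fit_rate(fast_spec(n_trees = 200, seed = 2), X, D, E)
  pred <- predict_rate(m, matrix(0:1, ncol = 1, dimnames = list(NULL, "g")))
  expect_lt(abs(pred[1] / mle[1] - 1), 0.05)
  expect_lt(abs(pred[2] / mle[2] - 1), 0.05)
})

test_that("fitting is deterministic and predictions strictly positive", {
  set.seed(5)
  n <- 1000
  X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  D <- rpois(n, 1)
  E <- runif(n, 1, 10)
  m1 <- fit_rate(fast_spec(seed = 9), X, D, E)
  m2 <- fit_rate(fast_spec(seed = 9), X, D, E)
  Xn <- matrix(rnorm(2e5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  p1 <- predict_rate(m1, Xn)
  expect_identical(p1, predict_rate(m2, Xn))
  expect_true(all(p1 > 0))
  # Poisson balance on training data
  expect_lt(abs(sum(predict_rate(m1, X) * E) / sum(D) - 1), 0.01)
})

test_that("learner guards: negative deaths, zero deaths, missing columns", {
  X <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fit_rate(fast_spec(), X, c(-1, rep(0, 9)), rep(1, 10)),
               "negative")
  expect_error(fit_rate(fast_spec(), X, rep(0, 10), rep(0, 10)), "positive")
  expect_warning(m0 <- fit_rate(fast_spec(), X, rep(0, 10), rep(1, 10)),
                 "zero")
  expect_true(all(predict_rate(m0, X) > 0)) # floored, never log(0)
  m <- fit_rate(learner_spec(n_trees = 0), X, rep(1, 10), rep(1, 10))
  bad <- matrix(1:10, ncol = 1, dimnames = list(NULL, "y"))
  expect_error(predict_rate(m, bad), "missing from X")
})

test_that("poisson_loglik and rmse match hand-computed values", {
  expect_equal(poisson_loglik(1, 1), -1)
  expect_equal(poisson_loglik(0, 1), -1)
  expect_equal(poisson_loglik(c(2, 3), c(2, 3)),
               2 * log(2) - 2 + 3 * log(3) - 3)
  expect_error(poisson_loglik(1, 0), "positive")
  expect_error(poisson_loglik(c(1, 2), 1), "aligned")
  expect_equal(rmse(c(1, 0), c(0, 0)), sqrt(0.5))
  expect_equal(rmse(c(2, 5, 1), c(2, 5, 1)), 0)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("constant-prediction log-likelihood peaks at the mean", {
  D <- c(0, 1, 1, 2, 5, 3)
  grid <- seq(0.1, 6, by = 0.01)
  ll <- vapply(grid, function(c) poisson_loglik(D, rep(c, length(D))),
               numeric(1))
  expect_equal(grid[which.max(ll)], mean(D), tolerance = 0.01)
})

test_that("actual-over-expected ratios aggregate correctly", {
  out <- ae_by_group(c(4, 6), c(4, 4), c("g", "g"))
  expect_equal(unname(out$by_group["g"]), 1.25)
  expect_equal(out$overall, 1.25)
  # identity predictions give ratio 1 everywhere
  D <- c(1, 2, 3, 4)
  out <- ae_by_group(D, D, c("a", "a", "b", "b"))
  expect_true(all(out$by_group == 1))
  expect_equal(out$overall, 1)
  # equal expected in two groups with ratios 0.9 / 1.1 averages to 1.0
  out <- ae_by_group(c(9, 11), c(10, 10), c("a", "b"))
  expect_equal(out$overall, 1)
  # zero expected deaths is undefined, not infinite
  out <- ae_by_group(c(1, 0), c(1, 0), c("a", "b"))
  expect_true(is.na(out$by_group["b"]))
})
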