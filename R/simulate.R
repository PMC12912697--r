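#' Configure a synthetic multi-country insured-portfolio simulation
#'
#' The simulator draws aggregated experience records (one record per unique
#' feature combination) for a set of countries. Each record gets a true
#' mortality rate built from a Gompertz age baseline, multiplicative global
#' feature effects shared by all countries, and multiplicative local effects
#' (country level, local feature effects, and optionally one pairwise
#' interaction per country). Exposure per record is log-normal around the
#' country's scale, deaths are Poisson with mean rate x exposure, and local
#' features are masked to missing completely at random at configured
#' per-country fractions (with full masking for features a country does not
#' collect at all).
#'
#' @param countries list of per-country settings; each element is a list with
#'   `id` (label), `n_groups` (record count, >= 1), `exposure_scale` (mean
#'   life-years per record, > 0), optional `exposure_sdlog` (default 1),
#'   `log_level` (country log-rate deviation, default 0), `year_range`
#'   (length-2 integer vector, default `c(2016, 2020)`), `local_effects`
#'   (named list: for a categorical feature a named log-rate-ratio vector
#'   keyed by base level, for a metric feature `list(slope =, center =)`),
#'   `interaction` (optional `list(cat =, level =, metric =, slope =,
#'   center =)`), `available` (character vector of local features collected
#'   in this country; default all), and `missingness` (named fractions in
#'   `[0, 1]` for partially collected local features, default none).
#' @param global_effects list with `gompertz_a`, `gompertz_b` (baseline
#'   hazard `a * exp(b * age)`), `gender_log_rr` (log rate ratio male vs
#'   female), and `extra` (named list of effects for other global features,
#'   same encoding as `local_effects`).
#' @param generators named list of feature value generators, one per feature:
#'   `list(kind = "categorical", scope =, levels =, probs =, per_country =
#'   FALSE)` or `list(kind = "metric", scope =, min =, max =, integer =
#'   FALSE)`. The special generator `list(kind = "year", scope = "global")`
#'   draws integer years uniformly from the country's `year_range`.
#'   Categorical generators with `per_country = TRUE` store country-qualified
#'   values (`"<country>:<level>"`), mimicking local codes such as regions
#'   that are not comparable across countries; effects are keyed by the base
#'   level.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return an object of class `simulation_config`.
#' @seealso [simulate_portfolio()], [default_study_config()]
#' @export
simulation_config <- function(countries, global_effects = list(),
                              generators = NULL, seed = 1) {
  stopifnot(is.list(countries), length(countries) >= 1L)
  ge <- utils::modifyList(
    list(gompertz_a = 2e-5, gompertz_b = 0.09, gender_log_rr = 0.45,
         extra = list()),
    global_effects)
  if (ge$gompertz_a <= 0 || ge$gompertz_b <= 0) {
    stop("Gompertz baseline parameters must be positive")
  }
  if (is.null(generators)) {
    generators <- list(
      age    = list(kind = "metric", scope = "global", min = 25, max = 70),
      gender = list(kind = "categorical", scope = "global",
                    levels = c("F", "M"), probs = c(0.4, 0.6))
    )
  }
  countries <- lapply(countries, function(cc) {
    cc <- utils::modifyList(
      list(exposure_sdlog = 1, log_level = 0, year_range = c(2016L, 2020L),
           local_effects = list(), interaction = NULL,
           available = NULL, missingness = numeric()),
      cc)
    if (is.null(cc$id)) stop("every country needs an 'id'")
    if (is.null(cc$n_groups) || cc$n_groups < 1) {
      stop("country '", cc$id, "': n_groups must be >= 1")
    }
    if (is.null(cc$exposure_scale) || cc$exposure_scale <= 0) {
      stop("country '", cc$id, "': exposure_scale must be > 0")
    }
    if (length(cc$missingness) &&
        (any(cc$missingness < 0) || any(cc$missingness > 1))) {
      stop("country '", cc$id, "': missingness fractions must lie in [0, 1]")
    }
    cc
  })
  structure(list(countries = countries, global_effects = ge,
                 generators = generators, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", length(x$countries), "countries,",
      length(x$generators), "features, seed", x$seed, "\n")
  for (cc in x$countries) {
    cat(sprintf("  %-4s n_groups=%-8d exposure_scale=%-7.3f log_level=%+.2f\n",
                cc$id, as.integer(cc$n_groups), cc$exposure_scale,
                cc$log_level))
  }
  invisible(x)
}

#' Feature schema implied by a simulation config
#'
#' @param config a [simulation_config()].
#' @return the [feature_schema()] describing the simulated features,
#'   including per-country availability of local features.
#' @export
simulation_schema <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- vapply(config$countries, `[[`, "", "id")
  feature_schema(lapply(names(config$generators), function(nm) {
    g <- config$generators[[nm]]
    kind <- if (g$kind == "metric" || g$kind == "year") "metric"
            else "categorical"
    spec <- list(name = nm, kind = kind, scope = g$scope)
    if (g$scope == "local") {
      avail <- ids[vapply(config$countries, function(cc) {
        is.null(cc$available) || nm %in% cc$available
      }, logical(1))]
      if (length(avail) < length(ids)) spec$available_in <- avail
    }
    spec
  }))
}

# draw raw feature values for one country (no masking)
draw_features <- function(config, cc, n) {
  out <- list()
  for (nm in names(config$generators)) {
    g <- config$generators[[nm]]
    out[[nm]] <- switch(
      g$kind,
      year = sample(seq(cc$year_range[1], cc$year_range[2]), n, replace = TRUE),
      metric = {
        v <- stats::runif(n, g$min, g$max)
        if (isTRUE(g$integer)) round(v) else v
      },
      categorical = sample(g$levels, n, replace = TRUE,
                           prob = g$probs %||% NULL),
      stop("unknown generator kind: ", g$kind))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# log-rate contribution of one effect spec given raw (unqualified) values
eval_effect <- function(effect, values) {
  if (is.numeric(effect) && !is.null(names(effect))) {
    v <- effect[as.character(values)]
    v[is.na(v)] <- 0
    unname(v)
  } else if (is.list(effect)) {
    (as.numeric(values) - (effect$center %||% 0)) * effect$slope
  } else {
    stop("effect must be a named numeric vector or list(slope=, center=)")
  }
}

#' Simulate a multi-country portfolio with known ground truth
#'
#' @param config a [simulation_config()].
#' @return a list with `table` (the portfolio data frame, local features
#'   masked per config), `truth` (data frame with the per-record true rate
#'   `mu_true` and its decomposition `log_global` + `log_local`, which the
#'   masking never touches), and `schema` (the implied [feature_schema()]).
#' @export
simulate_portfolio <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gens <- config$generators
  ge <- config$global_effects
  with_seed(config$seed, {
    tabs <- list(); truths <- list()
    for (cc in config$countries) {
      n <- as.integer(cc$n_groups)
      feats <- draw_features(config, cc, n)
      # global log-rate component: Gompertz baseline + shared feature effects
      lg <- log(ge$gompertz_a) + ge$gompertz_b * feats$age
      if ("gender" %in% names(feats)) {
        lg <- lg + ifelse(feats$gender == "M", ge$gender_log_rr, 0)
      }
      for (nm in names(ge$extra)) {
        lg <- lg + eval_effect(ge$extra[[nm]], feats[[nm]])
      }
      # local log-rate component: country level + local effects + interaction
      ll <- rep(cc$log_level, n)
      for (nm in names(cc$local_effects)) {
        ll <- ll + eval_effect(cc$local_effects[[nm]], feats[[nm]])
      }
      if (!is.null(cc$interaction)) {
        ia <- cc$interaction
        hit <- feats[[ia$cat]] == ia$level
        ll <- ll + hit * (as.numeric(feats[[ia$metric]]) -
                            (ia$center %||% 0)) * ia$slope
      }
      mu <- exp(lg + ll)
      E <- stats::rlnorm(n, log(cc$exposure_scale) - cc$exposure_sdlog^2 / 2,
                         cc$exposure_sdlog)
      if (any(mu * E > 1e9)) {
        stop("config error: mu_true * exposure exceeds 1e9; ",
             "check effect sizes and exposure scale")
      }
      D <- stats::rpois(n, mu * E)
      # country-qualified storage for non-comparable local codes
      for (nm in names(gens)) {
        g <- gens[[nm]]
        if (identical(g$kind, "categorical") && isTRUE(g$per_country)) {
          feats[[nm]] <- paste(cc$id, feats[[nm]], sep = ":")
        }
      }
      # masking: features a country does not collect are fully missing;
      # partially collected ones are masked MCAR at the configured fraction
      for (nm in names(gens)) {
        if (gens[[nm]]$scope != "local") next
        if (!is.null(cc$available) && !(nm %in% cc$available)) {
          feats[[nm]][] <- NA
        } else {
          fr <- if (nm %in% names(cc$missingness)) cc$missingness[[nm]] else 0
          if (fr > 0) feats[[nm]][stats::runif(n) < fr] <- NA
        }
      }
      tabs[[length(tabs) + 1L]] <- cbind(
        data.frame(country = rep(as.character(cc$id), n),
                   stringsAsFactors = FALSE),
        feats,
        data.frame(deaths = D, exposure = E))
      truths[[length(truths) + 1L]] <- data.frame(
        country = rep(as.character(cc$id), n),
        mu_true = mu, log_global = lg, log_local = ll)
    }
    table <- do.call(rbind, tabs)
    truth <- do.call(rbind, truths)
    rownames(table) <- rownames(truth) <- NULL
    list(table = table, truth = truth, schema = simulation_schema(config))
  })
}

#' Poisson log-likelihood of the generating model
#'
#' Evaluates the Poisson log-likelihood `sum(D * log(mu_true * E) -
#' mu_true * E)` at the simulator's true rates. Out of sample, no fitted
#' model should beat this anchor by a large margin.
#'
#' @param truth ground-truth data frame from [simulate_portfolio()].
#' @param table the matching portfolio data frame (same record order).
#' @return a single number (larger is better).
#' @export
true_loglik_bound <- function(truth, table) {
  if (nrow(truth) != nrow(table)) {
    stop("truth and table must have the same number of records")
  }
  mu_e <- truth$mu_true * table$exposure
  sum(table$deaths * log(mu_e) - mu_e)
}

# Table-1-shaped study template constants: per-country group counts,
# exposures (life-years), year ranges of the published multi-country
# portfolio, used as relative shapes by default_study_config().
study_shape <- function() {
  list(
    n_groups = c(1880792, 2190943, 1868691, 1572539,
                 4825792, 3852306, 207951, 290290),
    exposure = c(1295299, 1686299, 815795, 1347150,
                 1825901, 1548157, 498560, 99473),
    years = list(c(2013, 2020), c(2010, 2020), c(2010, 2020), c(2017, 2020),
                 c(2016, 2020), c(2016, 2020), c(2017, 2020), c(2015, 2020))
  )
}

#' Default eight-country study configuration
#'
#' Builds a simulation config whose eight countries follow the relative group
#' counts, per-record exposures, and observation-year ranges of a realistic
#' multi-country insured portfolio, scaled down by `scale` (group counts are
#' `round(scale * N_j)`; per-record exposure levels are unaffected by
#' `scale`). Two countries (7 and 8) are data-scarce. Countries differ in
#' overall mortality level and in the direction and strength of their local
#' feature effects, and two countries carry a pairwise age interaction, so
#' the global model is misspecified exactly where local models should help.
#' Local categorical codes are country-qualified (not comparable across
#' countries), and blockwise missingness mimics structural availability
#' differences, including one feature a country does not collect at all.
#'
#' @param scale positive scale factor, at most 1. `scale = 0.01` yields
#'   roughly 167,000 records in total.
#' @param seed integer seed stored in the config.
#' @return a [simulation_config()].
#' @export
default_study_config <- function(scale = 0.01, seed = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0 || scale > 1) {
    stop("scale must lie in (0, 1]")
  }
  shp <- study_shape()
  n <- round(scale * shp$n_groups)
  if (any(n < 1)) {
    stop("scale ", scale, " leaves at least one country with 0 groups; ",
         "use a larger scale")
  }
  exposure_scale <- shp$exposure / shp$n_groups

  # base local effect maps; per-country multipliers flip and rescale them so
  # local structure genuinely differs across countries
  base_local <- list(
    region     = c(r1 = -0.20, r2 = -0.05, r3 = 0.10, r4 = 0.20),
    occupation = c(o1 = -0.15, o2 = 0.05, o3 = 0.25),
    uw_type    = c(full = -0.10, simplified = 0.10),
    loading    = list(slope = 0.30, center = 0.5),
    smoker_share = list(slope = 0.50, center = 0.3),
    product_detail = c(p1 = -0.10, p2 = 0.00, p3 = 0.12)
  )
  mult <- c(1.0, -1.0, 0.6, 1.4, -0.8, 1.2, 1.8, -1.2)
  log_level <- c(0.10, -0.15, -0.30, 0.20, 0.00, 0.15, 0.40, -0.25)
  scale_local <- function(m) {
    lapply(base_local, function(eff) {
      if (is.list(eff)) list(slope = eff$slope * m, center = eff$center)
      else eff * m
    })
  }
  availability <- list(
    `1` = NULL, `2` = NULL, `3` = NULL, `4` = NULL,
    `5` = c("region", "occupation", "uw_type", "loading", "smoker_share"),
    `6` = NULL, `7` = NULL, `8` = NULL)
  missingness <- list(
    `1` = c(loading = 0.72, region = 0.33),
    `2` = c(occupation = 0.48, smoker_share = 0.48),
    `3` = c(uw_type = 0.33, region = 0.05),
    `4` = c(region = 0.28, product_detail = 0.28),
    `5` = c(region = 0.72),
    `6` = c(occupation = 0.62, region = 0.58, loading = 0.62),
    `7` = c(region = 0.08, occupation = 0.08, uw_type = 0.08,
            loading = 0.08, smoker_share = 0.08, product_detail = 0.08),
    `8` = c(region = 0.06, occupation = 0.06, uw_type = 0.06,
            loading = 0.06, smoker_share = 0.06, product_detail = 0.06))
  interactions <- list(
    `5` = list(cat = "region", level = "r4", metric = "age",
               slope = 0.006, center = 45),
    `7` = list(cat = "occupation", level = "o3", metric = "age",
               slope = 0.008, center = 45))

  countries <- lapply(1:8, function(j) {
    id <- as.character(j)
    list(id = id, n_groups = n[j], exposure_scale = exposure_scale[j],
         exposure_sdlog = 1, log_level = log_level[j],
         year_range = shp$years[[j]],
         local_effects = scale_local(mult[j]),
         interaction = interactions[[id]],
         available = availability[[id]],
         missingness = missingness[[id]])
  })

  generators <- list(
    age      = list(kind = "metric", scope = "global", min = 25, max = 70),
    gender   = list(kind = "categorical", scope = "global",
                    levels = c("F", "M"), probs = c(0.4, 0.6)),
    year     = list(kind = "year", scope = "global"),
    duration = list(kind = "metric", scope = "global", min = 0, max = 20),
    sum_band = list(kind = "categorical", scope = "global",
                    levels = c("A", "B", "C", "D", "E"),
                    probs = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    product  = list(kind = "categorical", scope = "global",
                    levels = c("term", "whole", "endow"),
                    probs = c(0.5, 0.3, 0.2)),
    channel  = list(kind = "categorical", scope = "global",
                    levels = c("broker", "agent", "banca", "direct"),
                    probs = c(0.35, 0.30, 0.20, 0.15)),
    premium_type = list(kind = "categorical", scope = "global",
                        levels = c("regular", "single"),
                        probs = c(0.8, 0.2)),
    frequency = list(kind = "categorical", scope = "global",
                     levels = c("monthly", "annual"), probs = c(0.7, 0.3)),
    region   = list(kind = "categorical", scope = "local",
                    levels = c("r1", "r2", "r3", "r4"), per_country = TRUE),
    occupation = list(kind = "categorical", scope = "local",
                      levels = c("o1", "o2", "o3"), per_country = TRUE),
    uw_type  = list(kind = "categorical", scope = "local",
                    levels = c("full", "simplified"), probs = c(0.6, 0.4)),
    loading  = list(kind = "metric", scope = "local", min = 0, max = 1),
    smoker_share = list(kind = "metric", scope = "local", min = 0, max = 1),
    product_detail = list(kind = "categorical", scope = "local",
                          levels = c("p1", "p2", "p3"), per_country = TRUE)
  )

  global_effects <- list(
    gompertz_a = 2e-5, gompertz_b = 0.09, gender_log_rr = 0.45,
    extra = list(
      year     = list(slope = -0.010, center = 2015),   # mortality improvement
      duration = list(slope = 0.015, center = 5),       # selection wearing off
      sum_band = c(A = 0.10, B = 0.05, C = 0.00, D = -0.05, E = -0.12),
      product  = c(term = 0.00, whole = 0.05, endow = -0.05),
      channel  = c(broker = 0.00, agent = 0.03, banca = -0.03, direct = 0.05),
      premium_type = c(regular = 0.00, single = 0.05)
      # 'frequency' carries no effect: a pure noise feature
    ))

  simulation_config(countries, global_effects, generators, seed = seed)
}
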