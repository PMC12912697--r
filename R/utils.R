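#' Derive a stage-specific sub-seed from a master seed
#'
#' Sub-seeds are keyed by stage name so that adding or removing a pipeline
#' stage never shifts the random stream of another stage. The derivation is a
#' simple polynomial rolling hash of the stage label folded into the master
#' seed, reduced modulo 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"simulate"`,
#'   `"global"`, `"local:5"`).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "global")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer((h + (abs(master) %% m) * 7919) %% m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Assign records to k folds. When the distinct (grouping) labels number at
# least k, whole groups are kept together (grouped CV): groups are placed on
# the currently lightest fold, largest first, with seeded tie-breaking.
# Otherwise plain record-level k-fold assignment is used.
make_folds <- function(groups, k, seed) {
  stopifnot(k >= 2)
  n <- length(groups)
  groups <- as.character(groups)
  tab <- table(groups)
  with_seed(seed, {
    if (length(tab) >= k) {
      # shuffle before ordering so equal-sized groups break ties randomly
      tab <- tab[sample(length(tab))]
      tab <- tab[order(-as.integer(tab))]
      load <- numeric(k)
      fold_of <- integer(length(tab))
      names(fold_of) <- names(tab)
      for (i in seq_along(tab)) {
        f <- which.min(load)
        fold_of[i] <- f
        load[f] <- load[f] + tab[i]
      }
      unname(fold_of[groups])
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
}

# country-year grouping label used for encoding and tuning folds; falls back
# to country alone when no year column is present
fold_group_labels <- function(table) {
  if ("year" %in% names(table)) {
    paste(table$country, table$year, sep = "\r")
  } else {
    as.character(table$country)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
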