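#' Framework run configuration
#'
#' Collects and validates every knob of the multiple-holdout framework. The
#' defaults mirror the reference scheme: 10 outer optimization/holdout splits
#' at 80/20, 50 inner training/validation splits within each optimization
#' set, 1000 permutations on the holdout, and a 0.05 significance level.
#'
#' @param model `"spls"` or `"kcca"`.
#' @param n_outer_splits Number of outer optimization/holdout splits.
#' @param holdout_fraction Fraction of samples held out per outer split, in (0,1).
#' @param n_inner_splits Number of inner training/validation splits per
#'   optimization set.
#' @param validation_fraction Fraction of each optimization set used for
#'   validation per inner split, in (0,1).
#' @param grid Hyperparameter grid: a list with elements `x` and `y`, each a
#'   numeric vector (SPLS: L1 budgets `c`; KCCA: `kappa` values); the grid is
#'   their outer product. `NULL` uses the model default — 10 logarithmically
#'   spaced budgets spanning `[1, sqrt(d)]` per view for SPLS, `kappa` in
#'   `0, 0.1, ..., 1` per view for KCCA.
#' @param n_permutations Number of holdout permutations per split (>= 50;
#'   1000 by default).
#' @param alpha Significance level in (0,1).
#' @param max_effects Maximum number of successive latent effects.
#' @param seed Master seed; all resampling and permutation randomness derives
#'   from it.
#' @param scale_features Scale features to unit training variance in addition
#'   to mean centering?
#' @param global_confound_removal Residualize confounds once on the full
#'   dataset before splitting (the simpler but leakage-prone variant) instead
#'   of refitting the confound model inside every split (default).
#' @param tol,max_iter SPLS convergence controls.
#' @return An object of class `holdout_config`.
#' @export
holdout_config <- function(model = c("spls", "kcca"),
                           n_outer_splits = 10L,
                           holdout_fraction = 0.2,
                           n_inner_splits = 50L,
                           validation_fraction = 0.2,
                           grid = NULL,
                           n_permutations = 1000L,
                           alpha = 0.05,
                           max_effects = 5L,
                           seed = 1L,
                           scale_features = FALSE,
                           global_confound_removal = FALSE,
                           tol = 1e-6,
                           max_iter = 500L) {
  model <- match.arg(model)
  check_count <- function(x, nm, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
      stop(sprintf("`%s` must be an integer >= %d", nm, min), call. = FALSE)
    }
    as.integer(x)
  }
  check_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
      stop(sprintf("`%s` must lie strictly between 0 and 1", nm), call. = FALSE)
    }
    x
  }
  cfg <- list(
    model = model,
    n_outer_splits = check_count(n_outer_splits, "n_outer_splits"),
    holdout_fraction = check_frac(holdout_fraction, "holdout_fraction"),
    n_inner_splits = check_count(n_inner_splits, "n_inner_splits"),
    validation_fraction = check_frac(validation_fraction, "validation_fraction"),
    grid = grid,
    n_permutations = check_count(n_permutations, "n_permutations", min = 50L),
    alpha = check_frac(alpha, "alpha"),
    max_effects = check_count(max_effects, "max_effects"),
    seed = check_count(seed, "seed", min = 0L),
    scale_features = isTRUE(scale_features),
    global_confound_removal = isTRUE(global_confound_removal),
    tol = tol,
    max_iter = check_count(max_iter, "max_iter")
  )
  if (!is.null(grid)) {
    if (!is.list(grid) || !all(c("x", "y") %in% names(grid))) {
      stop("`grid` must be a list with numeric elements `x` and `y`", call. = FALSE)
    }
    if (model == "kcca" && (any(grid$x < 0 | grid$x > 1) || any(grid$y < 0 | grid$y > 1))) {
      stop("KCCA grid values (kappa) must lie in [0, 1]", call. = FALSE)
    }
    if (model == "spls" && (any(grid$x < 1) || any(grid$y < 1))) {
      stop("SPLS grid values (L1 budgets) must be >= 1", call. = FALSE)
    }
  }
  structure(cfg, class = "holdout_config")
}

#' @export
print.holdout_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<holdout_config> model=%s | %d outer splits (holdout %.0f%%) | ",
      "%d inner splits (validation %.0f%%) | %d permutations | alpha=%.3g | ",
      "max %d effects | seed=%d\n"
    ),
    x$model, x$n_outer_splits, 100 * x$holdout_fraction,
    x$n_inner_splits, 100 * x$validation_fraction,
    x$n_permutations, x$alpha, x$max_effects, x$seed
  ))
  invisible(x)
}

#' Read a run configuration from JSON
#'
#' The JSON document mirrors the [holdout_config()] argument names exactly;
#' absent fields take their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `holdout_config`.
#' @export
read_holdout_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(holdout_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(raw$grid)) raw$grid <- lapply(raw$grid, as.numeric)
  do.call(holdout_config, raw)
}

# Default hyperparameter grids given the view dimensions.
default_grid <- function(model, p, q) {
  if (model == "spls") {
    list(
      x = exp(seq(log(1), log(sqrt(p)), length.out = 10L)),
      y = exp(seq(log(1), log(sqrt(q)), length.out = 10L))
    )
  } else {
    list(x = seq(0, 1, by = 0.1), y = seq(0, 1, by = 0.1))
  }
}

# Deterministic child seed derivation from the master seed; keeps every
# stream reproducible and independent of data values. Stays below 2^31.
child_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}
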