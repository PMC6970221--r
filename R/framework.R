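#' Build the nested resampling plan
#'
#' Draws `n_outer_splits` uniform random partitions of the samples into an
#' optimization set and a holdout set, and within each optimization set
#' `n_inner_splits` further partitions into training and validation sets.
#' Everything is reproducible from the configuration seed; the scheme never
#' looks at data values.
#'
#' @param n Number of samples (>= 10).
#' @param config A [holdout_config()].
#' @return An object of class `split_scheme`: `outer` (list of
#'   `list(optimization, holdout)` index vectors), `inner` (per outer split, a
#'   list of `list(training, validation)` index vectors into the full sample
#'   set), and `seed`.
#' @export
make_splits <- function(n, config) {
  stopifnot(inherits(config, "holdout_config"))
  if (n < 10L) stop("need at least 10 samples to build holdout splits", call. = FALSE)
  h <- round(config$holdout_fraction * n)
  n_opt <- n - h
  v <- round(config$validation_fraction * n_opt)
  if (h < 2L) stop("holdout size below 2; increase `holdout_fraction` or n", call. = FALSE)
  if (v < 2L) stop("validation size below 2; increase `validation_fraction` or n", call. = FALSE)
  if (n_opt - v < 3L) stop("inner training size below 3", call. = FALSE)

  scheme <- withr::with_seed(child_seed(config$seed, 1L), {
    lapply(seq_len(config$n_outer_splits), function(j) {
      hold <- sort(sample.int(n, h))
      opt <- setdiff(seq_len(n), hold)
      inner <- lapply(seq_len(config$n_inner_splits), function(i) {
        val <- sort(opt[sample.int(length(opt), v)])
        list(training = setdiff(opt, val), validation = val)
      })
      list(optimization = opt, holdout = hold, inner = inner)
    })
  })
  structure(
    list(
      outer = lapply(scheme, function(s) s[c("optimization", "holdout")]),
      inner = lapply(scheme, `[[`, "inner"),
      seed = config$seed
    ),
    class = "split_scheme"
  )
}

#' Out-of-sample correlation of a fitted effect
#'
#' Pearson correlation between the projections `x_new %*% u` and
#' `y_new %*% v` on rows not used in fitting — the framework's
#' generalizability measure. The value is signed (the fitted model's
#' train-positive sign convention applies), so poor generalization can show
#' up as a negative correlation.
#'
#' @param model An `effect_model`.
#' @param x_new,y_new Held-out matrices already preprocessed with
#'   training-fitted confound/centering models.
#' @return A correlation in `[-1, 1]`; 0 with a warning if either score
#'   vector has zero variance.
#' @export
out_of_sample_correlation <- function(model, x_new, y_new) {
  sx <- compute_scores(x_new, model$u)
  sy <- compute_scores(y_new, model$v)
  if (stats::sd(sx) == 0 || stats::sd(sy) == 0) {
    warning("degenerate holdout: a score vector has zero variance; returning 0")
    return(0)
  }
  stats::cor(sx, sy)
}

#' Chance-corrected support overlap (sparse-weight stability)
#'
#' Averages, over all unordered pairs of support sets (indices of nonzero
#' weights from models fitted on different data subsets), the corrected
#' overlap `(|A∩B| - |A||B|/d) / (min(|A|,|B|) - |A||B|/d)`, which is 1 when
#' all (proper, nonempty) supports coincide and has expectation 0 for random
#' supports. Pairs with a nonpositive denominator (empty or full supports)
#' contribute 0.
#'
#' @param supports List (length >= 2) of integer index vectors.
#' @param d Total number of features.
#' @return Mean corrected overlap.
#' @export
corrected_overlap <- function(supports, d) {
  if (length(supports) < 2L) stop("need at least 2 support sets", call. = FALSE)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  m <- length(supports)
  vals <- c()
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      a <- supports[[i]]
      b <- supports[[j]]
      expected <- length(a) * length(b) / d
      den <- min(length(a), length(b)) - expected
      vals <- c(vals, if (den <= 0) 0 else (length(intersect(a, b)) - expected) / den)
    }
  }
  mean(vals)
}

#' Mean absolute pairwise weight correlation (dense-weight stability)
#'
#' The stability measure for non-sparse (KCCA) weights: the average absolute
#' Pearson correlation between weight vectors fitted on different subsets,
#' sign-invariant by construction.
#'
#' @param weights List (length >= 2) of equal-length numeric vectors.
#' @return Mean absolute pairwise correlation; zero-variance vectors make
#'   their pairs contribute 0 with a warning.
#' @export
weight_correlation_stability <- function(weights) {
  if (length(weights) < 2L) stop("need at least 2 weight vectors", call. = FALSE)
  lens <- lengths(weights)
  if (length(unique(lens)) != 1L) stop("weight vectors must have equal length", call. = FALSE)
  m <- length(weights)
  sds <- vapply(weights, stats::sd, numeric(1))
  if (any(sds == 0)) warning("zero-variance weight vector(s); affected pairs contribute 0")
  vals <- c()
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      vals <- c(
        vals,
        if (sds[i] == 0 || sds[j] == 0) 0 else abs(stats::cor(weights[[i]], weights[[j]]))
      )
    }
  }
  mean(vals)
}

# Clamp SPLS budgets into the valid range for the view dimension, then fit
# one effect of the configured model family.
fit_one_effect <- function(x, y, hx, hy, config) {
  if (config$model == "spls") {
    spls_fit(
      x, y,
      c_u = min(max(hx, 1), sqrt(ncol(x))),
      c_v = min(max(hy, 1), sqrt(ncol(y))),
      tol = config$tol, max_iter = config$max_iter
    )
  } else {
    kcca_effect_fit(x, y, kappa_x = hx, kappa_y = hy)
  }
}

# Fit confound + centering models on training rows, apply to training and
# test rows, then apply accumulated projection deflations to both views.
prepare_pair <- function(x, y, conf, train_idx, test_idx, config,
                         deflate_u = list(), deflate_v = list()) {
  tr_x <- x[train_idx, , drop = FALSE]
  tr_y <- y[train_idx, , drop = FALSE]
  te_x <- x[test_idx, , drop = FALSE]
  te_y <- y[test_idx, , drop = FALSE]
  if (!is.null(conf)) {
    tr_c <- conf[train_idx, , drop = FALSE]
    te_c <- conf[test_idx, , drop = FALSE]
    cm_x <- fit_confound_model(tr_x, tr_c)
    cm_y <- fit_confound_model(tr_y, tr_c)
    tr_x <- apply_confound_model(tr_x, tr_c, cm_x)
    tr_y <- apply_confound_model(tr_y, tr_c, cm_y)
    te_x <- apply_confound_model(te_x, te_c, cm_x)
    te_y <- apply_confound_model(te_y, te_c, cm_y)
  }
  ct_x <- fit_centering(tr_x, scale = config$scale_features)
  ct_y <- fit_centering(tr_y, scale = config$scale_features)
  tr_x <- apply_centering(tr_x, ct_x)
  tr_y <- apply_centering(tr_y, ct_y)
  te_x <- apply_centering(te_x, ct_x)
  te_y <- apply_centering(te_y, ct_y)
  for (u in deflate_u) {
    tr_x <- deflate_view(tr_x, u)
    te_x <- deflate_view(te_x, u)
  }
  for (v in deflate_v) {
    tr_y <- deflate_view(tr_y, v)
    te_y <- deflate_view(te_y, v)
  }
  list(train_x = tr_x, train_y = tr_y, test_x = te_x, test_y = te_y)
}

#' Evaluate a hyperparameter grid on the inner splits
#'
#' For every hyperparameter combination, fits the model on each inner
#' training set (with confound removal and centering refitted on the inner
#' training rows — fully nested preprocessing) and records the mean signed
#' validation out-of-sample correlation together with the stability of the
#' fitted weights across the inner splits (chance-corrected support overlap
#' for SPLS, absolute weight correlation for KCCA; each averaged over the two
#' views). Degenerate fits are excluded from the averages; a cell with more
#' than 50% degenerate fits is marked invalid.
#'
#' @param x,y Full-sample view matrices (raw, unpreprocessed).
#' @param conf Confound matrix or `NULL`.
#' @param inner_splits List of `list(training, validation)` index pairs.
#' @param grid List with numeric vectors `x` and `y`; cells = outer product.
#' @param config A `holdout_config`.
#' @param deflate_u,deflate_v Accumulated deflation weights from previously
#'   extracted effects (fitted on this outer split's optimization set).
#' @return A tibble with one row per grid cell: `hx`, `hy`,
#'   `mean_validation_correlation`, `stability`, `n_degenerate`, `valid`.
#' @export
grid_search <- function(x, y, conf, inner_splits, grid, config,
                        deflate_u = list(), deflate_v = list()) {
  if (length(grid$x) < 1L || length(grid$y) < 1L) stop("empty hyperparameter grid", call. = FALSE)
  prepared <- lapply(inner_splits, function(sp) {
    prepare_pair(x, y, conf, sp$training, sp$validation, config, deflate_u, deflate_v)
  })
  cells <- expand.grid(hx = grid$x, hy = grid$y, KEEP.OUT.ATTRS = FALSE)
  n_inner <- length(prepared)
  p <- ncol(x)
  q <- ncol(y)

  res <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    hx <- cells$hx[ci]
    hy <- cells$hy[ci]
    fits <- lapply(prepared, function(pr) {
      tryCatch(
        suppressWarnings(fit_one_effect(pr$train_x, pr$train_y, hx, hy, config)),
        error = function(e) NULL
      )
    })
    ok <- !vapply(fits, is.null, logical(1))
    val_r <- rep(NA_real_, n_inner)
    for (i in which(ok)) {
      val_r[i] <- suppressWarnings(
        out_of_sample_correlation(fits[[i]], prepared[[i]]$test_x, prepared[[i]]$test_y)
      )
    }
    n_degenerate <- sum(!ok)
    valid <- n_degenerate <= n_inner / 2 && sum(ok) >= 2L
    stability <- NA_real_
    if (valid) {
      kept <- fits[ok]
      if (config$model == "spls") {
        stability <- mean(c(
          corrected_overlap(lapply(kept, function(m) which(m$u != 0)), p),
          corrected_overlap(lapply(kept, function(m) which(m$v != 0)), q)
        ))
      } else {
        stability <- mean(c(
          suppressWarnings(weight_correlation_stability(lapply(kept, `[[`, "u"))),
          suppressWarnings(weight_correlation_stability(lapply(kept, `[[`, "v")))
        ))
      }
    }
    tibble::tibble(
      hx = hx, hy = hy,
      mean_validation_correlation = mean(val_r, na.rm = TRUE),
      stability = stability,
      n_degenerate = n_degenerate,
      valid = valid
    )
  })
  res
}

#' Select hyperparameters by the joint stability + generalizability criterion
#'
#' Ranks valid grid cells by mean validation correlation (descending) and by
#' stability (descending) and selects the cell with the minimal rank sum.
#' Ties are broken by higher validation correlation, then by the more
#' regularized cell (smaller L1 budget for SPLS, larger kappa for KCCA).
#'
#' @param cells Tibble from [grid_search()].
#' @param model `"spls"` or `"kcca"` (decides the regularization direction of
#'   the final tie-break).
#' @return The selected row of `cells` (one-row tibble) with a `rank_sum`
#'   column added.
#' @export
select_hyperparams <- function(cells, model = c("spls", "kcca")) {
  model <- match.arg(model)
  valid <- cells[cells$valid & is.finite(cells$mean_validation_correlation), , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid grid cell; all fits degenerate", call. = FALSE)
  r_gen <- rank(-valid$mean_validation_correlation, ties.method = "average")
  r_stab <- rank(-valid$stability, ties.method = "average")
  valid$rank_sum <- r_gen + r_stab
  reg_key <- if (model == "spls") valid$hx + valid$hy else -(valid$hx + valid$hy)
  ord <- order(valid$rank_sum, -valid$mean_validation_correlation, reg_key)
  valid[ord[1L], , drop = FALSE]
}

#' Permutation test of the holdout correlation
#'
#' Builds the null distribution of the out-of-sample correlation by randomly
#' re-pairing the holdout rows of the y view (permuting one view is enough to
#' break the cross-view pairing) and compares the observed correlation
#' against it one-sidedly — coherent with the sign convention that makes the
#' training correlation nonnegative:
#' `p = (1 + #{r_perm >= r_obs}) / (n_permutations + 1)`.
#'
#' @param model An `effect_model`.
#' @param holdout_x,holdout_y Preprocessed holdout matrices (>= 5 rows).
#' @param n_permutations Number of permutations (>= 50).
#' @param seed Seed for the permutation stream.
#' @return A list with `r_observed`, `p_value`, and the `null` correlations.
#' @export
holdout_permutation_test <- function(model, holdout_x, holdout_y,
                                     n_permutations = 1000L, seed = 1L) {
  n <- nrow(holdout_x)
  if (n < 5L) stop("holdout too small for permutation testing (need >= 5 rows)", call. = FALSE)
  if (n_permutations < 50L) stop("`n_permutations` must be >= 50", call. = FALSE)
  sx <- compute_scores(holdout_x, model$u)
  sy <- compute_scores(holdout_y, model$v)
  degenerate <- stats::sd(sx) == 0 || stats::sd(sy) == 0
  r_obs <- if (degenerate) {
    warning("degenerate holdout: a score vector has zero variance")
    0
  } else {
    stats::cor(sx, sy)
  }
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      syp <- sy[sample.int(n)]
      if (degenerate || stats::sd(syp) == 0) 0 else stats::cor(sx, syp)
    }, numeric(1))
  })
  p <- (1 + sum(null >= r_obs)) / (n_permutations + 1)
  list(r_observed = r_obs, p_value = p, null = null)
}

#' Across-split significance decision
#'
#' An effect is declared significant when the smallest per-split holdout
#' p-value survives Bonferroni correction across the outer splits:
#' `min(p) < alpha / n_splits`. A laxer majority rule (`p < alpha` in more
#' than half of the splits) is available as an alternative.
#'
#' @param p_values Per-outer-split permutation p-values.
#' @param alpha Significance level.
#' @param rule `"bonferroni_min"` (default) or `"majority"`.
#' @return List with `significant` (logical) and `n_below_alpha`, the count
#'   of splits with `p < alpha`.
#' @export
decide_significance <- function(p_values, alpha = 0.05, rule = c("bonferroni_min", "majority")) {
  rule <- match.arg(rule)
  n_below <- sum(p_values < alpha)
  sig <- switch(rule,
    bonferroni_min = min(p_values) < alpha / length(p_values),
    majority = n_below > length(p_values) / 2
  )
  list(significant = sig, n_below_alpha = n_below)
}

#' Pick the split with the best generalizability + stability combination
#'
#' Ranks the outer splits by holdout correlation (descending) and by the
#' stability of the selected grid cell (descending); the minimal rank sum
#' wins, with ties broken by the higher holdout correlation. This is the
#' split whose model is reported as representative.
#'
#' @param holdout_correlations,stabilities Equal-length numeric vectors, one
#'   entry per outer split.
#' @return The 1-based index of the chosen split.
#' @export
choose_best_split <- function(holdout_correlations, stabilities) {
  stopifnot(length(holdout_correlations) == length(stabilities), length(holdout_correlations) >= 1L)
  r1 <- rank(-holdout_correlations, ties.method = "average")
  r2 <- rank(-stabilities, ties.method = "average")
  order(r1 + r2, -holdout_correlations)[1L]
}

#' Run the stability-optimized multiple-holdout framework
#'
#' The full procedure for successive latent effects: within each outer
#' optimization/holdout split, preprocessing (confound removal, centering) is
#' fitted on the optimization rows; hyperparameters are selected on the inner
#' training/validation splits by the joint stability + generalizability
#' criterion; the selected model is refitted on the whole optimization set
#' and evaluated on the untouched holdout by permutation testing. If the
#' effect is significant across splits, both views are deflated within every
#' split using that split's optimization-set weights (holdout rows deflated
#' with the same weights, preserving the leakage guarantee) and the next
#' effect is sought, up to `max_effects` or the first non-significant effect
#' (which is returned, flagged).
#'
#' @param data A [paired_views] object.
#' @param config A [holdout_config()].
#' @return An object of class `holdout_result`; see [tidy.holdout_result()]
#'   and [glance.holdout_result()] for tabular summaries.
#' @export
run_holdout <- function(data, config) {
  stopifnot(inherits(data, "paired_views"), inherits(config, "holdout_config"))
  x <- data$x
  y <- data$y
  conf <- data$confounds
  n <- nrow(x)
  if (n < 25L) warning("fewer than 25 samples; holdout estimates will be unstable")

  if (config$global_confound_removal && !is.null(conf)) {
    cm_x <- fit_confound_model(x, conf)
    cm_y <- fit_confound_model(y, conf)
    x <- apply_confound_model(x, conf, cm_x)
    y <- apply_confound_model(y, conf, cm_y)
    conf <- NULL
  }

  scheme <- make_splits(n, config)
  grid <- if (is.null(config$grid)) default_grid(config$model, ncol(x), ncol(y)) else config$grid

  n_outer <- config$n_outer_splits
  active <- seq_len(n_outer)
  defl_u <- rep(list(list()), n_outer)
  defl_v <- rep(list(list()), n_outer)
  effects <- list()

  for (k in seq_len(config$max_effects)) {
    split_out <- vector("list", n_outer)
    for (j in active) {
      opt <- scheme$outer[[j]]$optimization
      hold <- scheme$outer[[j]]$holdout
      out <- tryCatch({
        cells <- grid_search(
          x, y, conf, scheme$inner[[j]], grid, config,
          defl_u[[j]], defl_v[[j]]
        )
        sel <- select_hyperparams(cells, config$model)
        prep <- prepare_pair(x, y, conf, opt, hold, config, defl_u[[j]], defl_v[[j]])
        model <- fit_one_effect(prep$train_x, prep$train_y, sel$hx, sel$hy, config)
        perm <- holdout_permutation_test(
          model, prep$test_x, prep$test_y,
          n_permutations = config$n_permutations,
          seed = child_seed(config$seed, 2L, k, j)
        )
        list(
          model = model, holdout_correlation = perm$r_observed,
          p_value = perm$p_value, stability = sel$stability,
          hx = sel$hx, hy = sel$hy,
          scores = tibble::tibble(
            sample_id = rownames(prep$test_x),
            x_score = compute_scores(prep$test_x, model$u),
            y_score = compute_scores(prep$test_y, model$v)
          )
        )
      }, error = function(e) e)
      split_out[[j]] <- out
    }

    failed <- active[vapply(split_out[active], inherits, logical(1), "error")]
    if (length(failed)) {
      warning(sprintf(
        "effect %d: split(s) %s failed (%s) and were dropped",
        k, paste(failed, collapse = ", "),
        conditionMessage(split_out[[failed[1L]]])
      ))
      active <- setdiff(active, failed)
      if (length(active) < max(2L, ceiling(0.8 * n_outer))) {
        stop(sprintf("effect %d: too many failed splits (%d of %d remain); aborting",
          k, length(active), n_outer
        ), call. = FALSE)
      }
    }

    ok <- split_out[active]
    per_split <- tibble::tibble(
      split = active,
      holdout_correlation = vapply(ok, `[[`, numeric(1), "holdout_correlation"),
      p_value = vapply(ok, `[[`, numeric(1), "p_value"),
      stability = vapply(ok, `[[`, numeric(1), "stability"),
      hx = vapply(ok, `[[`, numeric(1), "hx"),
      hy = vapply(ok, `[[`, numeric(1), "hy")
    )
    verdict <- decide_significance(per_split$p_value, config$alpha)
    best <- choose_best_split(per_split$holdout_correlation, per_split$stability)

    effects[[k]] <- structure(
      list(
        effect_index = k,
        per_split = per_split,
        models = lapply(ok, `[[`, "model"),
        holdout_scores = lapply(ok, `[[`, "scores"),
        significant = verdict$significant,
        n_splits_below_alpha = verdict$n_below_alpha,
        best_split_index = best
      ),
      class = "effect_result"
    )

    if (!verdict$significant) break
    if (k == config$max_effects) break
    for (idx in seq_along(active)) {
      j <- active[idx]
      defl_u[[j]] <- c(defl_u[[j]], list(ok[[idx]]$model$u))
      defl_v[[j]] <- c(defl_v[[j]], list(ok[[idx]]$model$v))
    }
  }

  structure(
    list(
      effects = effects, config = config, scheme = scheme,
      n = n, p = ncol(x), q = ncol(y),
      feature_names = list(x = colnames(x), y = colnames(y))
    ),
    class = "holdout_result"
  )
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf(
    "<holdout_result> model=%s | n=%d, p=%d, q=%d | %d effect(s) examined, %d significant\n",
    x$config$model, x$n, x$p, x$q, length(x$effects),
    sum(vapply(x$effects, `[[`, logical(1), "significant"))
  ))
  for (ef in x$effects) {
    cat(sprintf(
      "  effect %d: %s | min p = %.4g | best split %d (holdout r = %.3f)\n",
      ef$effect_index,
      if (ef$significant) "significant" else "not significant",
      min(ef$per_split$p_value), ef$best_split_index,
      ef$per_split$holdout_correlation[ef$best_split_index]
    ))
  }
  invisible(x)
}
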