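#' Simulate paired views with known sparse cross-modality latent structure
#'
#' Generates two row-aligned views sharing `n_effects` sparse latent factors:
#' latent scores `z_k ~ N(0, 1)` enter both views through sparse unit weight
#' vectors, `X = sum_k s_k z_k u_k' + confound term + noise` (and analogously
#' for Y with `v_k`), emulating, e.g., paired brain and behavioral matrices
#' driven by a small number of shared dimensions. Supports of distinct
#' effects within a view are disjoint and nonzero weight magnitudes are equal
#' (signs random) unless `decaying_magnitudes` is set; effect strengths must
#' be strictly decreasing so the ordering is identifiable. Optional Gaussian
#' confounds load on every feature with strength `confound_strength`.
#'
#' @param n Number of samples.
#' @param p,q Feature counts of the x and y views.
#' @param n_effects Number of shared latent factors (0 gives pure noise).
#' @param support_fraction Fraction of each view's features carrying nonzero
#'   weight per effect (recycled across effects/views).
#' @param effect_strengths Strictly decreasing positive signal standard
#'   deviations, one per effect.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_confounds Number of Gaussian confound columns (0 for none).
#' @param confound_strength Standard deviation of the per-feature confound
#'   loadings (0 disables the confound term even if columns are generated).
#' @param latent_dist `"gaussian"` (default) or `"t"` for heavy-tailed
#'   latents (`df` degrees of freedom, scaled to unit variance).
#' @param df Degrees of freedom for `latent_dist = "t"` (> 2).
#' @param decaying_magnitudes Give the support entries geometrically decaying
#'   magnitudes instead of equal ones (stresses support recovery).
#' @param seed Seed; identical seeds give identical output.
#' @return A list of class `paired_simulation`: `data` (a [paired_views]) and
#'   `truth` with `true_u`, `true_v` (d x K matrices of unit columns),
#'   `true_latents` (n x K), and `confound_values`.
#' @export
simulate_paired_views <- function(n, p, q, n_effects = 1L,
                                  support_fraction = 0.1,
                                  effect_strengths = NULL,
                                  noise_sd = 1,
                                  n_confounds = 0L,
                                  confound_strength = 0,
                                  latent_dist = c("gaussian", "t"),
                                  df = 3,
                                  decaying_magnitudes = FALSE,
                                  seed = 1L) {
  latent_dist <- match.arg(latent_dist)
  stopifnot(n >= 3L, p >= 2L, q >= 2L, n_effects >= 0L, noise_sd > 0)
  if (is.null(effect_strengths)) {
    effect_strengths <- if (n_effects > 0) seq(n_effects + 1, 2, length.out = n_effects) else numeric(0)
  }
  if (length(effect_strengths) != n_effects) {
    stop("`effect_strengths` must have one entry per effect", call. = FALSE)
  }
  if (n_effects > 1 && any(diff(effect_strengths) >= 0)) {
    stop("`effect_strengths` must be strictly decreasing", call. = FALSE)
  }
  if (n_effects > 0 && any(effect_strengths <= 0)) {
    stop("`effect_strengths` must be positive", call. = FALSE)
  }
  support_fraction <- rep_len(support_fraction, n_effects)
  k_x <- pmax(1L, round(support_fraction * p))
  k_y <- pmax(1L, round(support_fraction * q))
  if (sum(k_x) > p || sum(k_y) > q) {
    stop("disjoint supports do not fit: support sizes exceed the feature count", call. = FALSE)
  }

  out <- withr::with_seed(as.integer(seed), {
    draw_latent <- function(n) {
      if (latent_dist == "gaussian") {
        stats::rnorm(n)
      } else {
        stats::rt(n, df = df) / sqrt(df / (df - 2))
      }
    }
    sparse_weights <- function(d, sizes) {
      w <- matrix(0, d, length(sizes))
      avail <- seq_len(d)
      for (k in seq_along(sizes)) {
        idx <- avail[sample.int(length(avail), sizes[k])]
        avail <- setdiff(avail, idx)
        mag <- if (decaying_magnitudes) 0.8^(seq_along(idx) - 1L) else rep(1, length(idx))
        w[idx, k] <- sample(c(-1, 1), sizes[k], replace = TRUE) * mag
        w[, k] <- w[, k] / sqrt(sum(w[, k]^2))
      }
      w
    }
    true_u <- sparse_weights(p, k_x)
    true_v <- sparse_weights(q, k_y)
    z <- matrix(vapply(seq_len(max(n_effects, 1L)), function(k) draw_latent(n), numeric(n)),
      nrow = n
    )
    if (n_effects == 0L) z <- z[, 0, drop = FALSE]

    x <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    y <- matrix(stats::rnorm(n * q, sd = noise_sd), n, q)
    for (k in seq_len(n_effects)) {
      x <- x + effect_strengths[k] * tcrossprod(z[, k], true_u[, k])
      y <- y + effect_strengths[k] * tcrossprod(z[, k], true_v[, k])
    }
    conf <- NULL
    if (n_confounds > 0L) {
      conf <- matrix(stats::rnorm(n * n_confounds), n, n_confounds)
      if (confound_strength > 0) {
        g_x <- matrix(stats::rnorm(n_confounds * p, sd = confound_strength), n_confounds, p)
        g_y <- matrix(stats::rnorm(n_confounds * q, sd = confound_strength), n_confounds, q)
        x <- x + conf %*% g_x
        y <- y + conf %*% g_y
      }
      dimnames(conf) <- list(paste0("s", seq_len(n)), paste0("conf", seq_len(n_confounds)))
    }
    dimnames(x) <- list(paste0("s", seq_len(n)), paste0("x", seq_len(p)))
    dimnames(y) <- list(paste0("s", seq_len(n)), paste0("y", seq_len(q)))
    list(x = x, y = y, conf = conf, true_u = true_u, true_v = true_v, z = z)
  })

  structure(
    list(
      data = paired_views(out$x, out$y, out$conf),
      truth = list(
        true_u = out$true_u, true_v = out$true_v,
        true_latents = out$z, confound_values = out$conf,
        effect_strengths = effect_strengths, noise_sd = noise_sd
      )
    ),
    class = "paired_simulation"
  )
}

#' Recovery metrics against simulated ground truth
#'
#' Sign-agnostic comparison of an estimated effect with a planted one:
#' per-view support F1 (estimated nonzeros vs true support), absolute cosine
#' between estimated and true weight vectors, and the absolute correlation of
#' the estimated latent scores with the true latent factor.
#'
#' @param model An `effect_model`.
#' @param truth The `truth` element of a [simulate_paired_views()] result.
#' @param effect_index Which planted effect to compare against (1-based).
#' @param data The [paired_views] the model was fitted on (used to compute
#'   scores); centered internally before projecting.
#' @return A tibble with one row per view: `view`, `support_f1`,
#'   `cosine_similarity`, `latent_score_correlation`.
#' @export
recovery_metrics <- function(model, truth, effect_index, data) {
  k_max <- ncol(truth$true_u)
  if (effect_index < 1L || effect_index > k_max) {
    stop(sprintf("`effect_index` must be in 1..%d", k_max), call. = FALSE)
  }
  f1 <- function(est, tru) {
    est_s <- which(est != 0)
    tru_s <- which(tru != 0)
    tp <- length(intersect(est_s, tru_s))
    if (length(est_s) == 0L || tp == 0L) return(0)
    prec <- tp / length(est_s)
    rec <- tp / length(tru_s)
    2 * prec * rec / (prec + rec)
  }
  abs_cos <- function(a, b) abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  z <- truth$true_latents[, effect_index]
  cx <- scale(data$x, center = TRUE, scale = FALSE)
  cy <- scale(data$y, center = TRUE, scale = FALSE)
  score_cor <- function(m, w) {
    s <- compute_scores(m, w)
    if (stats::sd(s) == 0) 0 else abs(stats::cor(s, z))
  }
  tibble::tibble(
    view = c("x", "y"),
    support_f1 = c(
      f1(model$u, truth$true_u[, effect_index]),
      f1(model$v, truth$true_v[, effect_index])
    ),
    cosine_similarity = c(
      abs_cos(model$u, truth$true_u[, effect_index]),
      abs_cos(model$v, truth$true_v[, effect_index])
    ),
    latent_score_correlation = c(score_cor(cx, model$u), score_cor(cy, model$v))
  )
}
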