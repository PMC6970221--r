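#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a holdout framework result
#'
#' One row per latent effect per outer split, with the holdout correlation,
#' permutation p-value, stability of the selected grid cell, the selected
#' hyperparameters, and whether the split is the reported best split.
#'
#' @param x A `holdout_result` from [run_holdout()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy holdout_result
#' @export
tidy.holdout_result <- function(x, ...) {
  hp_names <- if (x$config$model == "spls") c("c_u", "c_v") else c("kappa_x", "kappa_y")
  purrr::map_dfr(x$effects, function(ef) {
    out <- dplyr::mutate(
      ef$per_split,
      effect = ef$effect_index,
      significant = ef$significant,
      best_split = dplyr::row_number() == ef$best_split_index,
      .before = 1L
    )
    names(out)[names(out) == "hx"] <- hp_names[1L]
    names(out)[names(out) == "hy"] <- hp_names[2L]
    out
  })
}

#' One-row summary of a holdout framework result
#'
#' @param x A `holdout_result`.
#' @param ... Unused.
#' @return A one-row tibble: problem sizes, model family, number of effects
#'   examined and found significant, and the best split's holdout correlation
#'   and minimum p-value for the first effect.
#' @method glance holdout_result
#' @export
glance.holdout_result <- function(x, ...) {
  e1 <- x$effects[[1L]]
  tibble::tibble(
    model = x$config$model,
    n = x$n, p = x$p, q = x$q,
    n_effects_examined = length(x$effects),
    n_effects_significant = sum(vapply(x$effects, `[[`, logical(1), "significant")),
    effect1_min_p = min(e1$per_split$p_value),
    effect1_best_holdout_r = e1$per_split$holdout_correlation[e1$best_split_index]
  )
}

#' Tidy an effect model into a weight table
#'
#' @param x An `effect_model`.
#' @param ... Unused.
#' @return A tibble with `view`, `feature`, `weight` for every variable of
#'   both views.
#' @method tidy effect_model
#' @export
tidy.effect_model <- function(x, ...) {
  fx <- x$feature_names$x %||% paste0("x", seq_along(x$u))
  fy <- x$feature_names$y %||% paste0("y", seq_along(x$v))
  tibble::tibble(
    view = rep(c("x", "y"), c(length(x$u), length(x$v))),
    feature = c(fx, fy),
    weight = c(x$u, x$v)
  )
}

#' Plot a holdout framework result
#'
#' `type = "correlation"` shows the per-split holdout correlations by effect
#' (the best split highlighted); `type = "latent"` shows the holdout latent
#' space — x scores against y scores — of the best split of each effect.
#'
#' @param object A `holdout_result`.
#' @param type `"correlation"` or `"latent"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot holdout_result
#' @export
autoplot.holdout_result <- function(object, type = c("correlation", "latent"), ...) {
  type <- match.arg(type)
  if (type == "correlation") {
    td <- tidy(object)
    ggplot2::ggplot(td, ggplot2::aes(
      x = factor(.data$effect), y = .data$holdout_correlation
    )) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_jitter(
        ggplot2::aes(colour = .data$significant, size = .data$best_split),
        width = 0.08, height = 0, alpha = 0.8
      ) +
      ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4)) +
      ggplot2::labs(
        x = "latent effect", y = "holdout correlation",
        colour = "significant", size = "best split"
      ) +
      ggplot2::theme_minimal()
  } else {
    sc <- purrr::map_dfr(object$effects, function(ef) {
      dplyr::mutate(
        ef$holdout_scores[[ef$best_split_index]],
        effect = paste0("effect ", ef$effect_index)
      )
    })
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$x_score, y = .data$y_score)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
      ggplot2::facet_wrap(~effect, scales = "free") +
      ggplot2::labs(x = "x-view score", y = "y-view score") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data %||%
NULL
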