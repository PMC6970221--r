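#' Write result artifacts to a directory
#'
#' For every effect and outer split, writes per-view weight tables
#' (`effect{k}_split{j}_{x,y}_weights.csv`: feature_name, weight) and
#' holdout subject score tables (`effect{k}_split{j}_scores.csv`: sample_id,
#' x_score, y_score), plus one machine-readable `summary.json` holding, per
#' effect: per-split holdout correlation, p-value, stability and selected
#' hyperparameters, the significance verdict, and the best-split index.
#'
#' @param result A `holdout_result` from [run_holdout()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_effect_report <- function(result, out_dir) {
  stopifnot(inherits(result, "holdout_result"))
  if (length(result$effects) < 1L) stop("no effects to report", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory: %s", out_dir), call. = FALSE)

  files <- character(0)
  for (ef in result$effects) {
    k <- ef$effect_index
    for (i in seq_along(ef$models)) {
      j <- ef$per_split$split[i]
      m <- ef$models[[i]]
      if (all(m$u == 0) || all(m$v == 0)) {
        warning(sprintf("effect %d split %d: all-zero weight vector written", k, j))
      }
      wt <- tidy(m)
      for (vw in c("x", "y")) {
        f <- file.path(out_dir, sprintf("effect%d_split%d_%s_weights.csv", k, j, vw))
        utils::write.csv(
          data.frame(
            feature_name = wt$feature[wt$view == vw],
            weight = sprintf("%.17g", wt$weight[wt$view == vw])
          ),
          f,
          row.names = FALSE, quote = FALSE
        )
        files <- c(files, f)
      }
      f <- file.path(out_dir, sprintf("effect%d_split%d_scores.csv", k, j))
      sc <- ef$holdout_scores[[i]]
      utils::write.csv(
        data.frame(
          sample_id = sc$sample_id,
          x_score = sprintf("%.17g", sc$x_score),
          y_score = sprintf("%.17g", sc$y_score)
        ),
        f,
        row.names = FALSE, quote = FALSE
      )
      files <- c(files, f)
    }
  }

  summary <- list(
    model = result$config$model,
    n = result$n, p = result$p, q = result$q,
    effects = lapply(result$effects, function(ef) {
      list(
        effect_index = ef$effect_index,
        significant = ef$significant,
        n_splits_below_alpha = ef$n_splits_below_alpha,
        best_split_index = ef$best_split_index,
        per_split = ef$per_split
      )
    })
  )
  sf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sf)
  invisible(files)
}

#' Read back a written result summary
#'
#' Loads `summary.json` written by [write_effect_report()]; numeric fields
#' round-trip exactly.
#'
#' @param out_dir Directory holding a `summary.json`.
#' @return A list mirroring the written summary, with `per_split` tables as
#'   tibbles.
#' @export
read_effect_summary <- function(out_dir) {
  path <- file.path(out_dir, "summary.json")
  if (!file.exists(path)) stop(sprintf("no summary.json in %s", out_dir), call. = FALSE)
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$effects <- lapply(seq_len(nrow(s$effects)), function(i) {
    ef <- as.list(s$effects[i, setdiff(names(s$effects), "per_split")])
    ef$per_split <- tibble::as_tibble(s$effects$per_split[[i]])
    ef
  })
  s
}
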