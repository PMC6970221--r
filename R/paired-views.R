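#' Paired two-view dataset
#'
#' Bundles two row-aligned numeric views — `x` (samples x p features, e.g.
#' voxelwise gray-matter volumes) and `y` (samples x q features, e.g.
#' item-level behavioral variables) — together with an optional confound
#' matrix. Rows are matched by sample ID: the constructor takes the
#' intersection of the IDs, ordered as in `x`, and drops unmatched rows with
#' a message.
#'
#' @param x,y A numeric matrix with unique row names (sample IDs) and unique
#'   column names (feature names), or a data frame whose first column holds
#'   the sample IDs.
#' @param confounds Optional matrix/data frame of numeric confound columns
#'   (e.g. total intracranial volume, indicator-coded acquisition site) in the
#'   same format. Categorical confounds must be pre-encoded as indicators.
#' @return An object of class `paired_views`: a list with elements `x`, `y`
#'   (numeric matrices with dimnames) and `confounds` (matrix or `NULL`).
#' @examples
#' x <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), paste0("f", 1:3)))
#' y <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), paste0("g", 1:2)))
#' pv <- paired_views(x, y)
#' dim(pv$x)
#' @export
paired_views <- function(x, y, confounds = NULL) {
  x <- as_view_matrix(x, "x")
  y <- as_view_matrix(y, "y")
  confounds <- if (!is.null(confounds)) as_view_matrix(confounds, "confounds", min_features = 1L)

  ids_x <- rownames(x)
  ids_y <- rownames(y)
  shared <- intersect(ids_x, ids_y)
  if (!is.null(confounds)) shared <- intersect(shared, rownames(confounds))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared sample IDs across views; cannot align", call. = FALSE)
  }
  # order = x order
  shared <- ids_x[ids_x %in% shared]
  dropped <- (length(ids_x) - length(shared)) + (length(ids_y) - length(shared))
  if (dropped > 0L) {
    message(sprintf(
      "aligned %d shared samples; dropped %d x row(s) and %d y row(s) without a match",
      length(shared), length(ids_x) - length(shared), length(ids_y) - length(shared)
    ))
  }
  x <- x[shared, , drop = FALSE]
  y <- y[shared, , drop = FALSE]
  if (!is.null(confounds)) confounds <- confounds[shared, , drop = FALSE]

  if (ncol(x) < 2L || ncol(y) < 2L) {
    stop("each view needs at least 2 features", call. = FALSE)
  }
  structure(
    list(x = x, y = y, confounds = confounds),
    class = "paired_views"
  )
}

#' @export
print.paired_views <- function(x, ...) {
  cat(sprintf(
    "<paired_views> %d samples | x: %d features | y: %d features | confounds: %s\n",
    nrow(x$x), ncol(x$x), ncol(x$y),
    if (is.null(x$confounds)) "none" else ncol(x$confounds)
  ))
  invisible(x)
}

# Coerce a data frame (first column = sample ID) or matrix to a validated
# numeric matrix with unique dimnames and no non-finite entries.
as_view_matrix <- function(obj, what, min_features = 1L) {
  if (is.data.frame(obj)) {
    ids <- as.character(obj[[1L]])
    m <- as.matrix(obj[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else if (is.matrix(obj)) {
    m <- obj
    storage.mode(m) <- "double"
  } else {
    stop(sprintf("`%s` must be a matrix or data frame", what), call. = FALSE)
  }
  if (is.null(rownames(m))) {
    stop(sprintf("`%s` must carry sample IDs (row names / first column)", what), call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop(sprintf("`%s` must carry feature names (column names / header)", what), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("duplicate sample IDs in `%s`", what), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("duplicate feature names in `%s`", what), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite value in `%s` at row '%s', column '%s'; missing values are not supported",
      what, rownames(m)[bad[1L]], colnames(m)[bad[2L]]
    ), call. = FALSE)
  }
  if (nrow(m) < 3L) stop(sprintf("`%s` needs at least 3 samples", what), call. = FALSE)
  if (ncol(m) < min_features) {
    stop(sprintf("`%s` needs at least %d feature column(s)", what, min_features), call. = FALSE)
  }
  m
}

#' Read a paired two-view dataset from delimited text files
#'
#' Each file is delimited text with a header row of feature names and a
#' leading sample-ID column. Rows are aligned across files by sample ID
#' (intersection, ordered as in the x file); dropped rows are reported.
#'
#' @param x_path,y_path Paths to the two view files.
#' @param confound_path Optional path to a confound file in the same format.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A [paired_views] object.
#' @export
read_paired_views <- function(x_path, y_path, confound_path = NULL, delim = ",") {
  x <- read_view_file(x_path, delim)
  y <- read_view_file(y_path, delim)
  confounds <- if (!is.null(confound_path)) read_view_file(confound_path, delim)
  paired_views(x, y, confounds)
}

read_view_file <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(
    path, header = TRUE, sep = delim, check.names = FALSE,
    colClasses = "character", quote = "\"", na.strings = character(0)
  )
  if (ncol(df) < 2L) stop(sprintf("%s: expected a sample-ID column plus feature columns", path), call. = FALSE)
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body), dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !(trimws(body[[j]]) %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf(
        "%s: non-numeric value '%s' at row '%s', column '%s'",
        path, body[[j]][bad[1L]], ids[bad[1L]], colnames(body)[j]
      ), call. = FALSE)
    }
    m[, j] <- v
  }
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s: missing/non-finite value at row '%s', column '%s'",
      path, rownames(m)[bad[1L]], colnames(m)[bad[2L]]
    ), call. = FALSE)
  }
  m
}

#' Write a view matrix as delimited text
#'
#' Inverse of [read_view_file()]-style loading: a header of feature names and
#' a leading `sample_id` column; full-precision numeric formatting so a
#' write/read round trip preserves values exactly.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_view <- function(m, path, delim = ",") {
  fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(sample_id = rownames(m), fm, check.names = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
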