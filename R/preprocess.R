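#' Fit a confound-removal (residualization) model
#'
#' Regresses every feature column of a view on the confounds (with intercept)
#' by ordinary least squares, so that confound effects can later be removed
#' from both training and held-out rows without leaking held-out information.
#' Rank-deficient confound matrices are handled by the minimum-norm
#' least-squares solution.
#'
#' @param train_view Numeric matrix (training rows x features).
#' @param train_confounds Numeric matrix (training rows x confounds), row-aligned
#'   with `train_view`.
#' @return An object of class `confound_model` with elements `coefficients`
#'   (`(c+1) x d`, first row = intercepts) and `feature_names`.
#' @seealso [apply_confound_model()]
#' @export
fit_confound_model <- function(train_view, train_confounds) {
  stopifnot(is.matrix(train_view), is.matrix(train_confounds))
  if (nrow(train_view) != nrow(train_confounds)) {
    stop("view and confounds must have the same number of rows", call. = FALSE)
  }
  n <- nrow(train_view)
  cc <- ncol(train_confounds)
  if (n <= cc + 1L) {
    stop(sprintf(
      "need more than %d training samples to fit %d confound(s) plus intercept",
      cc + 1L, cc
    ), call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, train_confounds)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    # minimum-norm solution for collinear/degenerate confounds
    coefficients <- MASS::ginv(design) %*% train_view
  } else {
    coefficients <- qr.coef(qr_d, train_view)
  }
  dimnames(coefficients) <- list(colnames(design), colnames(train_view))
  structure(
    list(coefficients = coefficients, feature_names = colnames(train_view)),
    class = "confound_model"
  )
}

#' Remove fitted confound effects from a view
#'
#' Returns the residuals `view - [1, confounds] %*% coefficients` using a
#' model fitted (typically on training rows only) by [fit_confound_model()].
#' Feature and sample labels are preserved.
#'
#' @param view Numeric matrix (rows x features), same feature set as the model.
#' @param confounds Numeric matrix row-aligned with `view`.
#' @param model A `confound_model`.
#' @return Residualized matrix with the same dimnames as `view`.
#' @export
apply_confound_model <- function(view, confounds, model) {
  stopifnot(inherits(model, "confound_model"))
  if (!identical(colnames(view), model$feature_names)) {
    stop("feature names of `view` do not match the fitted confound model", call. = FALSE)
  }
  if (nrow(view) != nrow(confounds)) {
    stop("view and confounds must have the same number of rows", call. = FALSE)
  }
  res <- view - cbind(1, confounds) %*% model$coefficients
  dimnames(res) <- dimnames(view)
  res
}

#' Fit column centering (and optional unit-variance scaling)
#'
#' Means and, if `scale = TRUE`, standard deviations are computed on training
#' rows only, so that applying the model to held-out rows is leakage-free.
#' Constant training columns get scale 1 with a warning.
#'
#' @param train_view Numeric matrix of training rows.
#' @param scale Divide by the training standard deviation as well?
#' @return An object of class `centering_model` with `means` and `scales`.
#' @export
fit_centering <- function(train_view, scale = FALSE) {
  means <- colMeans(train_view)
  if (scale) {
    scales <- apply(train_view, 2L, stats::sd)
    zero <- scales <= 0 | !is.finite(scales)
    if (any(zero)) {
      warning(sprintf("%d constant training column(s); scale forced to 1", sum(zero)))
      scales[zero] <- 1
    }
  } else {
    scales <- rep(1, ncol(train_view))
  }
  names(scales) <- colnames(train_view)
  structure(list(means = means, scales = scales), class = "centering_model")
}

#' Apply a fitted centering model
#'
#' @param view Numeric matrix with the model's feature set.
#' @param model A `centering_model` from [fit_centering()].
#' @return Centered (and possibly scaled) matrix.
#' @export
apply_centering <- function(view, model) {
  stopifnot(inherits(model, "centering_model"))
  if (ncol(view) != length(model$means)) {
    stop("feature dimension does not match the fitted centering model", call. = FALSE)
  }
  sweep(sweep(view, 2L, model$means, "-"), 2L, model$scales, "/")
}
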