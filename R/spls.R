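#' Soft-thresholding (lasso) operator
#'
#' Elementwise `sign(a) * max(|a| - delta, 0)` — the proximal operator of the
#' L1 penalty that underpins the sparse PLS weight updates.
#'
#' @param a Numeric vector.
#' @param delta Nonnegative threshold.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
#' @export
soft_threshold <- function(a, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("`delta` must be a single nonnegative number", call. = FALSE)
  }
  if (!all(is.finite(a))) stop("`a` must be finite", call. = FALSE)
  sign(a) * pmax(abs(a) - delta, 0)
}

#' Project a vector onto the unit L2 sphere intersected with an L1 ball
#'
#' Returns `w = S(a, delta) / ||S(a, delta)||_2` with the smallest threshold
#' `delta >= 0` (found by bisection) such that `||w||_1 <= c`. When the
#' plainly normalized vector already satisfies the L1 budget, it is returned
#' unchanged (`delta = 0`). `c = 1` forces a single nonzero entry (ties broken
#' toward the lowest index); `c = sqrt(d)` imposes no sparsity.
#'
#' @param a Numeric vector, not all zero.
#' @param c L1 budget, at least 1. Budgets at or above `sqrt(length(a))` are
#'   inactive (the plainly normalized vector is always feasible there).
#' @param tol Bisection tolerance on `delta` (default `1e-12`), so the
#'   projection is exact enough to keep the alternating objective monotone.
#' @param max_iter Maximum bisection iterations (default 200).
#' @return Unit-L2-norm vector with `||w||_1 <= c` (up to tolerance).
#' @export
l1_constrained_unit <- function(a, c, tol = 1e-12, max_iter = 200L) {
  d <- length(a)
  if (!all(is.finite(a))) stop("`a` must be finite", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 1 - 1e-12) {
    stop("`c` must be a single number >= 1", call. = FALSE)
  }
  amax <- max(abs(a))
  if (amax == 0) stop("`a` is all zero; projection undefined", call. = FALSE)

  w0 <- a / sqrt(sum(a^2))
  if (sum(abs(w0)) <= c + 1e-12) return(w0)

  # bisection on the threshold, on magnitudes only (signs reattached at the end)
  aa <- abs(a)
  lo <- 0
  hi <- amax
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- aa - mid
    s <- s * (s > 0)
    ns2 <- sum(s * s)
    if (ns2 == 0 || sum(s) / sqrt(ns2) > c) lo <- mid else hi <- mid
    if (hi - lo < tol * max(amax, 1)) break
  }
  s <- aa - hi
  s <- s * (s > 0)
  ns <- sqrt(sum(s * s))
  if (ns > 0) {
    w <- sign(a) * s / ns
    if (sum(abs(w)) <= c + 1e-6) return(w)
  }
  # tied maxima can make every feasible w collapse at delta -> max|a|:
  # fall back to a one-hot at the lowest-index argmax
  w <- numeric(d)
  w[which.max(abs(a))] <- sign(a[which.max(abs(a))])
  w
}

#' Fit one sparse PLS effect
#'
#' Rank-one sparse partial least squares: alternating updates
#' `u <- l1_constrained_unit(X'Yv, c_u)`, `v <- l1_constrained_unit(Y'Xu, c_v)`
#' maximize the covariance `u'X'Yv` between the two views' score vectors
#' subject to unit L2 norm and per-view L1 budgets. With inactive budgets
#' (`c = sqrt(d)`) the solution is the leading singular-vector pair of `X'Y`,
#' which also serves as the deterministic initialization.
#'
#' @param x,y Column-centered numeric matrices with a shared sample dimension
#'   (n x p and n x q, n >= 3).
#' @param c_u,c_v Per-view L1 budgets, `c_u` in `[1, sqrt(p)]`, `c_v` in
#'   `[1, sqrt(q)]`.
#' @param tol Convergence tolerance on `max(||u - u_prev||, ||v - v_prev||)`.
#' @param max_iter Maximum alternating iterations.
#' @return An object of class `effect_model`: unit-norm weight vectors `u`,
#'   `v` (the sign convention makes the training score correlation
#'   nonnegative), `hyperparams`, `train_correlation`, `n_iterations`,
#'   `converged`, and the per-iteration `objective_trace` of `u'X'Yv`.
#' @export
spls_fit <- function(x, y, c_u, c_v, tol = 1e-6, max_iter = 500L) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  cxy <- crossprod(x, y)
  if (max(abs(cxy)) == 0) {
    stop("cross-covariance X'Y is exactly zero; no effect to fit", call. = FALSE)
  }
  v <- svd(cxy, nu = 0L, nv = 1L)$v[, 1L]
  u <- l1_constrained_unit(drop(cxy %*% v), c_u)

  converged <- FALSE
  trace <- numeric(0)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    u_prev <- u
    v_prev <- v
    u <- l1_constrained_unit(drop(cxy %*% v), c_u)
    v <- l1_constrained_unit(drop(crossprod(cxy, u)), c_v)
    trace <- c(trace, drop(crossprod(u, cxy %*% v)))
    if (max(sqrt(sum((u - u_prev)^2)), sqrt(sum((v - v_prev)^2))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("sparse PLS did not converge in %d iterations", max_iter))
  }

  sx <- drop(x %*% u)
  sy <- drop(y %*% v)
  r <- if (stats::sd(sx) > 0 && stats::sd(sy) > 0) stats::cor(sx, sy) else 0
  if (r < 0) {
    v <- -v
    r <- -r
  }
  new_effect_model(
    u = u, v = v, kind = "spls",
    hyperparams = list(c_u = c_u, c_v = c_v),
    train_correlation = r, n_iterations = iter, converged = converged,
    objective_trace = trace,
    feature_names = list(x = colnames(x), y = colnames(y))
  )
}

new_effect_model <- function(u, v, kind, hyperparams, train_correlation,
                             n_iterations, converged, objective_trace = numeric(0),
                             feature_names = NULL, dual = NULL) {
  structure(
    list(
      u = u, v = v, kind = kind, hyperparams = hyperparams,
      train_correlation = train_correlation, n_iterations = n_iterations,
      converged = converged, objective_trace = objective_trace,
      feature_names = feature_names, dual = dual
    ),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams), signif(unlist(x$hyperparams), 4),
    sep = "=", collapse = ", "
  )
  cat(sprintf(
    "<effect_model:%s> %s | train r = %.3f | support %d/%d (x), %d/%d (y)\n",
    x$kind, hp, x$train_correlation,
    sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v)
  ))
  invisible(x)
}

#' Project samples onto a weight vector
#'
#' Computes per-sample scores `X u` — the weighted sum of a view's variables
#' defining its coordinate in the latent space.
#'
#' @param x Numeric matrix (n x d).
#' @param u Weight vector of length d.
#' @return Numeric score vector of length n.
#' @export
compute_scores <- function(x, u) {
  if (ncol(x) != length(u)) stop("dimension mismatch between `x` and `u`", call. = FALSE)
  drop(x %*% u)
}

#' Remove an extracted effect by projection deflation
#'
#' Returns `X (I - u u')`, projecting every row onto the orthogonal
#' complement of the unit weight vector so that the deflated matrix satisfies
#' `X_defl %*% u = 0` and the next effect is sought in the remaining subspace.
#'
#' @param x Numeric matrix (n x d).
#' @param u Unit-L2-norm weight vector of length d.
#' @return Deflated matrix, same dimnames as `x`.
#' @export
deflate_view <- function(x, u) {
  if (ncol(x) != length(u)) stop("dimension mismatch between `x` and `u`", call. = FALSE)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-6) stop("`u` must have unit L2 norm", call. = FALSE)
  res <- x - (x %*% u) %*% t(u)
  dimnames(res) <- dimnames(x)
  res
}
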