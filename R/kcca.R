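#' Linear kernel (Gram) matrix
#'
#' `K = X X'` on column-centered data: the symmetric positive semidefinite
#' sample-by-sample inner-product matrix that lets CCA be solved in the dual,
#' which is efficient when features far outnumber samples.
#'
#' @param x Column-centered numeric matrix (n x d).
#' @return n x n symmetric kernel matrix.
#' @export
linear_kernel <- function(x) {
  tcrossprod(x)
}

#' Fit one regularized kernel CCA effect
#'
#' Maximizes the dual objective `alpha' K_x K_y beta` subject to the
#' regularized unit constraints
#' `(1 - kappa_x) alpha' K_x^2 alpha + kappa_x alpha' K_x alpha = 1` (and the
#' analogous constraint for the y view). The regularization parameters
#' interpolate smoothly between maximizing correlation (`kappa = 0`, the
#' classical CCA limit) and maximizing covariance (`kappa = 1`, the PLS
#' limit). The problem is solved as an SVD in the Cholesky-whitened basis of
#' the constraint matrices; a small jitter on the constraint diagonal ensures
#' solvability and is escalated tenfold (up to 3 times) on failure.
#'
#' @param k_x,k_y n x n symmetric kernel matrices built from centered data.
#' @param kappa_x,kappa_y Regularization parameters in `[0, 1]`.
#' @param jitter Positive ridge added to each constraint matrix; default
#'   `1e-9 * trace(K)/n` per view.
#' @return An object of class `dual_solution`: dual vectors `alpha`, `beta`
#'   (normalized so each regularized quadratic form equals 1, sign fixed so
#'   the largest-magnitude entry of `alpha` is positive) and the achieved
#'   objective `rho`.
#' @export
kcca_fit <- function(k_x, k_y, kappa_x, kappa_y, jitter = NULL) {
  n <- nrow(k_x)
  if (!isSymmetric(unname(k_x), tol = 1e-8) || !isSymmetric(unname(k_y), tol = 1e-8)) {
    stop("kernel matrices must be symmetric", call. = FALSE)
  }
  if (nrow(k_y) != n) stop("kernels must have the same dimension", call. = FALSE)
  if (kappa_x < 0 || kappa_x > 1 || kappa_y < 0 || kappa_y > 1) {
    stop("`kappa` parameters must lie in [0, 1]", call. = FALSE)
  }
  k_x <- (k_x + t(k_x)) / 2
  k_y <- (k_y + t(k_y)) / 2
  jit_x <- if (is.null(jitter)) max(1e-9 * sum(diag(k_x)) / n, 1e-12) else jitter
  jit_y <- if (is.null(jitter)) max(1e-9 * sum(diag(k_y)) / n, 1e-12) else jitter

  constraint <- function(k, kappa, jit) {
    (1 - kappa) * (k %*% k) + kappa * k + diag(jit, nrow(k))
  }

  for (attempt in 0:3) {
    esc <- 10^attempt
    nx <- constraint(k_x, kappa_x, jit_x * esc)
    ny <- constraint(k_y, kappa_y, jit_y * esc)
    ux <- tryCatch(chol(nx), error = function(e) NULL)
    uy <- tryCatch(chol(ny), error = function(e) NULL)
    if (!is.null(ux) && !is.null(uy)) break
    if (attempt == 3L) {
      stop("constraint matrices not positive definite even after jitter escalation", call. = FALSE)
    }
  }

  # whitened cross-operator: a' M b with a = U_x alpha, b = U_y beta
  m <- t(backsolve(uy, t(backsolve(ux, k_x %*% k_y, transpose = TRUE)), transpose = TRUE))
  sv <- svd(m, nu = 1L, nv = 1L)
  alpha <- backsolve(ux, sv$u[, 1L])
  beta <- backsolve(uy, sv$v[, 1L])
  rho <- sv$d[1L]
  if (alpha[which.max(abs(alpha))] < 0) {
    alpha <- -alpha
    beta <- -beta
  }
  structure(list(alpha = alpha, beta = beta, rho = rho), class = "dual_solution")
}

#' Recover primal weights from a dual solution
#'
#' For the linear kernel the per-feature weight vector corresponding to a
#' dual vector is `w = X' alpha`, returned with unit L2 norm so weights are
#' comparable across views and splits.
#'
#' @param x Numeric matrix (n x d) the kernel was built from.
#' @param alpha Dual vector of length n.
#' @return Unit-norm weight vector of length d.
#' @export
recover_primal_weights <- function(x, alpha) {
  if (nrow(x) != length(alpha)) stop("dimension mismatch between `x` and `alpha`", call. = FALSE)
  w <- drop(crossprod(x, alpha))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("`X' alpha` is the zero vector; cannot recover weights", call. = FALSE)
  w / nw
}

#' Deflate a view for successive kernel CCA effects
#'
#' Projection deflation in primal space, identical to [deflate_view()];
#' kernels for the next effect are recomputed from the deflated matrix.
#'
#' @inheritParams deflate_view
#' @param w Unit-norm primal weight vector.
#' @return Deflated matrix.
#' @export
kcca_deflate <- function(x, w) {
  deflate_view(x, w)
}

# Fit one KCCA effect in primal terms so it plugs into the shared framework:
# kernels from the (already centered) matrices, dual fit, primal recovery,
# and the train-positive sign convention on v.
kcca_effect_fit <- function(x, y, kappa_x, kappa_y, jitter = NULL) {
  sol <- kcca_fit(linear_kernel(x), linear_kernel(y), kappa_x, kappa_y, jitter)
  u <- recover_primal_weights(x, sol$alpha)
  v <- recover_primal_weights(y, sol$beta)
  sx <- drop(x %*% u)
  sy <- drop(y %*% v)
  r <- if (stats::sd(sx) > 0 && stats::sd(sy) > 0) stats::cor(sx, sy) else 0
  if (r < 0) {
    v <- -v
    r <- -r
  }
  new_effect_model(
    u = u, v = v, kind = "kcca",
    hyperparams = list(kappa_x = kappa_x, kappa_y = kappa_y),
    train_correlation = r, n_iterations = 1L, converged = TRUE,
    feature_names = list(x = colnames(x), y = colnames(y)),
    dual = sol
  )
}
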