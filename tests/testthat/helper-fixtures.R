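# Shared fixtures: small labelled matrices and reduced configurations.

centered_matrix <- function(n, d, seed = 1, prefix = "f") {
  m <- withr::with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0(prefix, seq_len(d)))
  scale(m, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

labelled_matrix <- function(n, d, seed = 1, prefix = "f") {
  m <- withr::with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0(prefix, seq_len(d)))
  m
}

tiny_config <- function(model = "spls", ...) {
  defaults <- list(
    model = model, n_outer_splits = 3L, n_inner_splits = 5L,
    grid = if (model == "spls") {
      list(x = c(1.5, 2.5), y = c(1.5, 2.5))
    } else {
      list(x = c(0, 0.5, 1), y = c(0, 0.5, 1))
    },
    n_permutations = 99L, max_effects = 2L, seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(holdout_config, args)
}

# independent brute-force oracle for the L1-ball projection: scans a grid of
# thresholds for the smallest one meeting the budget, then refines the grid
# once within the bracketing interval (the achieved L1 norm is steep in the
# threshold near the one-hot limit, so one pass is not enough there)
brute_force_l1_unit <- function(a, c, n_grid = 1e4) {
  scan <- function(lo, hi) {
    deltas <- seq(lo, hi, length.out = n_grid)
    feasible <- function(d) {
      s <- pmax(abs(a) - d, 0)
      ns <- sqrt(sum(s^2))
      ns > 0 && sum(s) / ns <= c
    }
    for (i in seq_along(deltas)) {
      if (feasible(deltas[i])) {
        return(c(if (i == 1L) lo else deltas[i - 1L], deltas[i]))
      }
    }
    NULL
  }
  br <- scan(0, max(abs(a)))
  if (!is.null(br) && br[1L] < br[2L]) br <- scan(br[1L], br[2L])
  if (is.null(br)) {
    w <- numeric(length(a))
    w[which.max(abs(a))] <- sign(a[which.max(abs(a))])
    return(w)
  }
  s <- sign(a) * pmax(abs(a) - br[2L], 0)
  s / sqrt(sum(s^2))
}
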