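# Nested resampling, stability measures, joint selection, permutation
# inference, and the end-to-end deflation loop.

test_that("split sizes follow the 80/20 and inner 80/20 arithmetic", {
  cfg <- holdout_config(n_outer_splits = 10, n_inner_splits = 50, seed = 3)
  sch <- make_splits(345, cfg)
  expect_length(sch$outer, 10)
  for (s in sch$outer) {
    expect_length(s$optimization, 276)
    expect_length(s$holdout, 69)
    expect_setequal(c(s$optimization, s$holdout), 1:345)
    expect_length(intersect(s$optimization, s$holdout), 0)
  }
  expect_length(sch$inner[[1]], 50)
  for (is in sch$inner[[3]][1:5]) {
    expect_length(is$training, 221)
    expect_length(is$validation, 55)
    expect_setequal(c(is$training, is$validation), sch$outer[[3]]$optimization)
  }
})

test_that("split schemes are deterministic in the seed", {
  cfg <- holdout_config(n_outer_splits = 4, n_inner_splits = 6, seed = 17)
  expect_identical(make_splits(60, cfg), make_splits(60, cfg))
  cfg2 <- holdout_config(n_outer_splits = 4, n_inner_splits = 6, seed = 18)
  expect_false(identical(make_splits(60, cfg), make_splits(60, cfg2)))
})

test_that("out-of-sample correlation hits its exact and null values", {
  u <- c(1, 0)
  model <- mvholdout:::new_effect_model(
    u = u, v = u, kind = "spls", hyperparams = list(),
    train_correlation = 1, n_iterations = 1, converged = TRUE
  )
  x <- cbind(seq(-2, 2, length.out = 20), 0)
  expect_equal(out_of_sample_correlation(model, x, x), 1)
  expect_equal(out_of_sample_correlation(model, x, -x), -1)
  expect_warning(
    r0 <- out_of_sample_correlation(model, x, 0 * x),
    "zero variance"
  )
  expect_equal(r0, 0)

  # independent Gaussian data: |r| concentrates near 0
  xg <- centered_matrix(1000, 2, seed = 5)
  yg <- centered_matrix(1000, 2, seed = 6, prefix = "g")
  expect_lt(abs(out_of_sample_correlation(model, xg, yg)), 0.1)
})

test_that("corrected overlap matches hand-computed cases and is chance-centered", {
  expect_equal(corrected_overlap(list(c(1, 2), c(1, 2), c(1, 2)), 10), 1)
  expect_equal(corrected_overlap(list(c(1, 2), c(3, 4)), 10), -0.25)
  # empty/full supports contribute 0
  expect_equal(corrected_overlap(list(integer(0), c(1, 2)), 10), 0)
  expect_equal(corrected_overlap(list(1:10, 1:10), 10), 0)
  expect_error(corrected_overlap(list(1:2), 10), "at least 2")

  # random size-k supports in a large universe average out to ~0
  sets <- withr::with_seed(9, lapply(1:46, function(i) sample.int(1000, 50)))
  expect_lt(abs(corrected_overlap(sets, 1000)), 0.05)  # 1035 pairs
})

test_that("weight-correlation stability is sign-invariant and chance-small", {
  w <- withr::with_seed(10, rnorm(50))
  expect_equal(weight_correlation_stability(list(w, w, w)), 1)
  expect_equal(weight_correlation_stability(list(w, -w)), 1)
  ws <- withr::with_seed(11, lapply(1:10, function(i) rnorm(1000)))
  expect_lt(weight_correlation_stability(ws), 0.1)
  expect_warning(
    z <- weight_correlation_stability(list(w, rep(1, 50))),
    "zero-variance"
  )
  expect_equal(z, 0)
})

test_that("hyperparameter selection follows the rank-sum rule and tie-breaks", {
  cells <- tibble::tibble(
    hx = c(2, 3, 4), hy = c(2, 3, 4),
    mean_validation_correlation = c(0.5, 0.4, 0.3),
    stability = c(0.9, 0.8, 0.7),
    n_degenerate = 0L, valid = TRUE
  )
  expect_equal(select_hyperparams(cells, "spls")$hx, 2)  # dominates both

  # ranks (1,3) vs (2,1) vs (3,2): rank sums 4, 3, 5 -> middle cell wins
  cells2 <- tibble::tibble(
    hx = c(2, 3, 4), hy = 2,
    mean_validation_correlation = c(0.6, 0.5, 0.4),
    stability = c(0.2, 0.9, 0.5),
    n_degenerate = 0L, valid = TRUE
  )
  expect_equal(select_hyperparams(cells2, "spls")$hx, 3)

  # exact tie in rank sum and correlation -> more regularized cell
  cells3 <- tibble::tibble(
    hx = c(2, 5), hy = 2,
    mean_validation_correlation = c(0.5, 0.5),
    stability = c(0.7, 0.7),
    n_degenerate = 0L, valid = TRUE
  )
  expect_equal(select_hyperparams(cells3, "spls")$hx, 2)
  expect_equal(select_hyperparams(dplyr::mutate(cells3, hx = c(0.2, 0.8)), "kcca")$hx, 0.8)

  expect_error(
    select_hyperparams(dplyr::mutate(cells3, valid = FALSE), "spls"),
    "no valid grid cell"
  )
  # a single-cell grid is selected unconditionally
  expect_equal(nrow(select_hyperparams(cells[1, ], "spls")), 1)
})

test_that("identical grid cells give identical statistics", {
  x <- labelled_matrix(40, 6, seed = 21)
  y <- labelled_matrix(40, 5, seed = 22, prefix = "g")
  cfg <- tiny_config(grid = list(x = c(2, 2), y = c(1.8, 1.8)))
  sch <- make_splits(40, cfg)
  cells <- grid_search(x, y, NULL, sch$inner[[1]], cfg$grid, cfg)
  expect_equal(nrow(cells), 4)
  expect_equal(cells$mean_validation_correlation[1], cells$mean_validation_correlation[2],
    tolerance = 1e-12
  )
  expect_equal(cells$stability[1], cells$stability[2], tolerance = 1e-12)
})

test_that("permutation p-values honour their floor, ties, and seed", {
  # strong effect: observed correlation beats every permutation
  sim <- simulate_paired_views(80, 6, 6, n_effects = 1, effect_strengths = 6,
                               noise_sd = 0.2, seed = 31)
  x <- scale(sim$data$x, scale = FALSE)[, ]
  y <- scale(sim$data$y, scale = FALSE)[, ]
  m <- spls_fit(x, y, sqrt(6), sqrt(6))
  pt <- holdout_permutation_test(m, x, y, n_permutations = 199, seed = 1)
  expect_equal(pt$p_value, 1 / 200)
  expect_length(pt$null, 199)

  # identical seeds reproduce the null exactly
  pt2 <- holdout_permutation_test(m, x, y, n_permutations = 199, seed = 1)
  expect_identical(pt$null, pt2$null)

  # constant y scores: all permutations tie, p = 1
  y0 <- y
  y0[] <- 0
  expect_warning(
    pt3 <- holdout_permutation_test(m, x, y0, n_permutations = 100, seed = 2),
    "zero variance"
  )
  expect_equal(pt3$p_value, 1)

  expect_error(
    holdout_permutation_test(m, x[1:4, ], y[1:4, ], 100, 1),
    "holdout too small"
  )
})

test_that("null permutation p-values are stochastically no smaller than uniform", {
  ps <- vapply(1:300, function(i) {
    x_tr <- centered_matrix(40, 5, seed = 2 * i)
    y_tr <- centered_matrix(40, 5, seed = 2 * i + 1, prefix = "g")
    m <- suppressWarnings(spls_fit(x_tr, y_tr, 1.8, 1.8))
    x_te <- centered_matrix(30, 5, seed = 10000 + i)
    y_te <- centered_matrix(30, 5, seed = 20000 + i, prefix = "g")
    holdout_permutation_test(m, x_te, y_te, n_permutations = 99, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the across-split significance rule is Bonferroni on the minimum p", {
  p <- c(0.001, 0.4, 0.3, 0.2, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  v <- decide_significance(p, 0.05)
  expect_true(v$significant)
  expect_equal(v$n_below_alpha, 1)
  expect_false(decide_significance(rep(0.5, 10), 0.05)$significant)
  expect_false(decide_significance(c(0.006, rep(0.5, 9)), 0.05)$significant)  # 0.006 > 0.005
  expect_true(decide_significance(rep(0.01, 10), 0.05, rule = "majority")$significant)
})

test_that("the best split optimizes generalizability plus stability jointly", {
  expect_equal(choose_best_split(c(0.9, 0.5), c(0.8, 0.2)), 1)  # dominates
  expect_equal(choose_best_split(c(0.9, 0.8), c(0.1, 0.9)), 1)  # equal sums, higher r wins
  expect_equal(choose_best_split(0.4, 0.5), 1)                  # single split
})

test_that("the framework finds a planted effect, stops, and caps at max_effects", {
  sim <- simulate_paired_views(100, 10, 8, n_effects = 1, support_fraction = 0.3,
                               effect_strengths = 4, noise_sd = 1, seed = 41)
  cfg <- tiny_config(
    n_outer_splits = 4L, n_inner_splits = 6L,
    grid = list(x = c(1.8, 3.2), y = c(1.7, 2.8)),
    n_permutations = 199L, max_effects = 3L, seed = 5L
  )
  res <- run_holdout(sim$data, cfg)
  expect_true(res$effects[[1]]$significant)
  # the loop stops at the first non-significant effect (flagged, included)
  last <- res$effects[[length(res$effects)]]
  expect_true(!last$significant || length(res$effects) == cfg$max_effects)
  expect_lt(length(res$effects), 4)

  capped <- run_holdout(sim$data, tiny_config(
    n_outer_splits = 3L, n_inner_splits = 4L, n_permutations = 99L,
    max_effects = 1L, seed = 5L
  ))
  expect_length(capped$effects, 1)

  # determinism: identical config and seed reproduce every number
  res2 <- run_holdout(sim$data, cfg)
  expect_identical(tidy(res), tidy(res2))
  expect_identical(
    res$effects[[1]]$models[[1]]$u,
    res2$effects[[1]]$models[[1]]$u
  )
})

test_that("tidy, glance, and autoplot summarize a result coherently", {
  sim <- simulate_paired_views(60, 6, 5, n_effects = 1, effect_strengths = 3, seed = 51)
  res <- run_holdout(sim$data, tiny_config(max_effects = 1L))
  td <- tidy(res)
  expect_true(all(c("effect", "split", "holdout_correlation", "p_value",
                    "stability", "c_u", "c_v", "best_split") %in% names(td)))
  expect_equal(sum(td$best_split), length(res$effects))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 60)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, type = "latent"), "ggplot")
  wt <- tidy(res$effects[[1]]$models[[1]])
  expect_equal(nrow(wt), 6 + 5)
})

test_that("a KCCA run works end to end on the same data as SPLS", {
  sim <- simulate_paired_views(70, 6, 6, n_effects = 1, effect_strengths = 4, seed = 61)
  cfg <- tiny_config(
    model = "kcca", n_outer_splits = 3L, n_inner_splits = 4L,
    grid = list(x = c(0, 0.5, 1), y = c(0, 0.5, 1)),
    n_permutations = 99L, max_effects = 1L, seed = 7L
  )
  res <- run_holdout(sim$data, cfg)
  expect_length(res$effects, 1)
  expect_true(all(is.finite(res$effects[[1]]$per_split$holdout_correlation)))
  td <- tidy(res)
  expect_true(all(c("kappa_x", "kappa_y") %in% names(td)))
})

test_that("confounds are removed within each split without touching holdout rows", {
  sim <- simulate_paired_views(90, 8, 6, n_effects = 1, effect_strengths = 3,
                               n_confounds = 2, confound_strength = 1, seed = 71)
  cfg <- tiny_config(n_outer_splits = 3L, n_inner_splits = 4L,
                     n_permutations = 99L, max_effects = 1L)
  res <- run_holdout(sim$data, cfg)
  expect_length(res$effects, 1)
  # the global variant also runs and gives a (possibly different) result
  res_g <- run_holdout(sim$data, tiny_config(
    n_outer_splits = 3L, n_inner_splits = 4L, n_permutations = 99L,
    max_effects = 1L, global_confound_removal = TRUE
  ))
  expect_length(res_g$effects, 1)
})
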