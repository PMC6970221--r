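# Data container, file loading, alignment, and report round trips.

make_view_file <- function(ids, d, path, seed = 1, prefix = "f") {
  m <- withr::with_seed(seed, matrix(stats::rnorm(length(ids) * d), length(ids), d))
  dimnames(m) <- list(ids, paste0(prefix, seq_len(d)))
  write_view(m, path)
  m
}

test_that("rows are aligned by sample ID in x-file order", {
  tmp <- withr::local_tempdir()
  fx <- file.path(tmp, "x.csv")
  fy <- file.path(tmp, "y.csv")
  mx <- make_view_file(c("s1", "s2", "s3"), 3, fx, seed = 1)
  my <- make_view_file(c("s3", "s2", "s1"), 2, fy, seed = 2, prefix = "g")
  pv <- read_paired_views(fx, fy)
  expect_identical(rownames(pv$x), c("s1", "s2", "s3"))
  expect_identical(rownames(pv$y), c("s1", "s2", "s3"))
  expect_equal(pv$y["s3", ], my["s3", ])
  expect_equal(pv$x, mx[c("s1", "s2", "s3"), ])
})

test_that("identical files give identical views and round trips are exact", {
  tmp <- withr::local_tempdir()
  fx <- file.path(tmp, "x.csv")
  m <- make_view_file(paste0("s", 1:5), 4, fx, seed = 3)
  pv <- read_paired_views(fx, fx)
  expect_identical(pv$x, pv$y)
  # full-precision round trip
  expect_identical(pv$x, m)
})

test_that("partial ID overlap keeps the intersection and reports drops", {
  tmp <- withr::local_tempdir()
  fx <- file.path(tmp, "x.csv")
  fy <- file.path(tmp, "y.csv")
  make_view_file(paste0("s", 1:5), 3, fx)
  make_view_file(paste0("s", 2:6), 3, fy, prefix = "g")
  expect_message(pv <- read_paired_views(fx, fy), "dropped 1 x row\\(s\\) and 1 y row")
  expect_identical(rownames(pv$x), paste0("s", 2:5))
  expect_equal(nrow(pv$x), 4L)
})

test_that("malformed inputs are rejected with informative errors", {
  tmp <- withr::local_tempdir()
  fx <- file.path(tmp, "x.csv")
  make_view_file(paste0("s", 1:4), 3, fx)

  bad <- file.path(tmp, "bad.csv")
  writeLines(c("sample_id,f1,f2", "s1,1.0,oops", "s2,2,3", "s3,4,5"), bad)
  expect_error(read_paired_views(fx, bad), "non-numeric value 'oops'.*row 's1'.*column 'f2'")

  dup <- file.path(tmp, "dup.csv")
  writeLines(c("sample_id,f1,f2", "s1,1,2", "s1,3,4", "s2,5,6"), dup)
  expect_error(read_paired_views(fx, dup), "duplicate sample IDs")

  nas <- file.path(tmp, "na.csv")
  writeLines(c("sample_id,f1,f2", "s1,1,NA", "s2,3,4", "s3,5,6"), nas)
  expect_error(read_paired_views(fx, nas), "missing/non-finite")

  disjoint <- file.path(tmp, "disjoint.csv")
  make_view_file(paste0("t", 1:4), 3, disjoint)
  expect_error(read_paired_views(fx, disjoint), "fewer than 3 shared")
})

test_that("effect report writes the contracted file set and round-trips", {
  sim <- simulate_paired_views(60, 8, 6, n_effects = 1, effect_strengths = 4, seed = 5)
  res <- run_holdout(sim$data, tiny_config(n_outer_splits = 3L, max_effects = 2L))
  tmp <- withr::local_tempdir()
  files <- write_effect_report(res, tmp)
  n_eff <- length(res$effects)
  # per effect and split: 2 weight tables + 1 score table; plus one summary
  expect_length(files, n_eff * 3L * 3L + 1L)
  expect_true(file.exists(file.path(tmp, "effect1_split1_x_weights.csv")))

  s <- read_effect_summary(tmp)
  expect_equal(length(s$effects), n_eff)
  for (k in seq_len(n_eff)) {
    expect_equal(
      as.data.frame(s$effects[[k]]$per_split),
      as.data.frame(res$effects[[k]]$per_split)
    )
    expect_identical(s$effects[[k]]$significant, res$effects[[k]]$significant)
    expect_identical(
      as.integer(s$effects[[k]]$best_split_index),
      res$effects[[k]]$best_split_index
    )
  }

  wt <- utils::read.csv(file.path(tmp, "effect1_split1_x_weights.csv"))
  expect_identical(wt$feature_name, colnames(sim$data$x))
  expect_equal(wt$weight, unname(res$effects[[1]]$models[[1]]$u), tolerance = 1e-15)
})

test_that("the CLI simulates, runs, and reports deterministically", {
  tmp <- withr::local_tempdir()
  gen <- file.path(tmp, "gen.json")
  jsonlite::write_json(
    list(n = 50, p = 6, q = 5, n_effects = 1, effect_strengths = 3, seed = 9),
    gen,
    auto_unbox = TRUE
  )
  expect_equal(cli_main(c("simulate", "--config", gen, "--out", file.path(tmp, "sim"),
                          "--log-level", "quiet")), 0L)
  expect_true(file.exists(file.path(tmp, "sim", "x.csv")))

  cfg <- file.path(tmp, "cfg.json")
  jsonlite::write_json(
    list(
      model = "spls", n_outer_splits = 3, n_inner_splits = 4,
      grid = list(x = c(1.5, 2.2), y = c(1.5, 2.2)),
      n_permutations = 99, max_effects = 1, seed = 3
    ),
    cfg,
    auto_unbox = TRUE
  )
  run_cli <- function(out) {
    cli_main(c(
      "run", "--x", file.path(tmp, "sim", "x.csv"), "--y", file.path(tmp, "sim", "y.csv"),
      "--config", cfg, "--out", out, "--log-level", "quiet"
    ))
  }
  expect_equal(run_cli(file.path(tmp, "run1")), 0L)
  expect_true(file.exists(file.path(tmp, "run1", "summary.json")))
  expect_equal(run_cli(file.path(tmp, "run2")), 0L)
  expect_identical(
    readLines(file.path(tmp, "run1", "summary.json")),
    readLines(file.path(tmp, "run2", "summary.json"))
  )

  expect_equal(cli_main(c(
    "report", "--results", file.path(tmp, "run1"),
    "--out", file.path(tmp, "rep"), "--log-level", "quiet"
  )), 0L)
  expect_true(file.exists(file.path(tmp, "rep", "summary_flat.csv")))

  # invalid configuration and unknown subcommand exit nonzero
  bad <- file.path(tmp, "bad.json")
  jsonlite::write_json(list(model = "spls", holdout_fraction = 1.0), bad, auto_unbox = TRUE)
  expect_equal(suppressMessages(cli_main(c(
    "run", "--x", file.path(tmp, "sim", "x.csv"),
    "--y", file.path(tmp, "sim", "y.csv"), "--config", bad
  ))), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
})
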