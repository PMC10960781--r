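write_cfg <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cfg",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("config files are parsed and validated fail-fast", {
  cfg <- read_experiment_config(write_cfg(c(
    "# a demo run", "experiment = demo2d", "shape = crescents",
    "gammas = 2.4, 4.0, 6.0", "seed = 3")))
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$gammas, c(2.4, 4.0, 6.0))
  expect_equal(cfg$seed, 3)

  expect_error(read_experiment_config(write_cfg(c(
    "experiment = demo2d", "shape = crescents"))), "gammas")
  expect_error(read_experiment_config(write_cfg(c(
    "experiment = demo2d", "shape = crescents", "gammas = 2",
    "bogus_key = 1"))), "bogus_key")
  expect_error(read_experiment_config(write_cfg(c(
    "experiment = teleport"))), "unknown experiment")
  expect_error(read_experiment_config(write_cfg(c(
    "experiment = demo2d", "shape = crescents", "gammas = a,b"))),
    "non-numeric")
  expect_error(read_experiment_config(write_cfg("just some text")),
               "key = value")
})

test_that("demo2d writes one table per method and is byte-reproducible", {
  dir1 <- withr::local_tempdir()
  files <- run_demo2d(list(experiment = "demo2d", shape = "crescents",
                           n = 128, gammas = c(2.4, 4, 6), seed = 0,
                           output_dir = dir1))
  expect_setequal(basename(files),
                  c("vanilla.csv", "mixup.csv", "zeta_gamma_2.4.csv",
                    "zeta_gamma_4.csv", "zeta_gamma_6.csv", "manifest.json"))
  for (f in files[grepl("csv$", files)])
    expect_equal(nrow(utils::read.csv(f)), 128L)

  dir2 <- withr::local_tempdir()
  run_demo2d(list(experiment = "demo2d", shape = "crescents", n = 128,
                  gammas = c(2.4, 4, 6), seed = 0, output_dir = dir2))
  for (f in c("vanilla.csv", "mixup.csv", "zeta_gamma_2.4.csv"))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
})

test_that("augmented points approach the originals as the exponent grows", {
  nearest_orig <- function(aug, orig) {
    mean(apply(aug, 1, function(r) {
      sqrt(min(colSums((t(orig) - r)^2)))
    }))
  }
  dists <- sapply(1:5, function(s) {
    b <- make_crescents(n = 256, seed = s)
    sapply(c(2.4, 6, 24), function(g) {
      nearest_orig(apply_zeta_mixup(b, gamma = g, seed = s)$features,
                   b$features)
    })
  })
  avg <- rowMeans(dists)
  expect_true(all(diff(avg) < 0))
})

test_that("run_suite dispatches id-curve and realism with stable schemas", {
  dir1 <- withr::local_tempdir()
  run_suite(list(experiment = "id-curve", shape = "helix", n = 256,
                 gammas = c(2.4, 16), k = 8, seed = 1, output_dir = dir1))
  curve <- utils::read.csv(file.path(dir1, "id_curve.csv"))
  expect_identical(names(curve),
                   c("method", "gamma", "k", "mean_id", "sd_id", "n_points"))
  expect_equal(nrow(curve), 4L)  # vanilla + mixup + 2 grid values

  dir2 <- withr::local_tempdir()
  run_suite(list(experiment = "realism", gamma = 2.8, n = 64,
                 seeds = c(1, 2), methods = "zeta,mixup",
                 output_dir = dir2))
  samples <- utils::read.csv(file.path(dir2, "realism_samples.csv"))
  expect_identical(names(samples),
                   c("method", "seed", "entropy", "cross_entropy"))
  expect_equal(nrow(samples), 2L * 2L * 64L)
  summary_df <- utils::read.csv(file.path(dir2, "realism_summary.csv"))
  expect_true(all(c("method", "mean_entropy", "mean_ce", "seed")
                  %in% names(summary_df)))
  expect_true(file.exists(file.path(dir2, "manifest.json")))
})

test_that("generate then augment round-trips through batch files", {
  dir1 <- withr::local_tempdir()
  run_suite(list(experiment = "generate", shape = "blobs", n = 64,
                 seed = 2, output_dir = dir1))
  src <- file.path(dir1, "blobs.csv")
  expect_true(file.exists(src))

  run_suite(list(experiment = "augment", input = src, gamma = 2.8,
                 seed = 5, output_dir = dir1))
  aug <- read_batch_csv(file.path(dir1, "augmented.csv"))
  expect_equal(nrow(aug$features), 64L)
  expect_equal(rowSums(aug$labels), rep(1, 64), tolerance = 1e-9)

  # same config, different seed: equal schema, different values
  dir2 <- withr::local_tempdir()
  run_suite(list(experiment = "augment", input = src, gamma = 2.8,
                 seed = 6, output_dir = dir2))
  aug2 <- read_batch_csv(file.path(dir2, "augmented.csv"))
  expect_equal(dim(aug2$features), dim(aug$features))
  expect_false(identical(aug2$features, aug$features))
})
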