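# Allowed config keys per experiment. Flat key = value files, fail-fast:
# unknown keys are errors, so a typo cannot silently change a run.
experiment_schema <- list(
  demo2d = list(
    required = c("experiment", "shape", "gammas"),
    optional = c("n", "noise_sd", "seed", "output_dir")),
  `id-curve` = list(
    required = c("experiment", "gammas"),
    optional = c("shape", "n", "ambient_dim", "k", "threshold", "seed",
                 "output_dir")),
  realism = list(
    required = c("experiment", "gamma"),
    optional = c("n", "methods", "seeds", "output_dir")),
  generate = list(
    required = c("experiment", "shape"),
    optional = c("n", "ambient_dim", "noise_sd", "seed", "format",
                 "output_dir")),
  augment = list(
    required = c("experiment", "input", "gamma"),
    optional = c("group_size", "seed", "outputs_per_input",
                 "allow_subcritical", "format", "output_dir"))
)

#' Read a flat key-value experiment configuration
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. The keys are checked against the schema of the named
#' experiment: a missing required key or an unknown key is an error.
#' Comma-separated values (`gammas`, `seeds`, `k`) are parsed into numeric
#' vectors.
#'
#' @param path Path to the config file.
#' @return A named list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad))
    stop("config line not of the form key = value: '", lines[bad[1]], "'")
  cfg <- stats::setNames(lapply(kv, `[[`, 3L),
                         vapply(kv, `[[`, 2L, FUN.VALUE = ""))
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  if (is.null(cfg$experiment))
    stop("config error: missing required key 'experiment'")
  if (!cfg$experiment %in% names(experiment_schema))
    stop("unknown experiment '", cfg$experiment, "'; expected one of: ",
         paste(names(experiment_schema), collapse = ", "))
  schema <- experiment_schema[[cfg$experiment]]
  missing <- setdiff(schema$required, names(cfg))
  if (length(missing))
    stop("config error: missing required key '", missing[1], "'")
  unknown <- setdiff(names(cfg), c(schema$required, schema$optional))
  if (length(unknown))
    stop("config error: unknown key '", unknown[1], "'")
  for (key in intersect(names(cfg), c("gammas", "seeds", "k"))) {
    if (!is.numeric(cfg[[key]]))
      cfg[[key]] <- suppressWarnings(
        as.numeric(strsplit(cfg[[key]], ",")[[1]]))
    if (any(is.na(cfg[[key]]))) stop("config error: non-numeric '", key, "'")
  }
  for (key in intersect(names(cfg), c("n", "ambient_dim", "noise_sd",
                                      "seed", "gamma", "group_size",
                                      "outputs_per_input", "threshold"))) {
    if (!is.numeric(cfg[[key]]))
      cfg[[key]] <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(cfg[[key]])) stop("config error: non-numeric '", key, "'")
  }
  structure(cfg, class = "experiment_config")
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

write_manifest <- function(output_dir, cfg, files) {
  plain <- lapply(unclass(cfg), function(v) unname(v))
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE), tmp)
  manifest <- list(config = plain,
                   config_md5 = unname(tools::md5sum(tmp)),
                   files = basename(files))
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

make_2d_batch <- function(shape, n, noise_sd, seed) {
  switch(shape,
    crescents = make_crescents(n = n, noise_sd = noise_sd, seed = seed),
    spirals = make_spirals(n = n, noise_sd = noise_sd, seed = seed),
    stop("demo2d supports shapes 'crescents' and 'spirals', got '",
         shape, "'"))
}

#' Two-dimensional augmentation demonstration run
#'
#' Generates a crescents or spirals fixture, augments it with pairwise
#' mixup and with p-series mixing at each exponent in `gammas`, and writes
#' every point set as a CSV plus a JSON manifest recording the config and
#' seeds. Reruns with the same config are byte-identical. As the exponent
#' grows, synthesized points hug the original arcs more tightly (their mean
#' distance to the nearest original point shrinks), which is the quantity
#' demo analyses read off these tables.
#'
#' @param config An `experiment_config` (or path to one) with keys `shape`,
#'   `gammas`, and optionally `n`, `noise_sd`, `seed`, `output_dir`.
#' @return Invisibly, the paths of the written files.
#' @export
run_demo2d <- function(config) {
  cfg <- as_experiment_config(config, "demo2d")
  out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(cfg, "seed", 0))
  batch <- make_2d_batch(cfg$shape, cfg_get(cfg, "n", 512),
                         cfg_get(cfg, "noise_sd", 0.1), seed)
  files <- file.path(out_dir, "vanilla.csv")
  write_batch_csv(batch, files[1])
  mix <- mixup_pairwise(batch, seed = seed)
  files <- c(files, file.path(out_dir, "mixup.csv"))
  write_batch_csv(mix, files[2])
  for (g in cfg$gammas) {
    f <- file.path(out_dir, sprintf("zeta_gamma_%s.csv", format(g)))
    write_batch_csv(
      suppressWarnings(apply_zeta_mixup(batch, gamma = g, seed = seed,
                                        allow_subcritical = TRUE)), f)
    files <- c(files, f)
  }
  files <- c(files, write_manifest(out_dir, cfg, files))
  invisible(files)
}

run_id_curve <- function(cfg) {
  out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(cfg, "seed", 0))
  shape <- cfg_get(cfg, "shape", "helix")
  n <- cfg_get(cfg, "n", 1024)
  batch <- if (shape == "helix")
    make_helix(n = n, ambient_dim = cfg_get(cfg, "ambient_dim", 3),
               seed = seed)
  else make_2d_batch(shape, n, 0.1, seed)
  curve <- id_vs_gamma(batch, gamma_grid = sort(cfg$gammas),
                       k_values = as.integer(cfg_get(cfg, "k", 8)),
                       seed = seed,
                       threshold_ratio = cfg_get(cfg, "threshold", 0.05))
  f <- file.path(out_dir, "id_curve.csv")
  utils::write.csv(curve, f, row.names = FALSE, quote = FALSE)
  invisible(c(f, write_manifest(out_dir, cfg, f)))
}

run_realism <- function(cfg) {
  out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- as.integer(cfg_get(cfg, "seeds", 0))
  methods <- strsplit(cfg_get(cfg, "methods", "zeta,mixup"), ",")[[1]]
  n <- cfg_get(cfg, "n", 256)
  per_sample <- list(); summaries <- list()
  for (s in seeds) {
    batch <- make_blobs(n = n, seed = s)
    aug <- stats::setNames(lapply(methods, function(meth) {
      switch(meth,
        zeta = apply_zeta_mixup(batch, gamma = cfg$gamma, seed = s),
        mixup = mixup_pairwise(batch, seed = s),
        dirichlet = dirichlet_mixing(batch, seed = s),
        stop("unknown method '", meth, "'"))
    }), methods)
    rep <- realism_report(aug, batch)
    rep$seed <- s
    summaries[[as.character(s)]] <- rep
    sc <- attr(rep, "scores")
    per_sample[[as.character(s)]] <- do.call(rbind, lapply(methods, function(meth) {
      data.frame(method = meth, seed = s,
                 entropy = sc[[meth]]$entropy,
                 cross_entropy = sc[[meth]]$cross_entropy)
    }))
  }
  f1 <- file.path(out_dir, "realism_samples.csv")
  f2 <- file.path(out_dir, "realism_summary.csv")
  utils::write.csv(do.call(rbind, per_sample), f1, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(do.call(rbind, summaries), f2, row.names = FALSE,
                   quote = FALSE)
  invisible(c(f1, f2, write_manifest(out_dir, cfg, c(f1, f2))))
}

run_generate <- function(cfg) {
  out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(cfg, "seed", 0))
  shape <- cfg$shape
  batch <- switch(shape,
    crescents = ,
    spirals = make_2d_batch(shape, cfg_get(cfg, "n", 512),
                            cfg_get(cfg, "noise_sd", 0.1), seed),
    helix = make_helix(n = cfg_get(cfg, "n", 8192),
                       ambient_dim = cfg_get(cfg, "ambient_dim", 3),
                       noise_sd = cfg_get(cfg, "noise_sd", 0), seed = seed),
    blobs = make_blobs(n = cfg_get(cfg, "n", 300), seed = seed),
    stop("unknown shape '", shape, "'"))
  f <- write_batch_file(batch, file.path(out_dir, shape),
                        cfg_get(cfg, "format", "csv"))
  invisible(c(f, write_manifest(out_dir, cfg, f)))
}

run_augment <- function(cfg) {
  out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  batch <- read_batch_file(cfg$input)
  aug <- apply_zeta_mixup(
    batch, gamma = cfg$gamma,
    group_size = if (!is.null(cfg$group_size)) as.integer(cfg$group_size),
    seed = as.integer(cfg_get(cfg, "seed", 0)),
    outputs_per_input = as.integer(cfg_get(cfg, "outputs_per_input", 1)),
    allow_subcritical = isTRUE(as.logical(cfg_get(cfg, "allow_subcritical",
                                                  "FALSE"))))
  f <- write_batch_file(aug, file.path(out_dir, "augmented"),
                        cfg_get(cfg, "format", "csv"))
  invisible(c(f, write_manifest(out_dir, cfg, f)))
}

write_batch_file <- function(batch, stem, format = c("csv", "rds")) {
  format <- match.arg(format)
  path <- paste0(stem, ".", format)
  if (format == "csv") write_batch_csv(batch, path)
  else saveRDS(list(features = batch$features, labels = batch$labels), path)
  path
}

read_batch_file <- function(path) {
  if (grepl("\\.rds$", path)) {
    obj <- readRDS(path)
    labeled_batch(obj$features, obj$labels)
  } else read_batch_csv(path)
}

as_experiment_config <- function(config, expected = NULL) {
  cfg <- if (is.character(config)) read_experiment_config(config)
         else validate_experiment_config(config)
  if (!is.null(expected) && cfg$experiment != expected)
    stop("expected a '", expected, "' config, got '", cfg$experiment, "'")
  cfg
}

#' Run a configured experiment end to end
#'
#' Dispatches on the config's `experiment` key (`demo2d`, `id-curve`,
#' `realism`, `generate`, `augment`), runs it, and writes its tables plus a
#' JSON manifest (config, md5, file list) into `output_dir`. Every random
#' draw is tied to seeds listed in the config, so a rerun reproduces the
#' artifacts byte for byte.
#'
#' @param config Path to a key-value config file, or a named list.
#' @return Invisibly, the paths of the written artifacts.
#' @export
run_suite <- function(config) {
  cfg <- as_experiment_config(config)
  switch(cfg$experiment,
    demo2d = run_demo2d(cfg),
    `id-curve` = run_id_curve(cfg),
    realism = run_realism(cfg),
    generate = run_generate(cfg),
    augment = run_augment(cfg))
}
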