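#' Specification of a synthetic low-dimensional manifold
#'
#' Bundles the parameters of a synthetic distribution whose intrinsic
#' dimension `d` is far below its ambient dimension `D`: two-class crescents
#' and spirals in the plane (`d = 1` arcs plus noise), a 1-D helix embedded
#' in 3 or 12 ambient dimensions, and Gaussian-mixture blobs (which admit a
#' closed-form Bayes posterior, see [bayes_posterior()]).
#'
#' @param name One of `"crescents"`, `"spirals"`, `"helix"`, `"blobs"`.
#' @param sample_count Total number of points `N`.
#' @param ambient_dim Ambient dimension `D`.
#' @param intrinsic_dim Intrinsic dimension `d` of the noiseless manifold.
#' @param noise_sd Standard deviation of isotropic Gaussian coordinate noise.
#' @param class_count Number of classes `K`.
#' @param seed Integer seed making generation deterministic.
#' @param shape_params Named list of shape parameters (radii, turns, blob
#'   means/covariance, ...), merged over the generator's defaults.
#' @return An object of class `manifold_spec`.
#' @export
manifold_spec <- function(name, sample_count, ambient_dim, intrinsic_dim,
                          noise_sd = 0, class_count = 2L, seed = NULL,
                          shape_params = list()) {
  name <- match.arg(name, c("crescents", "spirals", "helix", "blobs"))
  if (intrinsic_dim > ambient_dim)
    stop("intrinsic_dim must not exceed ambient_dim")
  if (sample_count < class_count || class_count < 1L)
    stop("need sample_count >= class_count >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(name = name, sample_count = as.integer(sample_count),
         ambient_dim = as.integer(ambient_dim),
         intrinsic_dim = as.integer(intrinsic_dim),
         noise_sd = noise_sd, class_count = as.integer(class_count),
         seed = seed, shape_params = shape_params),
    class = "manifold_spec"
  )
}

#' Generate the batch described by a manifold spec
#'
#' @param spec A [manifold_spec()].
#' @return A [labeled_batch()] with the spec attached as attribute
#'   `manifold_spec`.
#' @export
generate_manifold <- function(spec) {
  stopifnot(inherits(spec, "manifold_spec"))
  sp <- spec$shape_params
  switch(spec$name,
    crescents = make_crescents(n = spec$sample_count,
                               noise_sd = spec$noise_sd, seed = spec$seed),
    spirals = do.call(make_spirals, c(
      list(n = spec$sample_count, noise_sd = spec$noise_sd, seed = spec$seed),
      sp[intersect(names(sp), c("turn_coef", "theta_range"))])),
    helix = do.call(make_helix, c(
      list(n = spec$sample_count, ambient_dim = spec$ambient_dim,
           noise_sd = spec$noise_sd, seed = spec$seed),
      sp[intersect(names(sp), "turns")])),
    blobs = do.call(make_blobs, c(
      list(n = spec$sample_count, class_count = spec$class_count,
           seed = spec$seed),
      sp[intersect(names(sp), c("means", "sigma"))]))
  )
}

# Stratified per-class counts: |n_k - N/K| <= 1 always.
stratified_counts <- function(n, k) {
  base <- n %/% k
  counts <- rep(base, k)
  extra <- n %% k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

add_noise <- function(x, sd) {
  if (sd > 0) x + matrix(stats::rnorm(length(x), sd = sd), nrow = nrow(x))
  else x
}

#' Two interleaving crescents
#'
#' The classic two-moons construction: class 0 lies on the upper unit
#' half-circle `(cos t, sin t)`, class 1 on the reflected half-circle
#' `(1 - cos t, 0.5 - sin t)`, `t` evenly spaced on `[0, pi]`, with
#' isotropic Gaussian noise of standard deviation `noise_sd` added to both
#' coordinates. Classes are balanced (`floor(n/2)` and `ceiling(n/2)`).
#' Arc parameters are evenly spaced, not random, so local neighborhoods are
#' well conditioned for intrinsic-dimension estimation.
#'
#' @param n Total number of points (default 512).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param seed Optional integer seed.
#' @return A [labeled_batch()] in 2 ambient dimensions with 2 classes.
#' @export
make_crescents <- function(n = 512L, noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- stratified_counts(n, 2L)
  t0 <- seq(0, pi, length.out = counts[1])
  t1 <- seq(0, pi, length.out = counts[2])
  x <- rbind(cbind(cos(t0), sin(t0)),
             cbind(1 - cos(t1), 0.5 - sin(t1)))
  x <- add_noise(x, noise_sd)
  out <- labeled_batch(x, rep(0:1, counts), class_count = 2L)
  attr(out, "manifold_spec") <- manifold_spec(
    "crescents", n, 2L, 1L, noise_sd, 2L, seed)
  out
}

#' Two interleaving spiral arms
#'
#' Archimedean spirals `r = a * theta` with `theta` evenly spaced on
#' `theta_range`; the second arm is the first rotated by `pi`. Gaussian
#' noise `noise_sd` is added to the coordinates.
#'
#' @param n Total number of points (default 512).
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param seed Optional integer seed.
#' @param turn_coef Radial growth coefficient `a` (default 0.3).
#' @param theta_range Angular extent, default `c(0.5 * pi, 3 * pi)`.
#' @return A [labeled_batch()] in 2 ambient dimensions with 2 classes.
#' @export
make_spirals <- function(n = 512L, noise_sd = 0.1, seed = NULL,
                         turn_coef = 0.3, theta_range = c(0.5 * pi, 3 * pi)) {
  if (!is.null(seed)) set.seed(seed)
  counts <- stratified_counts(n, 2L)
  arm <- function(n_arm, phase) {
    theta <- seq(theta_range[1], theta_range[2], length.out = n_arm)
    r <- turn_coef * theta
    cbind(r * cos(theta + phase), r * sin(theta + phase))
  }
  x <- add_noise(rbind(arm(counts[1], 0), arm(counts[2], pi)), noise_sd)
  out <- labeled_batch(x, rep(0:1, counts), class_count = 2L)
  attr(out, "manifold_spec") <- manifold_spec(
    "spirals", n, 2L, 1L, noise_sd, 2L, seed,
    shape_params = list(turn_coef = turn_coef, theta_range = theta_range))
  out
}

#' 1-D helix in 3 or 12 ambient dimensions
#'
#' Points `(cos t, sin t, t / (2 * pi))` over `turns` full turns, `t` evenly
#' spaced. For `ambient_dim = 12` the 3-D helix is pushed through a seeded
#' random orthonormal linear map (Q factor of a Gaussian matrix), which
#' preserves all pairwise distances, so the intrinsic dimension stays 1
#' while no ambient axis is trivially degenerate. Noise defaults to 0.
#'
#' @param n Number of points (default 8192).
#' @param ambient_dim 3 or 12.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Optional integer seed (drives the 12-D embedding and noise).
#' @param turns Number of full turns (default 3).
#' @return A single-class [labeled_batch()].
#' @export
make_helix <- function(n = 8192L, ambient_dim = 3L, noise_sd = 0,
                       seed = NULL, turns = 3) {
  if (!ambient_dim %in% c(3L, 12L))
    stop("`ambient_dim` must be 3 or 12, got ", ambient_dim)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi * turns, length.out = n)
  x <- cbind(cos(t), sin(t), t / (2 * pi))
  if (ambient_dim == 12L) {
    q <- qr.Q(qr(matrix(stats::rnorm(12L * 3L), nrow = 12L)))
    x <- x %*% t(q)
  }
  x <- add_noise(x, noise_sd)
  out <- labeled_batch(x, rep(0L, n), class_count = 1L)
  attr(out, "manifold_spec") <- manifold_spec(
    "helix", n, ambient_dim, 1L, noise_sd, 1L, seed,
    shape_params = list(turns = turns))
  out
}

#' Gaussian-mixture blobs with a closed-form posterior
#'
#' Equal-prior Gaussian mixture with one component per class and a shared
#' covariance; points are allocated to classes by stratification (class
#' counts differ by at most 1, exact when `K` divides `n`). Because the
#' generating mixture is retained in the `manifold_spec` attribute, the
#' exact Bayes class posterior of any point is available via
#' [bayes_posterior()] — this is the fixture the realism oracle runs on.
#'
#' @param n Total number of points.
#' @param means `K x D` matrix of class means; default two classes at
#'   `(3, 0)` and `(-3, 0)`.
#' @param sigma Shared `D x D` covariance matrix, default identity.
#' @param class_count Number of classes; inferred from `means`.
#' @param seed Optional integer seed.
#' @return A [labeled_batch()] with one-hot labels and the mixture stored in
#'   attribute `manifold_spec`.
#' @export
make_blobs <- function(n = 300L, means = rbind(c(3, 0), c(-3, 0)),
                       sigma = NULL, class_count = nrow(means),
                       seed = NULL) {
  means <- as.matrix(means)
  if (nrow(means) != class_count)
    stop("`means` must have one row per class")
  d <- ncol(means)
  if (is.null(sigma)) sigma <- diag(d)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`sigma` must be positive definite")
  if (!is.null(seed)) set.seed(seed)
  counts <- stratified_counts(n, class_count)
  x <- do.call(rbind, lapply(seq_len(class_count), function(k) {
    MASS::mvrnorm(counts[k], mu = means[k, ], Sigma = sigma)
  }))
  out <- labeled_batch(x, rep(seq_len(class_count) - 1L, counts),
                       class_count = class_count)
  attr(out, "manifold_spec") <- manifold_spec(
    "blobs", n, d, d, 0, class_count, seed,
    shape_params = list(means = means, sigma = sigma,
                        priors = counts / sum(counts)))
  out
}
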