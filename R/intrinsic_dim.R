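#' Local intrinsic dimensionality via neighborhood PCA
#'
#' Estimates the intrinsic dimension around every point with the
#' Fukunaga-Olsen rule: take the `k` nearest neighbors of the point
#' (Euclidean distance, the point itself excluded), form the covariance of
#' the neighborhood (centered at the neighborhood mean), and count the
#' eigenvalues larger than `threshold_ratio` times the largest eigenvalue.
#' That count — an integer in `[1, min(k, D)]` — is the point's local ID.
#'
#' Numerical conventions: eigenvalues come from a symmetric eigensolver and
#' tiny negative round-off values are clamped to 0 before thresholding; the
#' significance comparison is strict (an eigenvalue at exactly the threshold
#' does not count); a fully degenerate neighborhood (all eigenvalues 0)
#' yields ID 1 by convention rather than a division by zero.
#'
#' @param points Numeric `N x D` matrix.
#' @param k Neighborhood size, `2 <= k < N`. Typical values 8 and 128.
#' @param threshold_ratio Significance fraction of the largest eigenvalue,
#'   default 0.05 (the "5 percent" rule).
#' @return An object of class `local_id_profile`: list with `per_point_id`
#'   (integer vector of length `N`), `k`, `threshold_ratio`, `mean_id`,
#'   `sd_id`.
#' @examples
#' x <- cbind(matrix(rnorm(400), ncol = 2), 0)  # planar cloud in 3-D
#' local_id(x, k = 8)$mean_id                   # 2
#' @export
local_id <- function(points, k, threshold_ratio = 0.05) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k >= n) stop("`k` must be smaller than the number of points")
  if (k < 2L) stop("`k` must be at least 2")
  if (threshold_ratio <= 0 || threshold_ratio >= 1)
    stop("`threshold_ratio` must lie in (0, 1)")

  nn <- knn_indices(points, k)
  ids <- integer(n)
  for (i in seq_len(n)) {
    neigh <- points[nn[i, ], , drop = FALSE]
    ev <- eigen(stats::cov(neigh), symmetric = TRUE,
                only.values = TRUE)$values
    ev[ev < 0] <- 0
    ids[i] <- if (ev[1] == 0) 1L
              else sum(ev > threshold_ratio * ev[1])
  }
  structure(
    list(per_point_id = ids, k = as.integer(k),
         threshold_ratio = threshold_ratio,
         mean_id = mean(ids), sd_id = stats::sd(ids)),
    class = "local_id_profile"
  )
}

#' @export
print.local_id_profile <- function(x, ...) {
  cat("<local_id_profile> n = ", length(x$per_point_id), ", k = ", x$k,
      ", mean ID = ", format(x$mean_id, digits = 4),
      " (sd ", format(x$sd_id, digits = 3), ")\n", sep = "")
  invisible(x)
}

# k nearest neighbors of every point, self excluded. Chunked so the full
# N x N distance matrix is never materialized for large N.
knn_indices <- function(points, k, chunk = 512L) {
  n <- nrow(points)
  sq <- rowSums(points^2)
  out <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * points[idx, , drop = FALSE] %*% t(points)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    out[idx, ] <- t(apply(d2, 1L, function(row) {
      order(row)[seq_len(k)]
    }))
  }
  out
}

#' Local ID of augmented batches across the mixing exponent
#'
#' Traces how the mean local intrinsic dimension of synthesized samples
#' responds to the p-series exponent `gamma`: for every value in
#' `gamma_grid` the batch is augmented with [apply_zeta_mixup()]
#' (whole-batch mixing, `T = m`) and profiled with [local_id()]; reference
#' profiles are computed for the raw, unaugmented batch (`"vanilla"`) and
#' for the [mixup_pairwise()] output. Small exponents let samples stray off
#' the manifold and inflate the local ID; large exponents collapse the
#' weights onto single originals and the profile approaches (or, because the
#' augmented distribution is more compact, can drop slightly below) the raw
#' one. Sub-critical grid values are permitted here, since the sweep is a
#' diagnostic, not a training transform.
#'
#' @param batch A [labeled_batch()].
#' @param gamma_grid Strictly increasing numeric vector of exponents.
#' @param k_values Integer vector of neighborhood sizes (default `c(8L)`;
#'   the full-scale audit uses `c(8L, 128L)`).
#' @param seed Integer seed for the augmentation draws.
#' @param threshold_ratio Passed to [local_id()].
#' @param include_original Also pool the original points with the augmented
#'   ones before profiling (default `FALSE`: augmented-only).
#' @return A data frame with columns `method` (`"vanilla"`, `"mixup"`, or
#'   `"zeta"`), `gamma` (`NA` for the references), `k`, `mean_id`, `sd_id`,
#'   `n_points`; the per-point profiles are attached as attribute
#'   `profiles`.
#' @export
id_vs_gamma <- function(batch, gamma_grid, k_values = c(8L), seed = 1L,
                        threshold_ratio = 0.05, include_original = FALSE) {
  stopifnot(inherits(batch, "labeled_batch"))
  if (!length(gamma_grid)) stop("`gamma_grid` must be non-empty")
  if (is.unsorted(gamma_grid, strictly = TRUE))
    stop("`gamma_grid` must be strictly increasing")

  pool <- function(x) {
    if (include_original) rbind(batch$features, x) else x
  }
  point_sets <- c(
    list(vanilla = batch$features,
         mixup = pool(mixup_pairwise(batch, seed = seed)$features)),
    stats::setNames(
      lapply(gamma_grid, function(g) {
        pool(suppressWarnings(
          apply_zeta_mixup(batch, gamma = g, seed = seed,
                           allow_subcritical = TRUE))$features)
      }),
      paste0("zeta_", gamma_grid))
  )
  gammas <- c(NA_real_, NA_real_, gamma_grid)
  methods <- c("vanilla", "mixup", rep("zeta", length(gamma_grid)))

  rows <- list(); profiles <- list()
  for (ki in k_values) {
    for (j in seq_along(point_sets)) {
      prof <- local_id(point_sets[[j]], k = ki,
                       threshold_ratio = threshold_ratio)
      key <- paste0(names(point_sets)[j], "_k", ki)
      profiles[[key]] <- prof
      rows[[key]] <- data.frame(
        method = methods[j], gamma = gammas[j], k = ki,
        mean_id = prof$mean_id, sd_id = prof$sd_id,
        n_points = length(prof$per_point_id))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "profiles") <- profiles
  out
}
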