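# Cached root of zeta(gamma) = 2; computed on first use.
.zm_cache <- new.env(parent = emptyenv())

gamma_min_cached <- function() {
  if (is.null(.zm_cache$gamma_min)) .zm_cache$gamma_min <- gamma_min()
  .zm_cache$gamma_min
}

#' Multi-sample p-series mixup
#'
#' Synthesizes new samples as convex combinations of `T >= 2` originals,
#' with weights from a randomly permuted, normalized p-series
#' (see [canonical_weights()]): features and labels are both transformed as
#' `W %*% x`, where `W` is a row-stochastic permutation weight matrix
#' ([sample_weight_matrix()]). For `gamma >= gamma_min()` each output is
#' dominated by a single original sample — more than half of its mass comes
#' from one point — so samples stay close to the data manifold while still
#' drawing label information from up to `min(T, K)` classes.
#'
#' By default the whole batch is mixed at once (`group_size = m`, the setting
#' used throughout for experiments). When `group_size < m`, the batch is
#' globally shuffled and split into contiguous groups of `group_size`; a
#' remainder of one sample is folded into the final group, a larger remainder
#' forms its own smaller group, so every sample is used exactly once.
#'
#' @param batch A [labeled_batch()].
#' @param gamma p-series exponent. Values below [gamma_min()] void the
#'   single-sample dominance guarantee and are refused unless
#'   `allow_subcritical = TRUE` (then a warning is emitted).
#' @param group_size Number of samples `T` mixed per output, `2 <= T <= m`.
#'   Defaults to the batch size `m`.
#' @param seed Optional integer seed driving all permutation draws.
#' @param outputs_per_input Number of synthesized samples per original
#'   sample; the output batch has `outputs_per_input * m` rows.
#' @param allow_subcritical Permit `gamma < gamma_min()` with a warning.
#' @param permutations Optional pinned permutation matrix forwarded to
#'   [sample_weight_matrix()]; only allowed when `group_size` equals the
#'   batch size and `outputs_per_input = 1`.
#' @return A [labeled_batch()] of synthesized samples, with attributes
#'   `gamma` and `seed`.
#' @examples
#' b <- make_crescents(n = 64, seed = 1)
#' aug <- apply_zeta_mixup(b, gamma = 2.8, seed = 1)
#' @export
apply_zeta_mixup <- function(batch, gamma, group_size = NULL, seed = NULL,
                             outputs_per_input = 1L,
                             allow_subcritical = FALSE,
                             permutations = NULL) {
  stopifnot(inherits(batch, "labeled_batch"))
  m <- nrow(batch$features)
  if (is.null(group_size)) group_size <- m
  if (group_size < 2L || group_size > m)
    stop("`group_size` must satisfy 2 <= T <= m = ", m)
  if (!is.finite(gamma)) stop("`gamma` must be finite")
  if (gamma < gamma_min_cached()) {
    if (!allow_subcritical)
      stop("gamma = ", gamma, " is below gamma_min = ",
           format(gamma_min_cached(), digits = 7),
           "; no single weight dominates. Set `allow_subcritical = TRUE` ",
           "to proceed anyway.")
    warning("gamma = ", gamma, " is below gamma_min; the dominant-weight ",
            "guarantee does not hold")
  }
  if (!is.null(permutations) && (group_size != m || outputs_per_input != 1L))
    stop("pinned `permutations` require group_size = m and ",
         "outputs_per_input = 1")
  if (!is.null(seed)) set.seed(seed)

  one_pass <- function() {
    if (group_size == m) {
      W <- sample_weight_matrix(m, gamma, permutations = permutations)
      return(list(x = W %*% batch$features, y = W %*% batch$labels))
    }
    ord <- sample.int(m)
    n_full <- m %/% group_size
    rem <- m %% group_size
    sizes <- rep(group_size, n_full)
    if (rem == 1L) sizes[n_full] <- sizes[n_full] + 1L
    else if (rem >= 2L) sizes <- c(sizes, rem)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    xs <- vector("list", length(sizes))
    ys <- vector("list", length(sizes))
    for (g in seq_along(sizes)) {
      idx <- ord[starts[g]:ends[g]]
      W <- sample_weight_matrix(sizes[g], gamma)
      xs[[g]] <- W %*% batch$features[idx, , drop = FALSE]
      ys[[g]] <- W %*% batch$labels[idx, , drop = FALSE]
    }
    list(x = do.call(rbind, xs), y = do.call(rbind, ys))
  }

  passes <- lapply(seq_len(outputs_per_input), function(i) one_pass())
  out <- labeled_batch(do.call(rbind, lapply(passes, `[[`, "x")),
                       do.call(rbind, lapply(passes, `[[`, "y")),
                       class_count = batch$class_count)
  attr(out, "gamma") <- gamma
  attr(out, "seed") <- seed
  out
}

#' Pairwise mixup baseline
#'
#' Classical two-sample mixing: each sample is paired with a random partner
#' and the output is `lambda * x_i + (1 - lambda) * x_j`, with labels mixed
#' identically. One `lambda` is drawn per call from `Beta(alpha, alpha)`
#' (with `alpha = 1` this is uniform on `[0, 1]`, the conventional setting),
#' or a fixed `lambda` may be supplied.
#'
#' When `group_size` is given, the batch is split into minibatches of that
#' size (after a global shuffle) and each minibatch gets its own `lambda`
#' draw and partner permutation — the situation during epoch-wise training,
#' where an augmented dataset pools outputs from many minibatches each with
#' its own mixing factor.
#'
#' @param batch A [labeled_batch()].
#' @param lambda Optional fixed mixing factor in `[0, 1]`.
#' @param alpha Beta-distribution concentration used when `lambda` is not
#'   given; must be positive. Default 1.
#' @param seed Optional integer seed.
#' @param partner Optional integer vector (a permutation of `1:m`) pinning
#'   each row's mixing partner; drawn uniformly at random by default.
#'   Incompatible with `group_size`.
#' @param group_size Optional minibatch size; one `lambda` is drawn per
#'   minibatch rather than per call.
#' @return A [labeled_batch()] with attributes `lambda` (vector when
#'   `group_size` is used) and `seed`.
#' @export
mixup_pairwise <- function(batch, lambda = NULL, alpha = 1, seed = NULL,
                           partner = NULL, group_size = NULL) {
  stopifnot(inherits(batch, "labeled_batch"))
  m <- nrow(batch$features)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(lambda) && (lambda < 0 || lambda > 1))
    stop("`lambda` must lie in [0, 1]")
  if (alpha <= 0) stop("`alpha` must be positive")

  if (!is.null(group_size)) {
    if (!is.null(partner))
      stop("`partner` cannot be combined with `group_size`")
    if (group_size < 2L || group_size > m)
      stop("`group_size` must satisfy 2 <= size <= m = ", m)
    ord <- sample.int(m)
    groups <- split(ord, ceiling(seq_along(ord) / group_size))
    if (length(groups[[length(groups)]]) == 1L && length(groups) > 1L) {
      groups[[length(groups) - 1L]] <-
        c(groups[[length(groups) - 1L]], groups[[length(groups)]])
      groups[[length(groups)]] <- NULL
    }
    parts <- lapply(groups, function(idx) {
      sub <- labeled_batch(batch$features[idx, , drop = FALSE],
                           batch$labels[idx, , drop = FALSE],
                           class_count = batch$class_count)
      mixup_pairwise(sub, lambda = lambda, alpha = alpha)
    })
    out <- labeled_batch(
      do.call(rbind, lapply(parts, function(p) p$features)),
      do.call(rbind, lapply(parts, function(p) p$labels)),
      class_count = batch$class_count)
    attr(out, "lambda") <- vapply(parts, attr, numeric(1), "lambda")
    attr(out, "seed") <- seed
    return(out)
  }

  if (is.null(lambda)) lambda <- stats::rbeta(1, alpha, alpha)
  if (is.null(partner)) partner <- sample.int(m)
  else if (!identical(sort(as.integer(partner)), seq_len(m)))
    stop("`partner` must be a permutation of 1:m")

  out <- labeled_batch(
    lambda * batch$features + (1 - lambda) * batch$features[partner, , drop = FALSE],
    lambda * batch$labels + (1 - lambda) * batch$labels[partner, , drop = FALSE],
    class_count = batch$class_count
  )
  attr(out, "lambda") <- lambda
  attr(out, "seed") <- seed
  out
}

#' Dirichlet whole-batch mixing baseline
#'
#' Ablation baseline: each output row is a convex combination of the entire
#' batch with weights drawn from a Dirichlet distribution (the multivariate
#' generalization of the Beta mixing law used by pairwise mixup). With a
#' symmetric unit concentration and large `m`, no single sample dominates
#' any output — the property that distinguishes this scheme from p-series
#' weighting.
#'
#' @param batch A [labeled_batch()].
#' @param concentration Positive numeric vector of length `m` (recycled if
#'   scalar) of Dirichlet concentration parameters. Default all 1.
#' @param seed Optional integer seed.
#' @return A [labeled_batch()] of `m` synthesized samples.
#' @export
dirichlet_mixing <- function(batch, concentration = 1, seed = NULL) {
  stopifnot(inherits(batch, "labeled_batch"))
  m <- nrow(batch$features)
  concentration <- rep_len(concentration, m)
  if (any(concentration <= 0)) stop("`concentration` must be positive")
  if (!is.null(seed)) set.seed(seed)
  W <- rdirichlet_rows(m, concentration)
  out <- labeled_batch(W %*% batch$features, W %*% batch$labels,
                       class_count = batch$class_count)
  attr(out, "seed") <- seed
  out
}

# n Dirichlet(alpha) rows via normalized Gamma draws.
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
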