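#' Exact Bayes class posterior under a Gaussian-mixture fixture
#'
#' For points drawn from (or synthesized near) a [make_blobs()] mixture, the
#' class posterior is available in closed form from the stored component
#' means, shared covariance and priors. This exact posterior plays the role
#' of a near-perfect classifier ("oracle"): its prediction entropy proxies
#' how realistic a synthesized point is, and it anchors the cross-entropy
#' check of assigned soft labels. Computation is done with log-densities and
#' a log-sum-exp normalization for numerical stability.
#'
#' @param points Numeric `n x D` matrix of query points.
#' @param spec A blobs [manifold_spec()] (or a [labeled_batch()] carrying
#'   one as attribute `manifold_spec`).
#' @return An `n x K` matrix of class posteriors; rows sum to 1.
#' @export
bayes_posterior <- function(points, spec) {
  if (inherits(spec, "labeled_batch")) spec <- attr(spec, "manifold_spec")
  if (!inherits(spec, "manifold_spec") || spec$name != "blobs")
    stop("oracle unavailable: a blobs manifold_spec is required")
  means <- spec$shape_params$means
  sigma <- spec$shape_params$sigma
  priors <- spec$shape_params$priors
  if (is.null(priors)) priors <- rep(1 / nrow(means), nrow(means))
  points <- as.matrix(points)
  if (ncol(points) != ncol(means))
    stop("points have ", ncol(points), " dims, mixture has ", ncol(means))

  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  k <- nrow(means)
  loglik <- vapply(seq_len(k), function(j) {
    centered <- sweep(points, 2L, means[j, ])
    z <- backsolve(ch, t(centered), transpose = TRUE)
    -0.5 * (colSums(z^2) + logdet + ncol(points) * log(2 * pi))
  }, numeric(nrow(points)))
  loglik <- matrix(loglik, ncol = k)  # n = 1 edge case
  logpost <- sweep(loglik, 2L, log(priors), "+")
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post / rowSums(post)
}

#' Prediction entropy of probability rows
#'
#' Shannon entropy `-sum(p * log(p))` in nats, with the `0 * log(0) = 0`
#' convention; bounded by `[0, log(K)]`. Low oracle entropy on a
#' synthesized sample means the oracle is confident about its class — the
#' working proxy for the sample being realistic.
#'
#' @param p A probability vector, or a matrix of probability rows.
#' @return A numeric value per row, in nats.
#' @examples
#' prediction_entropy(c(0.53, 0.47))
#' @export
prediction_entropy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  validate_label_matrix(p)
  terms <- ifelse(p > 0, p * log(p), 0)
  -rowSums(terms)
}

#' Cross-entropy between oracle posteriors and assigned soft labels
#'
#' Measures label correctness as `-sum(q * log(p))` in nats with `q` the
#' oracle posterior (the target) and `p` the soft label the augmentation
#' assigned, so a confident oracle paired with a wrong label scores high.
#' Probabilities inside the logarithm are floored at `floor` to keep the
#' value finite on exact zeros. The opposite orientation (soft label as
#' target) is available via `orientation = "label"`.
#'
#' @param assigned_label Probability vector or matrix of assigned labels.
#' @param oracle_posterior Probability vector or matrix from
#'   [bayes_posterior()]; same shape as `assigned_label`.
#' @param orientation `"oracle"` (default; oracle posterior is the target
#'   distribution) or `"label"`.
#' @param floor Lower clamp applied inside the logarithm, default `1e-12`.
#' @return A non-negative numeric value per row, in nats.
#' @examples
#' label_cross_entropy(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
label_cross_entropy <- function(assigned_label, oracle_posterior,
                                orientation = c("oracle", "label"),
                                floor = 1e-12) {
  orientation <- match.arg(orientation)
  if (is.null(dim(assigned_label)))
    assigned_label <- matrix(assigned_label, nrow = 1)
  if (is.null(dim(oracle_posterior)))
    oracle_posterior <- matrix(oracle_posterior, nrow = 1)
  validate_label_matrix(assigned_label)
  validate_label_matrix(oracle_posterior)
  if (!all(dim(assigned_label) == dim(oracle_posterior)))
    stop("assigned labels and oracle posteriors must have matching shapes")
  if (orientation == "oracle") {
    q <- oracle_posterior; p <- assigned_label
  } else {
    q <- assigned_label; p <- oracle_posterior
  }
  -rowSums(q * log(pmax(p, floor)))
}

#' Realism and label-correctness report
#'
#' Scores one or more augmented batches against the exact Bayes oracle of a
#' blobs fixture: per method, the mean and median oracle prediction entropy
#' (realism proxy; lower is better) and the mean and median cross-entropy
#' between oracle posteriors and assigned soft labels (label correctness;
#' lower is better), plus the mean cross-entropy restricted to the
#' low-entropy subset (oracle entropy below `entropy_threshold`) — the
#' samples that look most realistic, where label error is most damaging.
#'
#' @param augmented A [labeled_batch()], or a named list of them (one per
#'   method).
#' @param spec The blobs [manifold_spec()] (or the original blob batch).
#' @param entropy_threshold Restriction threshold in nats, default 0.1.
#' @return A data frame with one row per method and columns `method`, `n`,
#'   `mean_entropy`, `median_entropy`, `mean_ce`, `median_ce`,
#'   `mean_ce_low_entropy`, `n_low_entropy`. Per-sample scores are attached
#'   as attribute `scores` (a named list of `oracle_score` objects, each
#'   holding `entropy`, `cross_entropy` and `oracle_posterior`).
#' @export
realism_report <- function(augmented, spec, entropy_threshold = 0.1) {
  if (inherits(augmented, "labeled_batch"))
    augmented <- list(augmented = augmented)
  if (is.null(names(augmented)) || any(!nzchar(names(augmented))))
    stop("`augmented` must be a named list of labeled batches")
  if (inherits(spec, "labeled_batch")) spec <- attr(spec, "manifold_spec")

  scores <- lapply(augmented, function(b) {
    stopifnot(inherits(b, "labeled_batch"))
    post <- bayes_posterior(b$features, spec)
    structure(
      list(entropy = prediction_entropy(post),
           cross_entropy = label_cross_entropy(b$labels, post),
           oracle_posterior = post),
      class = "oracle_score"
    )
  })
  out <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    low <- s$entropy < entropy_threshold
    data.frame(
      method = nm, n = length(s$entropy),
      mean_entropy = mean(s$entropy), median_entropy = stats::median(s$entropy),
      mean_ce = mean(s$cross_entropy),
      median_ce = stats::median(s$cross_entropy),
      mean_ce_low_entropy = if (any(low)) mean(s$cross_entropy[low]) else NA_real_,
      n_low_entropy = sum(low))
  }))
  attr(out, "scores") <- scores
  out
}
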