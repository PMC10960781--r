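#' Construct a labeled batch
#'
#' A labeled batch is the unit every augmentation operator consumes and emits:
#' an `m x D` real feature matrix (rows are samples, columns are ambient
#' dimensions; images are supplied flattened) together with an `m x K`
#' row-stochastic label matrix giving the probability of each of `K` classes.
#' Hard integer class labels are accepted and one-hot encoded internally;
#' probabilistic label rows are validated, never silently re-normalized, so
#' that malformed labels surface as errors at construction time.
#'
#' @param features Numeric matrix, `m` rows by `D` columns. A data frame of
#'   numeric columns is accepted and coerced.
#' @param labels Either an integer vector of length `m` with 0-based class
#'   indices (see [one_hot_encode()]), or an `m x K` matrix of class
#'   probabilities whose rows sum to 1.
#' @param class_count Number of classes `K`. Required when `labels` is an
#'   integer vector; inferred from the column count otherwise.
#'
#' @return An object of class `labeled_batch`: a list with elements
#'   `features`, `labels` and `class_count`.
#'
#' @examples
#' x <- matrix(rnorm(12), nrow = 4)
#' b <- labeled_batch(x, c(0L, 1L, 1L, 0L), class_count = 2)
#' b$labels
#' @export
labeled_batch <- function(features, labels, class_count = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop("`features` must be a numeric matrix")
  m <- nrow(features)
  if (m < 2L)
    stop("a labeled batch needs at least 2 samples, got ", m)

  if (is.null(dim(labels))) {
    if (is.null(class_count))
      stop("`class_count` is required when `labels` are class indices")
    labels <- one_hot_encode(labels, class_count)
  } else {
    labels <- as.matrix(labels)
    if (is.null(class_count)) class_count <- ncol(labels)
  }
  if (nrow(labels) != m)
    stop("feature and label row counts differ: ", m, " vs ", nrow(labels))
  if (ncol(labels) != class_count)
    stop("label matrix has ", ncol(labels), " columns but class_count = ",
         class_count)
  validate_label_matrix(labels)

  structure(
    list(features = features, labels = labels,
         class_count = as.integer(class_count)),
    class = "labeled_batch"
  )
}

# Row-stochastic validity: non-negative entries, rows summing to 1 within
# 1e-9. Deliberately strict — re-normalizing here would mask caller bugs.
validate_label_matrix <- function(labels, tol = 1e-9) {
  if (any(!is.finite(labels)) || any(labels < 0))
    stop("label entries must be finite and non-negative")
  rs <- rowSums(labels)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("label rows must sum to 1 (row ", bad[1], " sums to ",
         format(rs[bad[1]], digits = 12), ")")
  invisible(labels)
}

#' @export
print.labeled_batch <- function(x, ...) {
  cat("<labeled_batch> ", nrow(x$features), " samples x ",
      ncol(x$features), " dims, ", x$class_count, " classes\n", sep = "")
  invisible(x)
}

#' One-hot encode integer class indices
#'
#' Class indices are 0-based (`0 .. K-1`), matching the `class_0 ..
#' class_{K-1}` label columns used in batch CSV files.
#'
#' @param class_indices Integer vector of class indices in `[0, K)`.
#' @param class_count Number of classes `K`.
#' @return A `length(class_indices) x K` matrix with a single 1 per row.
#' @examples
#' one_hot_encode(c(0L, 2L, 2L), 3)
#' @export
one_hot_encode <- function(class_indices, class_count) {
  idx <- as.integer(class_indices)
  if (any(is.na(idx)) || any(idx != class_indices))
    stop("class indices must be integers")
  if (any(idx < 0L) || any(idx >= class_count))
    stop("class indices must lie in [0, ", class_count, ")")
  out <- matrix(0, nrow = length(idx), ncol = class_count)
  out[cbind(seq_along(idx), idx + 1L)] <- 1
  colnames(out) <- paste0("class_", seq_len(class_count) - 1L)
  out
}

#' Hard class index of each label row
#'
#' @param batch A [labeled_batch()].
#' @return Integer vector of 0-based indices of the most probable class.
#' @export
hard_labels <- function(batch) {
  max.col(batch$labels, ties.method = "first") - 1L
}

#' Read and write labeled batches as CSV
#'
#' The delimited format stores feature columns `x1 .. xD` followed by label
#' columns `class_0 .. class_{K-1}`, with a header row. `write_batch_csv`
#' writes with full double precision so a round trip is lossless to the
#' printed digits.
#'
#' @param batch A [labeled_batch()].
#' @param path File path.
#' @return `read_batch_csv` returns a [labeled_batch()];
#'   `write_batch_csv` returns `path` invisibly.
#' @export
write_batch_csv <- function(batch, path) {
  feat <- batch$features
  colnames(feat) <- paste0("x", seq_len(ncol(feat)))
  lab <- batch$labels
  colnames(lab) <- paste0("class_", seq_len(ncol(lab)) - 1L)
  utils::write.csv(
    data.frame(feat, lab, check.names = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab_cols <- grep("^class_[0-9]+$", names(df))
  if (!length(lab_cols))
    stop("no label columns (class_0 ...) found in ", path)
  labeled_batch(as.matrix(df[, -lab_cols, drop = FALSE]),
                as.matrix(df[, lab_cols, drop = FALSE]))
}
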