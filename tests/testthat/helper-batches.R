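# Shared fixtures: small random labeled batches and a brute-force mixing
# oracle kept deliberately independent of the matrix-multiply code path.

random_batch <- function(m, d = 3L, k = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labeled_batch(matrix(rnorm(m * d), nrow = m),
                sample(0:(k - 1L), m, replace = TRUE),
                class_count = k)
}

# Element-by-element weighted sum over one pinned permutation per output
# row: out[r, j] = sum_i perm_rank^-gamma / C * x[i, j], scalar loops only.
brute_force_mix <- function(mat, gamma, perms) {
  m <- nrow(mat)
  cval <- 0
  for (j in seq_len(m)) cval <- cval + j^(-gamma)
  out <- matrix(0, nrow = nrow(perms), ncol = ncol(mat))
  for (r in seq_len(nrow(perms))) {
    for (j in seq_len(ncol(mat))) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + perms[r, i]^(-gamma) * mat[i, j]
      out[r, j] <- acc / cval
    }
  }
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
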