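test_that("p-series mixing matches the brute-force weighted sum", {
  for (m in 3:5) {
    b <- random_batch(m, d = 3, k = 3, seed = m)
    perms <- all_permutations(m)[seq_len(m), , drop = FALSE]
    out <- apply_zeta_mixup(b, gamma = 2.2, permutations = perms)
    expect_equal(out$features, brute_force_mix(b$features, 2.2, perms),
                 tolerance = 1e-12)
    expect_equal(unname(out$labels),
                 brute_force_mix(b$labels, 2.2, perms),
                 tolerance = 1e-12)
  }

  # spec of one hand-written row: ordering s = (2, 1, 3) at gamma = 2
  b3 <- random_batch(3, d = 2, k = 2, seed = 1)
  out <- apply_zeta_mixup(b3, gamma = 2,
                          permutations = rbind(c(2L, 1L, 3L), 1:3, 1:3))
  cval <- 1 + 2^-2 + 3^-2
  expect_equal(out$features[1, ],
               (2^-2 * b3$features[1, ] + b3$features[2, ] +
                  3^-2 * b3$features[3, ]) / cval,
               tolerance = 1e-14)
})

test_that("a batch of identical samples is a fixed point", {
  x <- matrix(rep(c(1.5, -2, 0.25), each = 6), nrow = 6)
  y <- matrix(rep(c(0.2, 0.8), each = 6), nrow = 6)
  b <- labeled_batch(x, y)
  out <- apply_zeta_mixup(b, gamma = 3, seed = 1)
  expect_equal(out$features, x, tolerance = 1e-12)
  expect_equal(out$labels, y, tolerance = 1e-12)
})

test_that("two-sample p-series mixing coincides with pairwise mixup", {
  b <- random_batch(2, d = 4, k = 3, seed = 3)
  set.seed(31)
  for (lam in runif(30, 0.01, 0.99)) {
    zeta_out <- apply_zeta_mixup(b, gamma = gamma_from_lambda(lam),
                                 permutations = rbind(1:2, 2:1),
                                 allow_subcritical = TRUE) |>
      suppressWarnings()
    mix_out <- mixup_pairwise(b, lambda = lam, partner = c(2L, 1L))
    expect_equal(zeta_out$features, mix_out$features, tolerance = 1e-12)
    expect_equal(zeta_out$labels, mix_out$labels, tolerance = 1e-12)
  }
})

test_that("pairwise mixup endpoints and soft labels behave", {
  b <- random_batch(6, d = 2, k = 4, seed = 8)
  out1 <- mixup_pairwise(b, lambda = 1, seed = 1)
  expect_equal(out1$features, b$features)
  expect_equal(out1$labels, b$labels)

  b2 <- labeled_batch(matrix(c(0, 0, 1, 1), nrow = 2),
                      c(0L, 1L), class_count = 2)
  half <- mixup_pairwise(b2, lambda = 0.5, partner = c(2L, 1L))
  expect_equal(unname(half$labels), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  soft <- mixup_pairwise(b2, lambda = 0.53, partner = c(2L, 1L))
  expect_equal(unname(soft$labels[1, ]), c(0.53, 0.47))

  expect_error(mixup_pairwise(b, lambda = 1.2), "lambda")
  expect_error(mixup_pairwise(b, alpha = -1), "alpha")
  expect_error(mixup_pairwise(b, partner = c(1L, 1L, 2L, 3L, 4L, 5L)),
               "permutation")
})

test_that("label support never exceeds min(T, K) classes", {
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(4:12, 1)
    k <- sample(2:6, 1)
    t_size <- sample(2:m, 1)
    b <- random_batch(m, d = 2, k = k)
    out <- apply_zeta_mixup(b, gamma = 2.8, group_size = t_size)
    support <- rowSums(out$labels > 1e-12)
    # a remainder of one sample is folded into the last group (size T + 1)
    bound <- t_size + as.integer(t_size < m && m %% t_size == 1L)
    expect_true(all(support <= min(bound, k)))
  }
  # pairwise baseline: at most 2 classes per output row
  b <- random_batch(10, d = 2, k = 5, seed = 2)
  out <- mixup_pairwise(b, seed = 2)
  expect_true(all(rowSums(out$labels > 1e-12) <= 2))
})

test_that("sub-batch grouping partitions the batch into disjoint groups", {
  # distinct one-hot classes make each output row's label support reveal
  # exactly which group of inputs it was mixed from
  m <- 10L
  b <- labeled_batch(matrix(rnorm(m * 2), nrow = m), 0:(m - 1L),
                     class_count = m)
  out <- apply_zeta_mixup(b, gamma = 2, group_size = 3L, seed = 9)
  expect_equal(nrow(out$features), m)
  supports <- apply(out$labels > 1e-12, 1, function(r) {
    paste(which(r), collapse = ",")
  })
  groups <- unique(supports)
  members <- lapply(strsplit(groups, ","), as.integer)
  # groups of sizes 3, 3, 4 (remainder of one folded into the last group)
  expect_setequal(lengths(members), c(3L, 3L, 4L))
  # disjoint cover of all 10 samples
  expect_setequal(unlist(members), 1:m)
  expect_equal(sum(lengths(members)), m)
  expect_error(apply_zeta_mixup(b, gamma = 3, group_size = 1L), "group_size")
  expect_error(apply_zeta_mixup(b, gamma = 3, group_size = 11L), "group_size")
})

test_that("sub-critical exponents are gated behind an explicit flag", {
  b <- random_batch(4, seed = 1)
  expect_error(apply_zeta_mixup(b, gamma = 1.5), "gamma_min")
  expect_warning(
    out <- apply_zeta_mixup(b, gamma = 1.5, allow_subcritical = TRUE,
                            seed = 1),
    "gamma_min")
  expect_equal(rowSums(out$labels), rep(1, 4), tolerance = 1e-9)
})

test_that("outputs_per_input replicates the batch with fresh permutations", {
  b <- random_batch(5, seed = 6)
  out <- apply_zeta_mixup(b, gamma = 2.4, seed = 3, outputs_per_input = 3L)
  expect_equal(nrow(out$features), 15L)
  expect_false(identical(out$features[1:5, ], out$features[6:10, ]))

  same1 <- apply_zeta_mixup(b, gamma = 2.4, seed = 12)
  same2 <- apply_zeta_mixup(b, gamma = 2.4, seed = 12)
  expect_identical(same1$features, same2$features)
})

test_that("Dirichlet mixing matches its distributional oracles", {
  # m = 2, unit concentration: first weight is uniform on [0, 1]
  b2 <- labeled_batch(matrix(c(0, 1, 0, 0), nrow = 2), c(0L, 1L),
                      class_count = 2)
  set.seed(14)
  w1 <- replicate(4000, dirichlet_mixing(b2)$features[1, 1])
  expect_gt(stats::ks.test(w1, "punif")$p.value, 0.01)

  # large symmetric concentration: weights approach uniform 1/m
  b <- random_batch(6, seed = 10)
  out <- dirichlet_mixing(b, concentration = 1e7, seed = 2)
  centroid <- colMeans(b$features)
  expect_lt(max(abs(sweep(out$features, 2, centroid))), 0.01)

  # m = 128, all-ones concentration: no dominant sample on average;
  # Monte-Carlo oracle for E[max Dirichlet(1,...,1)] = H_128 / 128 ~ 0.042
  set.seed(15)
  g <- matrix(rgamma(200 * 128, 1), nrow = 200)
  mc <- mean(apply(g / rowSums(g), 1, max))
  expect_lt(mc, 0.1)
  b128 <- random_batch(128, seed = 16)
  out128 <- dirichlet_mixing(b128, seed = 3)
  expect_equal(rowSums(out128$labels), rep(1, 128), tolerance = 1e-9)

  expect_error(dirichlet_mixing(b, concentration = c(1, -1)), "positive")
})
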