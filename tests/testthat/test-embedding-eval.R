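test_that("mean contextual embeddings equal hand-computed averages of encoder states", {
  tm <- tiny_model(head = "token_binary")
  m <- tm$model
  s1 <- c(1L, 4L, 6L)
  s2 <- c(1L, 6L, 5L, 4L)
  tab <- mean_contextual_embeddings(m, list(s1, s2), top_n = 10L, vocab = tm$vocab)
  e1 <- encode(m, s1); e2 <- encode(m, s2)
  ## taxon index 4 appears at position 2 of s1 and position 4 of s2
  manual4 <- (e1$token_states[2, ] + e2$token_states[4, ]) / 2
  expect_lt(max(abs(tab$embeddings["t01", ] - manual4)), 1e-9)
  ## taxon 5 occurs once: mean equals that single state
  expect_lt(max(abs(tab$embeddings["t02", ] - e2$token_states[3, ])), 1e-9)
  expect_identical(unname(tab$counts[c("t01", "t02", "t03")]), c(2L, 1L, 2L))
  ## duplicating the corpus leaves the means unchanged
  tab2 <- mean_contextual_embeddings(m, list(s1, s2, s1, s2), top_n = 10L, vocab = tm$vocab)
  expect_equal(tab$embeddings, tab2$embeddings, tolerance = 1e-12)
  ## top_n restriction keeps the most frequent taxa (ties by index)
  tab3 <- mean_contextual_embeddings(m, list(s1, s2), top_n = 1L, vocab = tm$vocab)
  expect_identical(rownames(tab3$embeddings), "t01")
})

test_that("purity is the modal frequency at k = 1, perfect at k = N, and finds pure blobs", {
  set.seed(19)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(b) {
    sweep(matrix(rnorm(30 * 2, sd = 0.3), 30, 2), 2, centers[b, ], `+`)
  }))
  rownames(X) <- sprintf("p%03d", 1:90)
  labs <- rep(c("A", "B", "C"), each = 30)
  pc <- purity_curve(X, labs, k_values = c(1L, 3L, 90L), seed = 4L)
  expect_equal(pc$purity[pc$k == 1], 1 / 3)
  expect_equal(pc$purity[pc$k == 3], 1)
  expect_equal(pc$purity[pc$k == 90], 1)
  ## shuffled labels: purity near the modal class frequency
  set.seed(20)
  pc2 <- purity_curve(X, sample(labs), k_values = 3L, seed = 4L)
  expect_lt(pc2$purity, 0.55)
  ## purity non-decreasing in k on a fixed fixture
  pc3 <- purity_curve(X, labs, k_values = c(2L, 4L, 8L, 16L), seed = 4L)
  expect_true(!is.unsorted(pc3$purity))
  expect_error(purity_curve(X, c(labs[-1], NA), k_values = 2L), "unlabeled")
})

test_that("pathway correlations match a rank-then-Pearson brute force within 1e-9", {
  set.seed(23)
  n <- 10
  E <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("t%02d", 1:n), NULL))
  P <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
              dimnames = list(rownames(E), sprintf("pw%d", 1:3)))
  P[, 3] <- 1  # constant column: undefined rank correlation -> 0 + flag
  res <- pathway_correlations(E, P)
  brute <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:2) {
    brute[i, j] <- stats::cor(rank(E[, i]), rank(P[, j]))
  }
  expect_lt(max(abs(res$r[, 1:2] - brute[, 1:2])), 1e-9)
  expect_identical(unname(res$constant), c(FALSE, FALSE, TRUE))
  expect_identical(unname(res$r[, 3]), rep(0, 4))
  ## dim equal to a pathway column -> r = 1; its negation -> r = -1
  E2 <- cbind(P[, 1] + 0, -P[, 1]); rownames(E2) <- rownames(P)
  res2 <- pathway_correlations(E2, P)
  expect_equal(unname(res2$r[1, 1]), 1)
  expect_equal(unname(res2$r[2, 1]), -1)
})

test_that("Spearman screening is invariant to monotone transforms of a dimension", {
  set.seed(29)
  E <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("t%02d", 1:20), NULL))
  P <- matrix(rbinom(40, 1, 0.4), 20, 2, dimnames = list(rownames(E), c("a", "b")))
  r1 <- pathway_correlations(E, P)$r
  E2 <- E; E2[, 1] <- E2[, 1]^3
  r2 <- pathway_correlations(E2, P)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("permutation mask flags a planted perfect pair and stays quiet under the null", {
  set.seed(31)
  n <- 60
  E <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("t%02d", 1:n), NULL))
  P <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
              dimnames = list(rownames(E), sprintf("pw%d", 1:4)))
  E[, 2] <- P[, 3]  # planted perfect dim-pathway pair
  res <- permutation_mask(E, P, n_perm = 300L, seed = 6L)
  expect_true(res$mask[2, 3])
  ## per-cell variant also flags it
  res2 <- permutation_mask(E, P, n_perm = 300L, seed = 6L, method = "per_cell")
  expect_true(res2$mask[2, 3])
  ## fully independent inputs: pooled-max criterion flags (almost) nothing
  set.seed(32)
  E0 <- matrix(rnorm(n * 5), n, 5, dimnames = dimnames(E))
  res0 <- permutation_mask(E0, P, n_perm = 300L, seed = 7L)
  expect_lte(mean(res0$mask), 0.005)
})

test_that("two-sample magnitude comparison reproduces reference statistics", {
  ## frozen oracle values computed with an independent reference
  ## implementation of the KS and Epps-Singleton tests
  a <- c(0.307545, 0.060593, 0.459701, 0.112761, 0.157036, 0.464352, 0.226414,
         0.26894, 0.251941, 0.197639, 0.492935, 0.054368, 0.083613, 0.17491,
         0.113432, 0.225141, 0.267855, 0.422463, 0.491631, 0.497537, 0.20994,
         0.34141, 0.360151, 0.419698, 0.283875, 0.424323, 0.098409, 0.221696,
         0.205039, 0.270971, 0.558228, 0.406419, 0.215321, 0.36621, 0.017667,
         0.202978, 0.222323, 0.553259, 0.138345, 0.549469)
  b <- c(0.604654, 0.717867, 0.569812, 0.466404, 0.757631, 0.347834, 0.301107,
         0.238107, 0.268804, 0.448496, 0.698069, 0.529537, 0.560196, 0.129455,
         0.129624, 0.434926, 0.555954, 0.365585, 0.36101, 0.180381, 0.139669,
         0.139814, 0.411072, 0.377361, 0.453698, 0.595312, 0.375383, 0.31033,
         0.325229, 0.193143)
  es <- epps_singleton_test(a, b)
  expect_equal(es$statistic, 9.168844559813182, tolerance = 1e-8)
  expect_equal(es$p_value, 0.057014976838199574, tolerance = 1e-8)
  rep_ <- compare_magnitude_distributions(a, b)
  expect_equal(rep_$ks_p, 0.03567105794761462, tolerance = 1e-8)
  expect_equal(rep_$es_p, es$p_value)

  ## small-sample correction branch
  a2 <- c(0.755792, 0.077412, -2.920857, 3.121594, 0.001428, -0.55162, 1.315186,
          1.484725, -0.570278, -0.832037, -0.88649, 0.349831)
  b2 <- c(0.96326, 1.584057, 0.68613, 0.287514, 0.919224, 0.228599, 1.459999,
          1.216856, 1.356145, 1.252313, 0.380715, -0.923072, 2.067223, 1.884905,
          0.056302)
  es2 <- epps_singleton_test(a2, b2)
  expect_equal(es2$statistic, 6.203698719492086, tolerance = 1e-8)
  expect_equal(es2$p_value, 0.18444362377661128, tolerance = 1e-8)
})

test_that("Cliff's delta matches the pairwise count definition and its edge cases", {
  set.seed(37)
  a <- rnorm(20); b <- rnorm(17, 0.4)
  brute <- (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) / (length(a) * length(b))
  expect_equal(cliffs_delta(a, b), brute, tolerance = 1e-12)
  expect_equal(cliffs_delta(a, a), 0)
  expect_equal(cliffs_delta(b + 100, a), 1)
  expect_equal(cliffs_delta(a, b + 100), -1)
  ## fewer than 5 values: Epps-Singleton omitted with warning
  expect_warning(out <- compare_magnitude_distributions(a[1:3], b), "Epps-Singleton")
  expect_true(is.na(out$es_p))
})
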