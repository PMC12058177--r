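test_that("masking selects round(rate * n) taxa, never CLS, with a floor of one", {
  vocab <- tiny_vocab(12)
  set.seed(4)
  s100 <- c(1L, sample(rep(4:15, 9), 100))  # length 101 incl CLS
  mk <- mask_sample(s100, 0.15, seed = 1L)
  expect_length(mk$plan$positions, 15L)
  expect_true(all(mk$plan$positions >= 2))
  expect_true(all(mk$tokens[mk$plan$positions] == 2L))
  expect_identical(mk$tokens[-mk$plan$positions], s100[-mk$plan$positions])

  one <- c(1L, 4L)
  mk1 <- mask_sample(one, 0.15, seed = 1L)
  expect_length(mk1$plan$positions, 1L)

  cls_only <- 1L
  mk0 <- mask_sample(cls_only, 0.15, seed = 1L)
  expect_identical(mk0$tokens, cls_only)
  expect_length(mk0$plan$positions, 0L)

  expect_identical(mask_sample(s100, 0.15, seed = 9L), mask_sample(s100, 0.15, seed = 9L))
})

test_that("replacement labels satisfy modified <=> emitted token differs from original", {
  tm <- tiny_model(head = "token_vocab")
  set.seed(5)
  for (i in 1:25) {
    s <- rand_seq(tm$vocab, sample(3:9, 1))
    mk <- mask_sample(s, 0.3, seed = i)
    rp <- generate_replacements(tm$model, mk, seed = i + 100L)
    expect_length(rp$tokens, length(s))
    expect_identical(rp$modified, rp$tokens != s)
    expect_false(rp$modified[1])
    ## unmasked positions untouched
    unmasked <- setdiff(seq_along(s), mk$plan$positions)
    expect_identical(rp$tokens[unmasked], s[unmasked])
  }
  ## empty plan: identity, all labels real
  mk0 <- list(tokens = c(1L, 4L), plan = list(positions = integer(0), original = integer(0)))
  rp0 <- generate_replacements(tm$model, mk0)
  expect_identical(rp0$tokens, c(1L, 4L))
  expect_false(any(rp0$modified))
  ## determinism
  s <- rand_seq(tm$vocab, 6)
  mk <- mask_sample(s, 0.3, seed = 2L)
  expect_identical(generate_replacements(tm$model, mk, seed = 5L),
                   generate_replacements(tm$model, mk, seed = 5L))
})

test_that("a uniform generator relabels masked positions as real at rate 1/vocab", {
  vocab <- taxon_vocabulary(sprintf("u%03d", 1:100))
  set.seed(6)
  emb <- matrix(rnorm(100 * 8), 100, 8, dimnames = list(vocab$taxon_ids, NULL))
  cfg <- model_config(vocab$size, embed_dim = 8L, hidden_dim = 16L, n_blocks = 1L,
                      n_heads = 2L, ff_dim = 32L, max_positions = 20L,
                      head_hidden = 12L, dropout = 0)
  m <- build_model(cfg, vocab, emb, head = "token_vocab", seed = 2L)
  m$params$head_W2[] <- 0; m$params$head_b2[] <- 0  # force uniform output
  n_real <- 0L; n_masked <- 0L
  for (i in 1:600) {
    s <- c(1L, sample(4:103, 15))
    mk <- mask_sample(s, 0.95, seed = i)
    rp <- generate_replacements(m, mk, seed = i)
    n_masked <- n_masked + length(mk$plan$positions)
    n_real <- n_real + sum(!rp$modified[mk$plan$positions])
  }
  expect_gt(n_masked, 8000)
  expect_equal(n_real / n_masked, 1 / 100, tolerance = 0.35)
})

test_that("the reference curriculum consumes its checkpoints in order", {
  sch <- pretrain_schedule()  # 240 / 30 / 120 / 15
  expect_identical(sch$generator_epochs %/% sch$generator_checkpoint_every, 8L)
  expect_identical(sch$discriminator_epochs %/% sch$generator_swap_every, 8L)
  ## mismatched counts are rejected at construction
  expect_error(pretrain_schedule(240L, 30L, 120L, 10L), "mismatch")

  ## a scaled curriculum with the same 8-checkpoint structure runs in order
  tm <- tiny_model(head = "token_vocab")
  sch2 <- pretrain_schedule(8L, 1L, 8L, 1L, batch_size = 8L, lr = 1e-3)
  set.seed(12)
  corpus <- lapply(1:16, function(i) rand_seq(tm$vocab, sample(4:9, 1)))
  gtr <- train_generator(tm$model, corpus, sch2, seed = 3L)
  expect_length(gtr$checkpoints, 8L)
  disc <- tiny_model(head = "token_binary")$model
  dtr <- train_discriminator(disc, corpus, gtr$checkpoints, sch2, seed = 4L)
  expect_equal(dtr$history$checkpoint, 1:8)
  expect_error(train_discriminator(disc, corpus, gtr$checkpoints[1:3], sch2),
               "need 8")
})

test_that("generator training reduces loss and recovers a planted co-occurrence", {
  ## taxon B always accompanies taxon A; after training, masking B while A is
  ## present should recover B far above the uniform rate
  vocab <- taxon_vocabulary(sprintf("p%02d", 1:20))
  set.seed(31)
  emb <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(vocab$taxon_ids, NULL))
  cfg <- model_config(vocab$size, embed_dim = 8L, hidden_dim = 16L, n_blocks = 1L,
                      n_heads = 2L, ff_dim = 32L, max_positions = 12L,
                      head_hidden = 16L, dropout = 0)
  gen <- build_model(cfg, vocab, emb, head = "token_vocab", seed = 17L)
  A <- 4L; B <- 5L
  corpus <- lapply(1:200, function(i) {
    others <- sample(6:23, 4)
    c(1L, sample(c(A, B, others)))
  })
  sch <- pretrain_schedule(10L, 5L, 10L, 5L, batch_size = 16L, lr = 3e-3)
  gtr <- train_generator(gen, corpus, sch, seed = 8L)
  expect_lt(gtr$history$train_loss[10], gtr$history$train_loss[1])

  hits <- 0L
  for (i in 1:50) {
    s <- corpus[[i]]
    masked <- s; masked[which(s == B)] <- 2L
    pr <- token_predictions(gen, masked)
    hits <- hits + (which.max(pr[which(s == B), ]) == B - 3L)
  }
  expect_gt(hits / 50, 3 / 20)  # >> 1/20 uniform
})

test_that("masked-token metrics are reproducible and bounded", {
  tm <- tiny_model(head = "token_vocab")
  set.seed(14)
  corpus <- lapply(1:10, function(i) rand_seq(tm$vocab, sample(4:9, 1)))
  m1 <- masked_token_metrics(tm$model, corpus, seed = 5L)
  m2 <- masked_token_metrics(tm$model, corpus, seed = 5L)
  expect_identical(m1, m2)
  expect_gte(m1$top1, 0); expect_lte(m1$top1, 1)
  expect_gt(m1$loss, 0)
})
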