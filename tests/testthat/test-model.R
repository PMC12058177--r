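test_that("analytic gradients match finite differences on a tiny encoder", {
  tm <- tiny_model(head = "token_vocab", seed = 7L)
  m <- tm$model
  seqs <- list(c(1L, 4L, 6L, 9L), c(1L, 5L, 7L, 10L, 11L))
  pb <- taxaformer:::pad_batch(seqs)
  rows <- c(1L + 2L * 1L, 2L + 2L * 2L)  # (seq 1, pos 2), (seq 2, pos 3)
  targ <- c(3L, 5L)
  loss_fn <- function(model) {
    fwd <- taxaformer:::forward_encoder(model, pb$tok, pb$lens, keep_cache = FALSE)
    hf <- taxaformer:::head_forward(model, fwd$H[rows, , drop = FALSE])
    p <- taxaformer:::softmax_rows(hf$logits)
    -mean(log(p[cbind(seq_along(targ), targ)]))
  }
  fwd <- taxaformer:::forward_encoder(m, pb$tok, pb$lens, keep_cache = TRUE)
  hf <- taxaformer:::head_forward(m, fwd$H[rows, , drop = FALSE])
  p <- taxaformer:::softmax_rows(hf$logits)
  dlog <- p
  dlog[cbind(seq_along(targ), targ)] <- dlog[cbind(seq_along(targ), targ)] - 1
  dlog <- dlog / length(targ)
  hb <- taxaformer:::head_backward(m, hf, fwd$H[rows, , drop = FALSE], dlog)
  dH <- matrix(0, nrow(fwd$H), ncol(fwd$H)); dH[rows, ] <- hb$dH
  g <- taxaformer:::backward_encoder(m, fwd, dH)
  g[names(hb$grads)] <- hb$grads

  eps <- 1e-5
  set.seed(42)
  for (nm in c("proj_W", "pos", "b1.Wq", "b1.Wv", "b1.ln1_g", "b1.W1", "b2.W2",
               "b2.ln2_b", "lnf_g", "head_W1", "head_b2")) {
    for (idx in sample(length(m$params[[nm]]), 2)) {
      p0 <- m$params[[nm]][idx]
      m$params[[nm]][idx] <- p0 + eps; lp <- loss_fn(m)
      m$params[[nm]][idx] <- p0 - eps; lm_ <- loss_fn(m)
      m$params[[nm]][idx] <- p0
      num <- (lp - lm_) / (2 * eps)
      expect_equal(g[[nm]][idx], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, idx))
    }
  }
  ## CLS embedding row gets a gradient, frozen taxon rows do not
  expect_gt(sum(abs(g$emb[1, ])), 0)
  expect_identical(sum(abs(g$emb[4:nrow(g$emb), ])), 0)
})

test_that("model building is deterministic and parameter count matches closed form", {
  tm1 <- tiny_model(head = "token_vocab", seed = 9L)
  tm2 <- tiny_model(head = "token_vocab", seed = 9L)
  expect_identical(param_digest(tm1$model), param_digest(tm2$model))
  tm3 <- tiny_model(head = "token_vocab", seed = 10L)
  expect_false(identical(param_digest(tm1$model), param_digest(tm3$model)))

  cfg <- tm1$cfg
  V <- cfg$vocab_size; E <- cfg$embed_dim; H <- cfg$hidden_dim
  FF <- cfg$ff_dim; P <- cfg$max_positions; HH <- cfg$head_hidden
  n_taxa <- V - 3L
  per_block <- 4 * (H * H + H) +        # Q,K,V,O projections + biases
    2 * (2 * H) +                        # two layer norms (gain + bias)
    H * FF + FF + FF * H + H             # feed-forward
  expected <- V * E +                    # embedding table
    E * H + H +                          # projection
    P * H +                              # positional embeddings
    cfg$n_blocks * per_block +
    2 * H +                              # final layer norm
    H * HH + HH + HH * n_taxa + n_taxa   # two-layer vocabulary head
  expect_equal(n_params(tm1$model), expected)
})

test_that("inference is deterministic, position-sensitive, and accepts [CLS] alone", {
  tm <- tiny_model(head = "cls_binary", dropout = 0.1)
  m <- tm$model
  s <- c(1L, 4L, 7L, 9L, 11L)
  e1 <- encode(m, s); e2 <- encode(m, s)
  expect_identical(e1$token_states, e2$token_states)

  swapped <- s; swapped[c(2, 4)] <- swapped[c(4, 2)]
  e3 <- encode(m, swapped)
  expect_gt(max(abs(e1$cls_state - e3$cls_state)), 1e-8)

  e4 <- encode(m, 1L)
  expect_identical(dim(e4$token_states), c(1L, 16L))
  expect_true(all(is.finite(e4$cls_state)))
})

test_that("classification head yields probabilities and sigmoid(0) = 0.5 with zeroed output layer", {
  tm <- tiny_model(head = "cls_binary")
  m <- tm$model
  set.seed(3)
  seqs <- lapply(1:50, function(i) rand_seq(tm$vocab, sample(2:8, 1)))
  p <- classify_sample(m, seqs)
  expect_true(all(p >= 0 & p <= 1))
  m$params$head_W2[] <- 0; m$params$head_b2[] <- 0
  expect_equal(classify_sample(m, seqs[[1]]), 0.5)
  expect_error(token_predictions(m, seqs[[1]]), "token-level")
})

test_that("token-level heads return normalized or bounded predictions of input length", {
  tmg <- tiny_model(head = "token_vocab")
  s <- c(1L, 4L, 6L, 8L)
  pg <- token_predictions(tmg$model, s)
  expect_identical(dim(pg), c(4L, 12L))
  expect_equal(unname(rowSums(pg)), rep(1, 4), tolerance = 1e-6)

  tmd <- tiny_model(head = "token_binary")
  pd <- token_predictions(tmd$model, s)
  expect_length(pd, 4L)
  expect_true(all(pd >= 0 & pd <= 1))
  expect_error(classify_sample(tmd$model, s), "cls_binary")

  ## masking a position changes predictions, never input length
  s2 <- s; s2[3] <- 2L
  pg2 <- token_predictions(tmg$model, s2)
  expect_identical(dim(pg2), dim(pg))
  expect_false(identical(pg, pg2))
})

test_that("frozen taxon embeddings stay bit-identical through pre-training steps", {
  tm <- tiny_model(head = "token_vocab", dropout = 0.1)
  m <- tm$model
  emb_before <- m$params$emb
  sch <- pretrain_schedule(2L, 1L, 2L, 1L, batch_size = 4L, lr = 1e-2)
  set.seed(8)
  corpus <- lapply(1:12, function(i) rand_seq(tm$vocab, sample(3:8, 1)))
  train_generator(m, corpus, sch, seed = 2L)
  taxa_rows <- 4:nrow(emb_before)
  expect_identical(m$params$emb[taxa_rows, ], emb_before[taxa_rows, ])
  ## trainable CLS/MASK rows did move
  expect_false(identical(m$params$emb[1:2, ], emb_before[1:2, ]))
  ## PAD row pinned at zero
  expect_identical(unname(m$params$emb[3, ]), rep(0, tm$cfg$embed_dim))
})

test_that("overlong sequences are rejected and checkpoints verify the vocabulary hash", {
  tm <- tiny_model(head = "cls_binary")
  too_long <- c(1L, rep(4:11, 3))
  expect_error(encode(tm$model, too_long), "max_positions")

  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(tm$model, f)
  back <- load_checkpoint(f, tm$vocab)
  expect_identical(param_digest(back), param_digest(tm$model))
  other <- taxon_vocabulary(c("u1", "u2"))
  expect_error(load_checkpoint(f, other), "different vocabulary")
})

test_that("hidden states have the configured width at every block", {
  tm <- tiny_model(head = "cls_binary")
  e <- encode(tm$model, c(1L, 4L, 5L))
  expect_identical(ncol(e$token_states), tm$cfg$hidden_dim)
  expect_length(e$cls_state, tm$cfg$hidden_dim)
})
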