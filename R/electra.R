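## ELECTRA-style self-supervised pre-training. A generator learns to fill in
## masked taxa from community context; a discriminator learns to tell
## original taxa from generator substitutes. The discriminator's encoder is
## the universal sample encoder used downstream. Difficulty is ramped by a
## checkpoint curriculum: the discriminator's inputs come from successively
## better-trained generator checkpoints.

#' Pre-training schedule
#'
#' Default curriculum: the generator trains for 240
#' epochs with a checkpoint every 30; the discriminator trains for 120
#' epochs and swaps to the next stronger generator checkpoint every 15, so
#' the 8 checkpoints are consumed in training order.
#'
#' @param generator_epochs total generator epochs
#' @param generator_checkpoint_every checkpoint interval (epochs)
#' @param discriminator_epochs total discriminator epochs
#' @param generator_swap_every discriminator epochs per generator checkpoint
#' @param mask_rate fraction of taxa masked per sample
#' @param batch_size minibatch size
#' @param lr Adam learning rate for both models
#' @return a `pretrain_schedule` list
#' @export
pretrain_schedule <- function(generator_epochs = 240L,
                              generator_checkpoint_every = 30L,
                              discriminator_epochs = 120L,
                              generator_swap_every = 15L,
                              mask_rate = 0.15, batch_size = 32L, lr = 1e-4) {
  stopifnot(is_count(generator_epochs), is_count(generator_checkpoint_every),
            is_count(discriminator_epochs), is_count(generator_swap_every),
            mask_rate > 0, mask_rate < 1, is_count(batch_size), lr > 0)
  n_ckpt <- generator_epochs %/% generator_checkpoint_every
  n_swap <- discriminator_epochs / generator_swap_every
  if (n_swap != round(n_swap) || n_swap != n_ckpt) {
    stopf("schedule mismatch: %d checkpoints but %.2f discriminator phases",
          n_ckpt, n_swap)
  }
  structure(list(
    generator_epochs = as.integer(generator_epochs),
    generator_checkpoint_every = as.integer(generator_checkpoint_every),
    discriminator_epochs = as.integer(discriminator_epochs),
    generator_swap_every = as.integer(generator_swap_every),
    mask_rate = mask_rate, batch_size = as.integer(batch_size), lr = lr
  ), class = "pretrain_schedule")
}

#' Mask taxa in a token sequence
#'
#' Selects `round(mask_rate * n_taxa)` positions (half-up, at least 1 when
#' any taxon is present; CLS is never masked) and replaces them with the
#' MASK token. Uses the current RNG state unless `seed` is given.
#'
#' @param tokens token sequence (CLS first)
#' @param mask_rate fraction of taxon tokens to mask
#' @param seed optional seed for reproducible masking
#' @return list with `tokens` (masked sequence) and `plan` (integer
#'   positions masked and their original token indices)
#' @export
mask_sample <- function(tokens, mask_rate = 0.15, seed = NULL) {
  stopifnot(mask_rate > 0, mask_rate < 1)
  n <- length(tokens) - 1L
  if (n <= 0) {
    return(list(tokens = tokens,
                plan = list(positions = integer(0), original = integer(0))))
  }
  k <- max(1L, as.integer(round_half_up(mask_rate * n)))
  pos <- with_seed(seed, sort(sample_vec(seq.int(2L, n + 1L), k)))
  out <- tokens
  orig <- out[pos]
  out[pos] <- 2L  # MASK
  list(tokens = out, plan = list(positions = pos, original = orig))
}

## Flat row index of (batch element b, position l) in the (B*L) x h layout.
flat_rows <- function(b, l, B) b + B * (l - 1L)

## Sample one class per row from a matrix of unnormalized log-probabilities
## using the Gumbel-max trick (vectorized, consumes nrow*ncol uniforms).
sample_rows_gumbel <- function(logp) {
  g <- -log(-log(matrix(runif(length(logp)), nrow(logp), ncol(logp))))
  max.col(logp + g, ties.method = "first")
}

#' Fill masked positions with generator predictions
#'
#' Each masked position is replaced by a draw from the generator's predicted
#' taxon distribution at that position. Every position is labeled `real` or
#' `modified`: unmasked positions are always real, and a masked position is
#' real iff the generator happened to re-emit the original taxon.
#'
#' @param generator an `encoder_model` with a `token_vocab` head
#' @param masked list as returned by [mask_sample()] (masked tokens + plan)
#' @param seed optional seed for the draws
#' @return list with `tokens` (replaced sequence) and `modified` (logical
#'   per position, CLS included as FALSE)
#' @export
generate_replacements <- function(generator, masked, seed = NULL) {
  if (generator$head_kind != "token_vocab") stopf("generator must have a token_vocab head")
  tokens <- masked$tokens
  plan <- masked$plan
  if (length(plan$positions) == 0) {
    return(list(tokens = tokens, modified = rep(FALSE, length(tokens))))
  }
  if (any(tokens[plan$positions] != 2L)) stopf("plan does not match masked sequence")
  probs <- token_predictions(generator, tokens)
  draw <- with_seed(seed, {
    sample_rows_gumbel(log(probs[plan$positions, , drop = FALSE] + 1e-300))
  })
  out <- tokens
  out[plan$positions] <- as.integer(draw) + 3L
  modified <- rep(FALSE, length(tokens))
  modified[plan$positions] <- out[plan$positions] != plan$original
  list(tokens = out, modified = modified)
}

## Internal: mask + (optionally) replace a batch of sequences. Consumes the
## current RNG stream. Returns padded tokens, lens, and flat-index/label
## vectors for the loss.
batch_mask <- function(seqs, mask_rate) {
  masked <- lapply(seqs, function(s) mask_sample(s, mask_rate))
  pb <- pad_batch(lapply(masked, `[[`, "tokens"))
  B <- length(seqs)
  rows <- integer(0); targ <- integer(0)
  for (b in seq_len(B)) {
    p <- masked[[b]]$plan
    rows <- c(rows, flat_rows(b, p$positions, B))
    targ <- c(targ, p$original - 3L)
  }
  list(pb = pb, masked = masked, rows = rows, targets = targ)
}

batch_replace <- function(generator, bm) {
  B <- nrow(bm$pb$tok)
  fwd <- forward_encoder(generator, bm$pb$tok, bm$pb$lens, train = FALSE, keep_cache = FALSE)
  if (length(bm$rows) > 0) {
    hf <- head_forward(generator, fwd$H[bm$rows, , drop = FALSE])
    logits <- hf$logits
    draw <- sample_rows_gumbel(logits)  # Gumbel-max on logits == softmax draw
    tok <- bm$pb$tok
    tok[cbind((bm$rows - 1L) %% B + 1L, (bm$rows - 1L) %/% B + 1L)] <- as.integer(draw) + 3L
    modified <- as.integer(draw) != bm$targets
  } else {
    tok <- bm$pb$tok; modified <- logical(0)
  }
  list(tok = tok, lens = bm$pb$lens, rows = bm$rows, modified = modified)
}

## Cross-entropy generator loss/step on one batch. Returns loss.
generator_step <- function(model, seqs, mask_rate, opt) {
  bm <- batch_mask(seqs, mask_rate)
  fwd <- forward_encoder(model, bm$pb$tok, bm$pb$lens, train = TRUE, keep_cache = TRUE)
  Hm <- fwd$H[bm$rows, , drop = FALSE]
  hf <- head_forward(model, Hm)
  p <- softmax_rows(hf$logits)
  nmask <- length(bm$rows)
  loss <- -mean(log(p[cbind(seq_len(nmask), bm$targets)] + 1e-12))
  dlog <- p
  dlog[cbind(seq_len(nmask), bm$targets)] <- dlog[cbind(seq_len(nmask), bm$targets)] - 1
  dlog <- dlog / nmask
  hb <- head_backward(model, hf, Hm, dlog)
  dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
  dH[bm$rows, ] <- hb$dH
  grads <- backward_encoder(model, fwd, dH)
  grads[names(hb$grads)] <- hb$grads
  opt_step(model, opt, grads)
  loss
}

## Binary cross-entropy discriminator loss/step on one replaced batch.
## The loss covers every taxon position (CLS and PAD excluded): unmasked
## positions are real negatives, replaced positions are labeled by whether
## the generator actually changed the taxon. Classes are re-weighted to
## equal total weight within the batch: only ~mask_rate of positions are
## replaced, and without the re-weighting the per-position loss is
## dominated by the "real" majority and the model collapses to predicting
## it everywhere.
discriminator_step <- function(model, rep_batch, opt) {
  B <- nrow(rep_batch$tok); lens <- rep_batch$lens
  rows <- unlist(lapply(seq_len(B), function(b) {
    if (lens[b] > 1) flat_rows(b, seq.int(2L, lens[b]), B) else integer(0)
  }))
  y <- numeric(length(rows))
  y[match(rep_batch$rows, rows)] <- as.numeric(rep_batch$modified)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  w <- ifelse(y == 1, 0.5 / max(n1, 1), 0.5 / max(n0, 1))
  fwd <- forward_encoder(model, rep_batch$tok, lens, train = TRUE, keep_cache = TRUE)
  Hm <- fwd$H[rows, , drop = FALSE]
  hf <- head_forward(model, Hm)
  p <- as.vector(sigmoid(hf$logits))
  loss <- -sum(w * (y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)))
  dlogit <- matrix(w * (p - y), ncol = 1)
  hb <- head_backward(model, hf, Hm, dlogit)
  dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
  dH[rows, ] <- hb$dH
  grads <- backward_encoder(model, fwd, dH)
  grads[names(hb$grads)] <- hb$grads
  opt_step(model, opt, grads)
  loss
}

chunk_indices <- function(n, size) split(seq_len(n), ceiling(seq_len(n) / size))

#' Train the masked-taxon generator
#'
#' Trains with cross-entropy on masked positions only; masking is
#' re-randomized every epoch. Snapshots of the model are taken every
#' `generator_checkpoint_every` epochs and returned in training order
#' (weakest first) for the discriminator curriculum.
#'
#' @param model an `encoder_model` with a `token_vocab` head
#' @param corpus list of token sequences
#' @param schedule a [pretrain_schedule()]
#' @param val_corpus optional held-out sequences; per-epoch validation loss
#'   and masked top-1 accuracy are logged
#' @param seed seed controlling shuffling, masking and dropout
#' @return list with `model`, `checkpoints` (ordered list of model
#'   snapshots) and `history` (per-epoch data.frame)
#' @export
train_generator <- function(model, corpus, schedule, val_corpus = NULL, seed = 1L) {
  if (model$head_kind != "token_vocab") stopf("generator must have a token_vocab head")
  if (length(corpus) == 0) stopf("empty corpus")
  set_trainable(model, "pretrain")
  opt <- opt_init(model, "adam", lr = schedule$lr)
  checkpoints <- list()
  hist <- vector("list", schedule$generator_epochs)
  for (epoch in seq_len(schedule$generator_epochs)) {
    ep_loss <- with_seed(derive_seed(seed, paste0("gen", epoch)), {
      ord <- sample(length(corpus))
      losses <- vapply(chunk_indices(length(ord), schedule$batch_size), function(ix) {
        generator_step(model, corpus[ord[ix]], schedule$mask_rate, opt)
      }, numeric(1))
      mean(losses)
    })
    val <- if (!is.null(val_corpus)) {
      masked_token_metrics(model, val_corpus, schedule$mask_rate,
                           seed = derive_seed(seed, "genval"))
    } else {
      list(loss = NA_real_, top1 = NA_real_)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val$loss, val_top1 = val$top1)
    if (epoch %% schedule$generator_checkpoint_every == 0) {
      checkpoints[[length(checkpoints) + 1L]] <- clone_model(model)
    }
  }
  list(model = model, checkpoints = checkpoints, history = do.call(rbind, hist))
}

#' Masked-token prediction metrics
#'
#' Masks a corpus with a fixed seed and scores the generator's masked-token
#' cross-entropy and top-1 recovery accuracy (inference mode).
#'
#' @param model generator model
#' @param corpus list of token sequences
#' @param mask_rate masking rate
#' @param seed seed fixing which positions are masked
#' @param batch_size inference batch size
#' @return list with `loss` and `top1`
#' @export
masked_token_metrics <- function(model, corpus, mask_rate = 0.15, seed = 1L,
                                 batch_size = 64L) {
  tot_ll <- 0; tot_top1 <- 0; tot_n <- 0
  with_seed(seed, {
    for (ix in chunk_indices(length(corpus), batch_size)) {
      bm <- batch_mask(corpus[ix], mask_rate)
      fwd <- forward_encoder(model, bm$pb$tok, bm$pb$lens, train = FALSE, keep_cache = FALSE)
      hf <- head_forward(model, fwd$H[bm$rows, , drop = FALSE])
      p <- softmax_rows(hf$logits)
      n <- length(bm$rows)
      tot_ll <- tot_ll - sum(log(p[cbind(seq_len(n), bm$targets)] + 1e-12))
      tot_top1 <- tot_top1 + sum(max.col(p, ties.method = "first") == bm$targets)
      tot_n <- tot_n + n
    }
  })
  list(loss = tot_ll / tot_n, top1 = tot_top1 / tot_n)
}

#' Train the replaced-taxon discriminator
#'
#' Every epoch, the corpus is re-masked and masked positions are filled by
#' the current generator checkpoint; the discriminator is trained with
#' binary cross-entropy over all taxon positions to label each taxon as
#' original or generator-modified. The generator is swapped for the next
#' stronger checkpoint every `generator_swap_every` epochs, in order.
#'
#' @param model an `encoder_model` with a `token_binary` head
#' @param corpus list of token sequences
#' @param checkpoints generator checkpoints ordered weakest to strongest
#' @param schedule a [pretrain_schedule()]
#' @param val_corpus optional held-out sequences; per-epoch balanced
#'   accuracy on replaced-vs-real is logged
#' @param seed seed controlling shuffling, masking, replacement and dropout
#' @return list with `model` and `history` (per-epoch data.frame including
#'   the checkpoint index used)
#' @export
train_discriminator <- function(model, corpus, checkpoints, schedule,
                                val_corpus = NULL, seed = 1L) {
  if (model$head_kind != "token_binary") stopf("discriminator must have a token_binary head")
  n_need <- schedule$discriminator_epochs %/% schedule$generator_swap_every
  if (length(checkpoints) < n_need) {
    stopf("need %d generator checkpoints, got %d", n_need, length(checkpoints))
  }
  set_trainable(model, "pretrain")
  opt <- opt_init(model, "adam", lr = schedule$lr)
  hist <- vector("list", schedule$discriminator_epochs)
  for (epoch in seq_len(schedule$discriminator_epochs)) {
    ck <- ceiling(epoch / schedule$generator_swap_every)
    gen <- checkpoints[[ck]]
    ep_loss <- with_seed(derive_seed(seed, paste0("disc", epoch)), {
      ord <- sample(length(corpus))
      losses <- vapply(chunk_indices(length(ord), schedule$batch_size), function(ix) {
        bm <- batch_mask(corpus[ord[ix]], schedule$mask_rate)
        rb <- batch_replace(gen, bm)
        discriminator_step(model, rb, opt)
      }, numeric(1))
      mean(losses)
    })
    val_bacc <- if (!is.null(val_corpus)) {
      discrimination_metrics(model, gen, val_corpus, schedule$mask_rate,
                             seed = derive_seed(seed, "discval"))$balanced_accuracy
    } else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, checkpoint = ck,
                                train_loss = ep_loss, val_balanced_accuracy = val_bacc)
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Replaced-vs-real discrimination metrics
#'
#' Masks and generator-replaces a corpus with a fixed seed, then scores the
#' discriminator's balanced accuracy (mean of true-positive and
#' true-negative rates at threshold 0.5) over all taxon positions.
#'
#' @param disc discriminator model (`token_binary` head)
#' @param generator generator model used to produce replacements
#' @param corpus list of token sequences
#' @param mask_rate masking rate
#' @param seed seed fixing masks and replacement draws
#' @param batch_size inference batch size
#' @return list with `balanced_accuracy`, `tpr`, `tnr`, `n_modified`, `n_real`
#' @export
discrimination_metrics <- function(disc, generator, corpus, mask_rate = 0.15,
                                   seed = 1L, batch_size = 64L) {
  scores <- numeric(0); labels <- numeric(0)
  with_seed(seed, {
    for (ix in chunk_indices(length(corpus), batch_size)) {
      bm <- batch_mask(corpus[ix], mask_rate)
      rb <- batch_replace(generator, bm)
      B <- nrow(rb$tok)
      rows <- unlist(lapply(seq_len(B), function(b) {
        if (rb$lens[b] > 1) flat_rows(b, seq.int(2L, rb$lens[b]), B) else integer(0)
      }))
      y <- numeric(length(rows))
      y[match(rb$rows, rows)] <- as.numeric(rb$modified)
      fwd <- forward_encoder(disc, rb$tok, rb$lens, train = FALSE, keep_cache = FALSE)
      hf <- head_forward(disc, fwd$H[rows, , drop = FALSE])
      scores <- c(scores, as.vector(sigmoid(hf$logits)))
      labels <- c(labels, y)
    }
  })
  pred <- as.numeric(scores > 0.5)
  tpr <- mean(pred[labels == 1] == 1)
  tnr <- mean(pred[labels == 0] == 0)
  list(balanced_accuracy = (tpr + tnr) / 2, tpr = tpr, tnr = tnr,
       n_modified = sum(labels == 1), n_real = sum(labels == 0))
}

#' Run the full ELECTRA pre-training pipeline
#'
#' Builds a generator and a discriminator of the same architecture (no
#' weight tying), trains the generator with checkpointing, then trains the
#' discriminator against the checkpoint curriculum. The returned
#' discriminator is the universal encoder for downstream fine-tuning.
#'
#' @param corpus list of token sequences (training split)
#' @param vocab `taxon_vocabulary`
#' @param vocab_embeddings frozen input embedding matrix
#' @param config [model_config()]
#' @param schedule [pretrain_schedule()]
#' @param val_corpus optional held-out sequences for per-epoch validation
#' @param seed master seed
#' @return list with `generator`, `checkpoints`, `discriminator`, and both
#'   training histories
#' @export
pretrain <- function(corpus, vocab, vocab_embeddings, config, schedule,
                     val_corpus = NULL, seed = 1L) {
  gen <- build_model(config, vocab, vocab_embeddings, head = "token_vocab",
                     seed = derive_seed(seed, "geninit"))
  gtr <- train_generator(gen, corpus, schedule, val_corpus, seed = derive_seed(seed, "gentrain"))
  disc <- build_model(config, vocab, vocab_embeddings, head = "token_binary",
                      seed = derive_seed(seed, "discinit"))
  dtr <- train_discriminator(disc, corpus, gtr$checkpoints, schedule, val_corpus,
                             seed = derive_seed(seed, "disctrain"))
  list(generator = gtr$model, checkpoints = gtr$checkpoints,
       discriminator = dtr$model,
       generator_history = gtr$history, discriminator_history = dtr$history)
}
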