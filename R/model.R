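## The encoder: frozen vocabulary embedding -> trainable linear projection
## into the hidden space -> learned absolute positional embeddings over rank
## positions -> a stack of pre-norm transformer encoder blocks -> final layer
## norm. Swappable heads: a vocabulary softmax over each token (generator), a
## per-token real/modified logit (discriminator), or a two-layer binary head
## on the CLS state (phenotype classifier).
##
## A model is an environment holding a flat named parameter list, so training
## code can mutate parameters in place while clone_model() gives cheap deep
## copies (R's copy-on-write duplicates only what an optimizer touches).

#' Encoder configuration
#'
#' @param vocab_size total token count including the 3 special tokens
#' @param embed_dim dimension of the (frozen) input vocabulary embeddings
#' @param hidden_dim width of the encoder hidden space
#' @param n_blocks number of encoder blocks
#' @param n_heads attention heads per block; must divide `hidden_dim`
#' @param ff_dim width of the position-wise feed-forward inner layer
#' @param max_positions maximum admissible sequence length including CLS
#' @param head_hidden hidden width of the two-layer classification heads
#' @param dropout dropout rate applied to embeddings and sublayer outputs
#'   during training (inference is always deterministic)
#' @param init_sd standard deviation of random parameter initialization
#' @return a `model_config` list
#' @export
model_config <- function(vocab_size, embed_dim = 100L, hidden_dim = 200L,
                         n_blocks = 5L, n_heads = 4L, ff_dim = 4L * hidden_dim,
                         max_positions = 513L, head_hidden = 200L,
                         dropout = 0.1, init_sd = 0.02) {
  stopifnot(is_count(vocab_size), is_count(embed_dim), is_count(hidden_dim),
            is_count(n_blocks), is_count(n_heads), is_count(ff_dim),
            is_count(max_positions), is_count(head_hidden),
            dropout >= 0, dropout < 1)
  if (hidden_dim %% n_heads != 0) stopf("hidden_dim must be divisible by n_heads")
  structure(list(
    vocab_size = as.integer(vocab_size), embed_dim = as.integer(embed_dim),
    hidden_dim = as.integer(hidden_dim), n_blocks = as.integer(n_blocks),
    n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
    max_positions = as.integer(max_positions),
    head_hidden = as.integer(head_hidden),
    dropout = dropout, init_sd = init_sd
  ), class = "model_config")
}

block_param_names <- function(i) {
  paste0("b", i, ".", c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
                        "Wo", "bo", "ln2_g", "ln2_b", "W1", "b1", "W2", "b2"))
}

#' Build an encoder model
#'
#' Taxon rows of the embedding layer are preset from `vocab_embeddings` and
#' frozen for the lifetime of the model; the CLS and MASK rows are trainable
#' and randomly initialized, and the PAD row is fixed at zero. Everything
#' else (projection, positional embeddings, encoder blocks, head) is
#' initialized from a single seeded stream, so equal seeds give bit-identical
#' models.
#'
#' @param config a [model_config()]
#' @param vocab a `taxon_vocabulary`
#' @param vocab_embeddings numeric matrix (taxon id rows) covering every
#'   taxon in `vocab`, with `config$embed_dim` columns
#' @param head `"token_vocab"` (generator), `"token_binary"` (discriminator)
#'   or `"cls_binary"` (phenotype classifier)
#' @param seed integer seed for all random initialization
#' @return an `encoder_model` environment
#' @export
build_model <- function(config, vocab, vocab_embeddings,
                        head = c("token_vocab", "token_binary", "cls_binary"),
                        seed = 1L) {
  head <- match.arg(head)
  stopifnot(inherits(config, "model_config"), inherits(vocab, "taxon_vocabulary"))
  if (config$vocab_size != vocab$size) stopf("config vocab_size != vocabulary size")
  missing <- setdiff(vocab$taxon_ids, rownames(vocab_embeddings))
  if (length(missing) > 0) {
    stopf("vocabulary embeddings missing %d taxa (e.g. %s)",
          length(missing), paste(utils::head(missing, 3), collapse = ", "))
  }
  if (ncol(vocab_embeddings) != config$embed_dim) {
    stopf("embedding dimension %d != config embed_dim %d",
          ncol(vocab_embeddings), config$embed_dim)
  }
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$head_kind <- head
  m$vocab_hash <- vocab_hash(vocab)
  m$n_taxa <- length(vocab$taxon_ids)

  sdv <- config$init_sd
  h <- config$hidden_dim
  P <- list()
  with_seed(seed, {
    emb <- matrix(0, config$vocab_size, config$embed_dim)
    emb[1, ] <- rnorm(config$embed_dim, 0, sdv)  # CLS, trainable
    emb[2, ] <- rnorm(config$embed_dim, 0, sdv)  # MASK, trainable
    emb[vocab$index, ] <- vocab_embeddings[vocab$taxon_ids, , drop = FALSE]
    P$emb <- emb
    P$proj_W <- matrix(rnorm(config$embed_dim * h, 0, sdv), config$embed_dim, h)
    P$proj_b <- numeric(h)
    P$pos <- matrix(rnorm(config$max_positions * h, 0, sdv), config$max_positions, h)
    for (i in seq_len(config$n_blocks)) {
      nm <- block_param_names(i)
      P[[nm[1]]] <- rep(1, h); P[[nm[2]]] <- numeric(h)
      for (w in nm[c(3, 5, 7, 9)]) P[[w]] <- matrix(rnorm(h * h, 0, sdv), h, h)
      for (b in nm[c(4, 6, 8, 10)]) P[[b]] <- numeric(h)
      P[[nm[11]]] <- rep(1, h); P[[nm[12]]] <- numeric(h)
      P[[nm[13]]] <- matrix(rnorm(h * config$ff_dim, 0, sdv), h, config$ff_dim)
      P[[nm[14]]] <- numeric(config$ff_dim)
      P[[nm[15]]] <- matrix(rnorm(config$ff_dim * h, 0, sdv), config$ff_dim, h)
      P[[nm[16]]] <- numeric(h)
    }
    P$lnf_g <- rep(1, h); P$lnf_b <- numeric(h)
    P <- c(P, init_head_params(config, head, m$n_taxa))
  })
  m$params <- P
  set_trainable(m, "pretrain")
  class(m) <- "encoder_model"
  m
}

init_head_params <- function(config, head, n_taxa) {
  h <- config$hidden_dim; hh <- config$head_hidden; sdv <- config$init_sd
  out_dim <- if (head == "token_vocab") n_taxa else 1L
  list(
    head_W1 = matrix(rnorm(h * hh, 0, sdv), h, hh),
    head_b1 = numeric(hh),
    head_W2 = matrix(rnorm(hh * out_dim, 0, sdv), hh, out_dim),
    head_b2 = numeric(out_dim)
  )
}

#' Replace a model's head
#'
#' Drops the current head and attaches a freshly initialized one of the
#' requested kind (used when turning a pre-trained discriminator into a
#' phenotype classifier).
#'
#' @param model an `encoder_model`
#' @param head new head kind
#' @param seed seed for the head (and nothing else)
#' @export
reset_head <- function(model, head = c("token_vocab", "token_binary", "cls_binary"),
                       seed = 1L) {
  head <- match.arg(head)
  model$head_kind <- head
  with_seed(seed, {
    model$params[c("head_W1", "head_b1", "head_W2", "head_b2")] <-
      init_head_params(model$config, head, model$n_taxa)
  })
  invisible(model)
}

## Which parameters receive gradients. "pretrain": everything except the
## frozen taxon embedding rows (CLS+MASK rows of emb do train). "finetune":
## only the projection, the head, and the CLS embedding row -- the encoder
## blocks and positional embeddings act as a fixed universal encoder.
set_trainable <- function(model, phase = c("pretrain", "finetune")) {
  phase <- match.arg(phase)
  all_names <- names(model$params)
  if (phase == "pretrain") {
    model$trainable <- setdiff(all_names, "emb")
    model$emb_trainable_rows <- c(1L, 2L)
  } else {
    model$trainable <- intersect(all_names,
      c("proj_W", "proj_b", "head_W1", "head_b1", "head_W2", "head_b2"))
    model$emb_trainable_rows <- 1L
  }
  model$phase <- phase
  invisible(model)
}

#' Deep-copy a model
#' @param model an `encoder_model`
#' @return an independent copy (training one never mutates the other)
#' @export
clone_model <- function(model) {
  m <- new.env(parent = emptyenv())
  for (nm in ls(model)) assign(nm, get(nm, envir = model), envir = m)
  class(m) <- "encoder_model"
  m
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %d blocks, hidden %d, head %s, %s params\n",
              x$config$n_blocks, x$config$hidden_dim, x$head_kind,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total parameter count
#' @param model an `encoder_model`
#' @return integer number of scalar parameters (including frozen ones)
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Fingerprint of selected parameters
#'
#' @param model an `encoder_model`
#' @param which character vector of parameter names; default all
#' @return MD5 string; bit-identical parameters give identical fingerprints
#' @export
param_digest <- function(model, which = NULL) {
  P <- model$params
  if (!is.null(which)) P <- P[which]
  object_digest(P)
}

## Names of the frozen-encoder parameter set checked by fine-tuning tests.
encoder_param_names <- function(model) {
  c("pos", unlist(lapply(seq_len(model$config$n_blocks), block_param_names)),
    "lnf_g", "lnf_b")
}

## ---------------------------------------------------------------------------
## Forward / backward engine.
##
## A batch is a B x L integer matrix of token indices padded with PAD, plus
## per-sequence lengths. State matrices are (B*L) x hidden with element (b,l)
## stored at row b + (l-1)*B (column-major over the batch), so position l of
## every sequence is a contiguous row block.

pad_batch <- function(seqs, pad_id = 3L) {
  lens <- lengths(seqs)
  L <- max(lens)
  tok <- matrix(pad_id, length(seqs), L)
  for (b in seq_along(seqs)) tok[b, seq_len(lens[b])] <- seqs[[b]]
  list(tok = tok, lens = lens)
}

seq_rows <- function(b, Lb, B) b + B * (seq_len(Lb) - 1L)

## Full encoder forward. Returns final normalized states H ((B*L) x hidden)
## and, if keep_cache, everything backward_encoder needs.
forward_encoder <- function(model, tok, lens, train = FALSE, keep_cache = train) {
  P <- model$params; cfg <- model$config
  B <- nrow(tok); L <- ncol(tok); n <- B * L
  if (L > cfg$max_positions) stopf("sequence length %d exceeds max_positions %d", L, cfg$max_positions)
  drop_rate <- if (train) cfg$dropout else 0

  tok_v <- as.vector(tok)
  X100 <- P$emb[tok_v, , drop = FALSE]
  pos_idx <- rep(seq_len(L), each = B)
  H <- X100 %*% P$proj_W + rep(P$proj_b, each = n) + P$pos[pos_idx, , drop = FALSE]
  emb_mask <- dropout_mask(n, cfg$hidden_dim, drop_rate)
  if (!is.null(emb_mask)) H <- H * emb_mask

  nh <- cfg$n_heads
  lens_i <- as.integer(lens)

  cache <- if (keep_cache) list(tok_v = tok_v, X100 = X100, pos_idx = pos_idx,
                                emb_mask = emb_mask, blocks = vector("list", cfg$n_blocks))
           else NULL

  for (i in seq_len(cfg$n_blocks)) {
    nm <- block_param_names(i)
    ln1 <- ln_forward(H, P[[nm[1]]], P[[nm[2]]])
    Q <- lin_forward(ln1$y, P[[nm[3]]], P[[nm[4]]])
    K <- lin_forward(ln1$y, P[[nm[5]]], P[[nm[6]]])
    V <- lin_forward(ln1$y, P[[nm[7]]], P[[nm[8]]])
    aw <- attn_forward_cpp(Q, K, V, lens_i, nh)
    O <- aw$O
    attn_out <- lin_forward(O, P[[nm[9]]], P[[nm[10]]])
    a_mask <- dropout_mask(n, cfg$hidden_dim, drop_rate)
    if (!is.null(a_mask)) attn_out <- attn_out * a_mask
    H_mid <- H + attn_out

    ln2 <- ln_forward(H_mid, P[[nm[11]]], P[[nm[12]]])
    U <- lin_forward(ln2$y, P[[nm[13]]], P[[nm[14]]])
    G <- relu(U)
    ffn_out <- lin_forward(G, P[[nm[15]]], P[[nm[16]]])
    f_mask <- dropout_mask(n, cfg$hidden_dim, drop_rate)
    if (!is.null(f_mask)) ffn_out <- ffn_out * f_mask
    H <- H_mid + ffn_out

    if (keep_cache) {
      cache$blocks[[i]] <- list(
        ln1 = ln1[c("xhat", "inv")], A_in = ln1$y,
        Q = Q, K = K, V = V, O = O, att = aw$att,
        a_mask = a_mask, H_mid = H_mid,
        ln2 = ln2[c("xhat", "inv")], F_in = ln2$y,
        U = U, G = G, f_mask = f_mask
      )
    }
  }
  lnf <- ln_forward(H, P$lnf_g, P$lnf_b)
  if (keep_cache) { cache$lnf <- lnf[c("xhat", "inv")]; cache$H_pre_lnf <- H }
  list(H = lnf$y, cache = cache, B = B, L = L, lens = lens)
}

## Backward through the encoder given dH at the final normalized states.
## Rows of dH at PAD positions must be zero. Returns flat gradient list.
## With full = FALSE (fine-tuning), gradients for the frozen encoder
## parameters (blocks, positional embeddings, final LN) are not materialized;
## only the backward *path* through them is computed, plus gradients for the
## projection and the trainable embedding rows.
backward_encoder <- function(model, fwd, dH, full = TRUE) {
  P <- model$params; cfg <- model$config; cache <- fwd$cache
  nh <- cfg$n_heads
  lens_i <- as.integer(fwd$lens)
  grads <- list()

  lb <- ln_backward(dH, cache$lnf, P$lnf_g)
  if (full) { grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db }
  dH <- lb$dx

  for (i in rev(seq_len(cfg$n_blocks))) {
    nm <- block_param_names(i)
    bc <- cache$blocks[[i]]

    d_ffn_out <- if (!is.null(bc$f_mask)) dH * bc$f_mask else dH
    if (full) {
      lb2 <- lin_backward(d_ffn_out, bc$G, P[[nm[15]]])
      grads[[nm[15]]] <- lb2$dW; grads[[nm[16]]] <- lb2$db
      dU <- lb2$dx * relu_grad(bc$U)
      lb1 <- lin_backward(dU, bc$F_in, P[[nm[13]]])
      grads[[nm[13]]] <- lb1$dW; grads[[nm[14]]] <- lb1$db
      dF_in <- lb1$dx
    } else {
      dU <- (d_ffn_out %*% t(P[[nm[15]]])) * relu_grad(bc$U)
      dF_in <- dU %*% t(P[[nm[13]]])
    }
    lnb2 <- ln_backward(dF_in, bc$ln2, P[[nm[11]]])
    if (full) { grads[[nm[11]]] <- lnb2$dg; grads[[nm[12]]] <- lnb2$db }
    dH_mid <- dH + lnb2$dx

    d_attn_out <- if (!is.null(bc$a_mask)) dH_mid * bc$a_mask else dH_mid
    if (full) {
      lbo <- lin_backward(d_attn_out, bc$O, P[[nm[9]]])
      grads[[nm[9]]] <- lbo$dW; grads[[nm[10]]] <- lbo$db
      dO <- lbo$dx
    } else {
      dO <- d_attn_out %*% t(P[[nm[9]]])
    }
    ab <- attn_backward_cpp(bc$Q, bc$K, bc$V, bc$att, dO, lens_i, nh)
    if (full) {
      lbq <- lin_backward(ab$dQ, bc$A_in, P[[nm[3]]])
      lbk <- lin_backward(ab$dK, bc$A_in, P[[nm[5]]])
      lbv <- lin_backward(ab$dV, bc$A_in, P[[nm[7]]])
      grads[[nm[3]]] <- lbq$dW; grads[[nm[4]]] <- lbq$db
      grads[[nm[5]]] <- lbk$dW; grads[[nm[6]]] <- lbk$db
      grads[[nm[7]]] <- lbv$dW; grads[[nm[8]]] <- lbv$db
      dA_in <- lbq$dx + lbk$dx + lbv$dx
    } else {
      dA_in <- ab$dQ %*% t(P[[nm[3]]]) + ab$dK %*% t(P[[nm[5]]]) +
        ab$dV %*% t(P[[nm[7]]])
    }
    lnb1 <- ln_backward(dA_in, bc$ln1, P[[nm[1]]])
    if (full) { grads[[nm[1]]] <- lnb1$dg; grads[[nm[2]]] <- lnb1$db }
    dH <- dH_mid + lnb1$dx
  }

  if (!is.null(cache$emb_mask)) dH <- dH * cache$emb_mask
  if (full) {
    grads$pos <- rowsum(dH, cache$pos_idx, reorder = TRUE)
    if (nrow(grads$pos) < cfg$max_positions) {
      pad <- matrix(0, cfg$max_positions - nrow(grads$pos), cfg$hidden_dim)
      grads$pos <- rbind(grads$pos, pad)
    }
  }
  lbp <- lin_backward(dH, cache$X100, P$proj_W)
  grads$proj_W <- lbp$dW; grads$proj_b <- lbp$db

  demb <- matrix(0, cfg$vocab_size, cfg$embed_dim)
  rows <- model$emb_trainable_rows
  sel <- cache$tok_v %in% rows
  if (any(sel)) {
    acc <- rowsum(lbp$dx[sel, , drop = FALSE], cache$tok_v[sel], reorder = TRUE)
    demb[as.integer(rownames(acc)), ] <- acc
  }
  grads$emb <- demb
  grads
}

## ---------------------------------------------------------------------------
## Heads.

head_forward <- function(model, H) {
  P <- model$params
  Z_pre <- lin_forward(H, P$head_W1, P$head_b1)
  Z <- relu(Z_pre)
  logits <- lin_forward(Z, P$head_W2, P$head_b2)
  list(logits = logits, Z = Z, Z_pre = Z_pre)
}

## dlogits -> gradients of head params + dH. `H` is the matrix fed in.
head_backward <- function(model, hf, H, dlogits) {
  P <- model$params
  lb2 <- lin_backward(dlogits, hf$Z, P$head_W2)
  dZ <- lb2$dx * relu_grad(hf$Z_pre)
  lb1 <- lin_backward(dZ, H, P$head_W1)
  list(grads = list(head_W1 = lb1$dW, head_b1 = lb1$db,
                    head_W2 = lb2$dW, head_b2 = lb2$db),
       dH = lb1$dx)
}

## ---------------------------------------------------------------------------
## User-facing inference.

#' Encode token sequences
#'
#' Runs the encoder in inference mode (dropout off, deterministic) and
#' returns the final-block states.
#'
#' @param model an `encoder_model`
#' @param seqs a single token sequence (integer vector starting with CLS) or
#'   a list of them
#' @return for one sequence: list with `token_states` (length x hidden matrix)
#'   and `cls_state`; for a list: list of such lists
#' @export
encode <- function(model, seqs) {
  single <- !is.list(seqs)
  if (single) seqs <- list(seqs)
  pb <- pad_batch(seqs)
  fwd <- forward_encoder(model, pb$tok, pb$lens, train = FALSE, keep_cache = FALSE)
  B <- length(seqs)
  out <- lapply(seq_len(B), function(b) {
    r <- seq_rows(b, pb$lens[b], B)
    st <- fwd$H[r, , drop = FALSE]
    list(token_states = st, cls_state = st[1, ])
  })
  if (single) out[[1]] else out
}

#' Predicted phenotype probability
#'
#' Applies the CLS binary head to the sample representation `h_cls`; this is
#' the probability-valued classifier M(X) used by attribution.
#'
#' @param model an `encoder_model` with a `cls_binary` head
#' @param seqs token sequence or list of sequences
#' @return numeric probabilities in \[0, 1\]
#' @export
classify_sample <- function(model, seqs) {
  if (model$head_kind != "cls_binary") stopf("model head is '%s', need 'cls_binary'", model$head_kind)
  single <- !is.list(seqs)
  if (single) seqs <- list(seqs)
  pb <- pad_batch(seqs)
  fwd <- forward_encoder(model, pb$tok, pb$lens, train = FALSE, keep_cache = FALSE)
  cls_rows <- seq_len(length(seqs))  # position 1 of each sequence
  hf <- head_forward(model, fwd$H[cls_rows, , drop = FALSE])
  p <- as.vector(sigmoid(hf$logits))
  if (single) p[1] else p
}

#' Per-token head predictions
#'
#' With a `token_vocab` head, returns for each non-PAD position a probability
#' distribution over the taxon vocabulary (rows sum to 1); with a
#' `token_binary` head, the per-position probability of being
#' generator-modified.
#'
#' @param model an `encoder_model` with a token-level head
#' @param tokens one token sequence
#' @return matrix length x n_taxa (token_vocab) or numeric vector
#'   (token_binary); row/element order follows the sequence including CLS
#' @export
token_predictions <- function(model, tokens) {
  if (model$head_kind == "cls_binary") stopf("token_predictions needs a token-level head")
  pb <- pad_batch(list(tokens))
  fwd <- forward_encoder(model, pb$tok, pb$lens, train = FALSE, keep_cache = FALSE)
  hf <- head_forward(model, fwd$H)
  if (model$head_kind == "token_vocab") {
    softmax_rows(hf$logits)
  } else {
    as.vector(sigmoid(hf$logits))
  }
}

## ---------------------------------------------------------------------------
## Checkpoints.

#' Save a model checkpoint
#'
#' Single-file archive holding the config, all parameter tensors, the head
#' kind and the vocabulary hash.
#'
#' @param model an `encoder_model`
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               head_kind = model$head_kind, vocab_hash = model$vocab_hash,
               n_taxa = model$n_taxa, phase = model$phase), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()]
#' @param vocab the `taxon_vocabulary` the model is to be used with; its hash
#'   must match the one stored in the checkpoint
#' @return an `encoder_model`
#' @export
load_checkpoint <- function(path, vocab) {
  x <- readRDS(path)
  if (!identical(x$vocab_hash, vocab_hash(vocab))) {
    stopf("checkpoint was trained with a different vocabulary")
  }
  m <- new.env(parent = emptyenv())
  m$config <- x$config; m$params <- x$params; m$head_kind <- x$head_kind
  m$vocab_hash <- x$vocab_hash; m$n_taxa <- x$n_taxa
  class(m) <- "encoder_model"
  set_trainable(m, x$phase %||% "pretrain")
  m
}
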