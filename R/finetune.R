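## Task fine-tuning on a frozen pre-trained encoder: a fresh CLS head is
## attached, and only the head, the projection layer and the CLS embedding
## row are trained (SGD with momentum, mean-squared-error on the predicted
## probability against the 0/1 label). Training uses random-deletion
## augmentation and minority-class oversampling; evaluation never does.

#' Fine-tuning configuration
#'
#' @param learning_rate SGD learning rate
#' @param momentum SGD momentum
#' @param epochs training epochs
#' @param deletion_rate fraction of taxa randomly deleted from each training
#'   sequence per epoch (augmentation; never applied at evaluation)
#' @param oversample_minority oversample the minority class to parity each
#'   epoch so the model sees equal numbers of samples from each class
#' @param batch_size minibatch size
#' @param loss `"mse"` (default) or `"ce"` (cross-entropy ablation toggle)
#' @return a `finetune_config` list
#' @export
finetune_config <- function(learning_rate = 0.01, momentum = 0.9, epochs = 50L,
                            deletion_rate = 0.10, oversample_minority = TRUE,
                            batch_size = 32L, loss = c("mse", "ce")) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, is_count(epochs),
            deletion_rate >= 0, deletion_rate < 1, is_count(batch_size))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), deletion_rate = deletion_rate,
                 oversample_minority = isTRUE(oversample_minority),
                 batch_size = as.integer(batch_size), loss = loss),
            class = "finetune_config")
}

#' Random-deletion augmentation
#'
#' Removes exactly `round(deletion_rate * n_taxa)` uniformly chosen taxa
#' from the sequence ("one in ten" at the default rate); the CLS token is
#' never deleted and survivor order is preserved.
#'
#' @param tokens token sequence (CLS first)
#' @param deletion_rate fraction of taxa to delete
#' @param seed optional seed (current RNG stream used when NULL)
#' @return augmented token sequence
#' @export
augment_delete <- function(tokens, deletion_rate = 0.10, seed = NULL) {
  stopifnot(deletion_rate >= 0, deletion_rate < 1)
  n <- length(tokens) - 1L
  if (n <= 0 || deletion_rate == 0) return(tokens)
  k <- as.integer(round_half_up(deletion_rate * n))
  if (k == 0) return(tokens)
  drop <- with_seed(seed, sample_vec(seq.int(2L, n + 1L), k))
  tokens[-drop]
}

## One SGD step on a batch of sequences for the CLS binary head.
cls_step <- function(model, seqs, y, opt, loss_kind) {
  pb <- pad_batch(seqs)
  fwd <- forward_encoder(model, pb$tok, pb$lens, train = TRUE, keep_cache = TRUE)
  B <- length(seqs)
  cls_rows <- seq_len(B)  # position 1 of each sequence
  Hc <- fwd$H[cls_rows, , drop = FALSE]
  hf <- head_forward(model, Hc)
  p <- as.vector(sigmoid(hf$logits))
  if (loss_kind == "mse") {
    loss <- mean((p - y)^2)
    dlogit <- matrix(2 * (p - y) * p * (1 - p) / B, ncol = 1)
  } else {
    loss <- -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
    dlogit <- matrix((p - y) / B, ncol = 1)
  }
  hb <- head_backward(model, hf, Hc, dlogit)
  dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
  dH[cls_rows, ] <- hb$dH
  grads <- backward_encoder(model, fwd, dH, full = FALSE)
  grads[names(hb$grads)] <- hb$grads
  opt_step(model, opt, grads)
  loss
}

## Oversample the minority class to parity (sampling with replacement).
oversample_to_parity <- function(labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) stopf("corpus has a single class")
  if (length(pos) < length(neg)) {
    extra <- sample_vec(pos, length(neg) - length(pos), replace = TRUE)
  } else if (length(neg) < length(pos)) {
    extra <- sample_vec(neg, length(pos) - length(neg), replace = TRUE)
  } else {
    extra <- integer(0)
  }
  c(seq_along(labels), extra)
}

#' Fine-tune a phenotype classifier on a frozen encoder
#'
#' Clones the pre-trained encoder, attaches a fresh CLS binary head, and
#' trains only the head, the projection layer and the CLS embedding row.
#' Encoder blocks, positional embeddings and taxon embeddings stay
#' bit-identical to the input model.
#'
#' @param encoder a pre-trained `encoder_model` (any head; it is replaced)
#' @param seqs list of token sequences
#' @param labels 0/1 integer vector aligned with `seqs`
#' @param config a [finetune_config()]
#' @param stopping_epoch train this many epochs instead of `config$epochs`
#'   (used after stopping-epoch selection)
#' @param val optional list(seqs, labels); per-epoch validation AUROC is
#'   logged (no augmentation, no oversampling)
#' @param seed seed for head init, shuffling, oversampling, augmentation
#' @param reinit_projection re-initialize the projection layer instead of
#'   continuing from its pre-trained weights (used per ensemble member)
#' @return a `phenotype_classifier`: list with `model` and per-epoch
#'   `history`
#' @export
finetune <- function(encoder, seqs, labels, config = finetune_config(),
                     stopping_epoch = NULL, val = NULL, seed = 1L,
                     reinit_projection = FALSE) {
  stopifnot(length(seqs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stopf("corpus has a single class")
  model <- clone_model(encoder)
  reset_head(model, "cls_binary", seed = derive_seed(seed, "head"))
  if (reinit_projection) {
    with_seed(derive_seed(seed, "proj"), {
      cfg <- model$config
      model$params$proj_W <- matrix(rnorm(cfg$embed_dim * cfg$hidden_dim, 0, cfg$init_sd),
                                    cfg$embed_dim, cfg$hidden_dim)
      model$params$proj_b <- numeric(cfg$hidden_dim)
    })
  }
  set_trainable(model, "finetune")
  opt <- opt_init(model, "sgd", lr = config$learning_rate, momentum = config$momentum)
  n_epochs <- as.integer(stopping_epoch %||% config$epochs)
  hist <- vector("list", n_epochs)
  for (epoch in seq_len(n_epochs)) {
    res <- with_seed(derive_seed(seed, paste0("ft", epoch)), {
      idx <- if (config$oversample_minority) oversample_to_parity(labels) else seq_along(labels)
      idx <- sample(idx)
      aug <- lapply(seqs[idx], augment_delete, deletion_rate = config$deletion_rate)
      losses <- vapply(chunk_indices(length(idx), config$batch_size), function(ix) {
        cls_step(model, aug[ix], labels[idx[ix]], opt, config$loss)
      }, numeric(1))
      list(loss = mean(losses), n_pos = sum(labels[idx] == 1), n_neg = sum(labels[idx] == 0))
    })
    val_auroc <- if (!is.null(val)) {
      auroc(classify_sample(model, val$seqs), val$labels)
    } else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = res$loss,
                                n_pos_seen = res$n_pos, n_neg_seen = res$n_neg,
                                val_auroc = val_auroc)
  }
  structure(list(model = model, history = do.call(rbind, hist)),
            class = "phenotype_classifier")
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat(sprintf("<phenotype_classifier> %d epochs trained\n", nrow(x$history)))
  invisible(x)
}

#' Choose the stopping epoch on a validation split
#'
#' Fine-tunes for the full epoch budget while tracking validation AUROC and
#' returns the epoch with the highest validation AUROC (earliest epoch on
#' ties).
#'
#' @inheritParams finetune
#' @param val list(seqs, labels) validation split (patient-disjoint from
#'   `seqs`)
#' @return list with `epoch` (selected stopping epoch) and `history`
#' @export
select_stopping_epoch <- function(encoder, seqs, labels, val,
                                  config = finetune_config(), seed = 1L) {
  if (length(unique(val$labels)) < 2) stopf("validation split has a single class")
  fit <- finetune(encoder, seqs, labels, config, val = val, seed = seed)
  list(epoch = which_best_epoch(fit$history$val_auroc), history = fit$history)
}

## argmax with earliest-epoch tie-break (exact ties only).
which_best_epoch <- function(vals) {
  which.max(vals)
}

#' Train a k-member single-epoch ensemble
#'
#' Each member gets a freshly seeded classification-head initialization
#' (the projection continues from its pre-trained weights, as a single
#' epoch cannot re-learn a randomly re-initialized projection) and is
#' fine-tuned for exactly one epoch on the full labeled corpus (with
#' oversampling and augmentation, each member with its own shuffling
#' order). Member probabilities are aggregated by arithmetic mean.
#'
#' @inheritParams finetune
#' @param k ensemble size
#' @return an `ensemble_classifier`: list of `phenotype_classifier` members
#' @export
train_ensemble <- function(encoder, seqs, labels, k = 10L,
                           config = finetune_config(), seed = 1L) {
  if (!is_count(k)) stopf("k must be a positive integer")
  members <- lapply(seq_len(k), function(j) {
    finetune(encoder, seqs, labels, config, stopping_epoch = 1L,
             seed = derive_seed(seed, paste0("member", j)))
  })
  structure(list(members = members, k = as.integer(k)), class = "ensemble_classifier")
}

#' @export
print.ensemble_classifier <- function(x, ...) {
  cat(sprintf("<ensemble_classifier> k = %d single-epoch members\n", x$k))
  invisible(x)
}

#' Predicted positive-class probability
#'
#' Generic probability-valued classifier interface M(X): methods exist for
#' fine-tuned classifiers, ensembles (mean member probability), raw
#' `encoder_model`s with a CLS head, and plain functions (useful for
#' analytic toy scorers).
#'
#' @param object a classifier
#' @param seqs token sequence or list of sequences
#' @param ... unused
#' @return numeric probabilities
#' @export
predict_proba <- function(object, seqs, ...) UseMethod("predict_proba")

#' @export
predict_proba.phenotype_classifier <- function(object, seqs, ...) {
  classify_sample(object$model, seqs)
}

#' @export
predict_proba.encoder_model <- function(object, seqs, ...) {
  classify_sample(object, seqs)
}

#' @export
predict_proba.ensemble_classifier <- function(object, seqs, ...) {
  preds <- lapply(object$members, predict_proba, seqs = seqs)
  Reduce(`+`, preds) / length(preds)
}

#' @export
predict_proba.function <- function(object, seqs, ...) {
  if (!is.list(seqs)) return(object(seqs))
  vapply(seqs, object, numeric(1))
}

#' Per-member ensemble predictions
#'
#' @param ens an `ensemble_classifier`
#' @param seqs list of token sequences
#' @return matrix samples x members of probabilities
#' @export
ensemble_member_proba <- function(ens, seqs) {
  vapply(ens$members, predict_proba, numeric(length(seqs)), seqs = seqs)
}
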