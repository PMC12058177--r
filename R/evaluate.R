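## Evaluation protocol: threshold-free metrics (AUROC / AUPR),
## patient-blocked splitting so no individual's samples straddle partitions,
## the repeated train/validate/refit/test protocol, and the
## abundance-weighted embedding baseline.

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counting one half (the normalized Mann-Whitney U statistic).
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 labels
#' @return AUROC in \[0, 1\]
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: walking thresholds from the highest score down,
#' precision is accumulated at each recall increment; tied scores are
#' processed as one block.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\]
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stopf("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  ## block boundaries at distinct score values
  ends <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Patient-blocked train/validation/test split
#'
#' Partitions patients (not samples) so that all samples from one individual
#' land in a single partition, then maps the partition back to samples.
#'
#' @param labels_df data.frame with `sample_id`, `label`, `patient_id`
#' @param test_frac fraction of patients held out for testing
#' @param val_frac fraction of the remaining patients used for validation
#' @param seed seed for the patient shuffle
#' @return list of integer row indices into `labels_df`: `train`, `val`,
#'   `test`
#' @export
patient_blocked_split <- function(labels_df, test_frac = 0.20, val_frac = 0.25,
                                  seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac >= 0, val_frac < 1)
  patients <- unique(labels_df$patient_id)
  if (length(patients) < 3) stopf("need at least 3 patients to split")
  perm <- with_seed(seed, sample(patients))
  n_test <- max(1L, as.integer(round(test_frac * length(patients))))
  test_pat <- perm[seq_len(n_test)]
  rest <- perm[-seq_len(n_test)]
  n_val <- as.integer(round(val_frac * length(rest)))
  val_pat <- if (n_val > 0) rest[seq_len(n_val)] else character(0)
  train_pat <- setdiff(rest, val_pat)
  list(train = which(labels_df$patient_id %in% train_pat),
       val = which(labels_df$patient_id %in% val_pat),
       test = which(labels_df$patient_id %in% test_pat))
}

#' Run the repeated fine-tuning evaluation protocol
#'
#' Per run: (1) block out a patient-level test split; (2) split the
#' remainder into train/validation and pick the stopping epoch by
#' validation AUROC; (3) re-fine-tune from scratch on all non-test data for
#' that many epochs; (4) score the test split. Reports per-run AUROC/AUPR
#' and their mean and standard deviation.
#'
#' @param encoder pre-trained `encoder_model`
#' @param seqs list of token sequences
#' @param labels_df data.frame with `sample_id`, `label`, `patient_id`,
#'   aligned with `seqs`
#' @param config [finetune_config()]
#' @param n_runs number of independent runs
#' @param test_frac,val_frac split fractions (patients)
#' @param seed master seed; run r derives its own split/training seeds
#' @return list with `runs` (per-run data.frame), `mean`, `sd`
#' @export
run_protocol <- function(encoder, seqs, labels_df, config = finetune_config(),
                         n_runs = 5L, test_frac = 0.20, val_frac = 0.25,
                         seed = 1L) {
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- patient_blocked_split(labels_df, test_frac, val_frac,
                                seed = derive_seed(seed, paste0("split", r)))
    stopifnot(length(intersect(labels_df$patient_id[sp$test],
                               labels_df$patient_id[c(sp$train, sp$val)])) == 0)
    sel <- select_stopping_epoch(
      encoder, seqs[sp$train], labels_df$label[sp$train],
      val = list(seqs = seqs[sp$val], labels = labels_df$label[sp$val]),
      config = config, seed = derive_seed(seed, paste0("sel", r))
    )
    nontest <- c(sp$train, sp$val)
    fit <- finetune(encoder, seqs[nontest], labels_df$label[nontest], config,
                    stopping_epoch = sel$epoch,
                    seed = derive_seed(seed, paste0("refit", r)))
    p <- predict_proba(fit, seqs[sp$test])
    y <- labels_df$label[sp$test]
    rows[[r]] <- data.frame(run = r, stopping_epoch = sel$epoch,
                            auroc = auroc(p, y), aupr = aupr(p, y),
                            n_pos = sum(y == 1), n_neg = sum(y == 0))
  }
  runs <- do.call(rbind, rows)
  list(runs = runs,
       mean = c(auroc = mean(runs$auroc), aupr = mean(runs$aupr)),
       sd = c(auroc = sd(runs$auroc), aupr = sd(runs$aupr)))
}

#' Abundance-weighted embedding baseline features
#'
#' Represents each sample by the abundance-weighted average of its taxa's
#' input embeddings (the non-contextualized baseline). Taxa without an
#' embedding row are dropped with weight renormalization over the covered
#' taxa.
#'
#' @param embeddings taxon embedding matrix (rownames = taxon ids)
#' @param tab an `abundance_table`
#' @return numeric matrix samples x embedding-dim
#' @export
weighted_baseline <- function(embeddings, tab) {
  covered <- intersect(colnames(tab), rownames(embeddings))
  if (length(covered) == 0) stopf("no sample taxa covered by the embedding matrix")
  W <- unclass(tab)[, covered, drop = FALSE]
  wsum <- rowSums(W)
  if (any(wsum == 0)) {
    stopf("sample '%s' has no covered taxa", rownames(tab)[which(wsum == 0)[1]])
  }
  (W %*% embeddings[covered, , drop = FALSE]) / wsum
}

## ---------------------------------------------------------------------------
## A small standalone two-layer MLP head over fixed feature vectors (same
## architecture as the model's classification head), so the Weighted
## baseline can be trained with the identical optimizer/loss regime.

#' Train an MLP head on fixed feature vectors
#'
#' Two-layer network (ReLU, sigmoid output) trained with SGD + momentum and
#' MSE loss, with minority oversampling — the same regime as encoder
#' fine-tuning, for like-for-like baseline comparisons.
#'
#' @param X feature matrix (samples x d)
#' @param y 0/1 labels
#' @param hidden hidden width
#' @param config [finetune_config()] (epochs, lr, momentum, oversampling)
#' @param seed seed
#' @return an `mlp_head` list with weight matrices
#' @export
train_mlp_head <- function(X, y, hidden = 200L, config = finetune_config(),
                           seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  d <- ncol(X)
  par <- with_seed(derive_seed(seed, "init"), list(
    W1 = matrix(rnorm(d * hidden, 0, 0.02), d, hidden), b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden, 0, 0.02), hidden, 1), b2 = 0
  ))
  vel <- lapply(par, function(p) p * 0)
  for (epoch in seq_len(config$epochs)) {
    with_seed(derive_seed(seed, paste0("ep", epoch)), {
      idx <- if (config$oversample_minority) oversample_to_parity(y) else seq_along(y)
      idx <- sample(idx)
      for (ix in chunk_indices(length(idx), config$batch_size)) {
        Xb <- X[idx[ix], , drop = FALSE]; yb <- y[idx[ix]]
        Z_pre <- lin_forward(Xb, par$W1, par$b1)
        Z <- relu(Z_pre)
        p <- as.vector(sigmoid(Z %*% par$W2 + par$b2))
        dlogit <- matrix(2 * (p - yb) * p * (1 - p) / length(yb), ncol = 1)
        g <- list(W2 = crossprod(Z, dlogit), b2 = sum(dlogit))
        dZ <- (dlogit %*% t(par$W2)) * relu_grad(Z_pre)
        g$W1 <- crossprod(Xb, dZ); g$b1 <- colSums(dZ)
        for (nm in names(par)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - config$learning_rate * g[[nm]]
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      }
    })
  }
  structure(list(par = par), class = "mlp_head")
}

#' @export
predict_proba.mlp_head <- function(object, seqs, ...) {
  X <- seqs  # feature matrix for this method
  par <- object$par
  as.vector(sigmoid(relu(lin_forward(X, par$W1, par$b1)) %*% par$W2 + par$b2))
}
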