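## Optimizers over the flat parameter list of an encoder_model. Updates are
## applied in place; only parameters in model$trainable move, and within the
## embedding matrix only the rows in model$emb_trainable_rows (the frozen
## taxon rows are never touched, keeping them bit-identical to construction).

opt_init <- function(model, kind = c("adam", "sgd"), lr, momentum = 0.9,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  st <- new.env(parent = emptyenv())
  st$kind <- kind; st$lr <- lr; st$momentum <- momentum
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- list(); st$v <- list()
  st
}

opt_step <- function(model, st, grads) {
  st$t <- st$t + 1L
  for (nm in model$trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (st$kind == "adam") {
      m <- st$m[[nm]]; v <- st$v[[nm]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- st$beta1 * m + (1 - st$beta1) * g
      v <- st$beta2 * v + (1 - st$beta2) * g * g
      st$m[[nm]] <- m; st$v[[nm]] <- v
      mhat <- m / (1 - st$beta1^st$t)
      vhat <- v / (1 - st$beta2^st$t)
      model$params[[nm]] <- model$params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
    } else {
      vel <- st$m[[nm]]
      if (is.null(vel)) vel <- g * 0
      vel <- st$momentum * vel - st$lr * g
      st$m[[nm]] <- vel
      model$params[[nm]] <- model$params[[nm]] + vel
    }
  }
  ## Embedding rows: update restricted to the trainable (special) rows so the
  ## frozen taxon rows stay bit-identical whatever the optimizer state does.
  rows <- model$emb_trainable_rows
  g <- grads$emb
  if (!is.null(g) && length(rows) > 0) {
    gr <- g[rows, , drop = FALSE]
    key <- "emb_rows"
    if (st$kind == "adam") {
      m <- st$m[[key]]; v <- st$v[[key]]
      if (is.null(m) || nrow(m) != length(rows)) { m <- gr * 0; v <- gr * 0 }
      m <- st$beta1 * m + (1 - st$beta1) * gr
      v <- st$beta2 * v + (1 - st$beta2) * gr * gr
      st$m[[key]] <- m; st$v[[key]] <- v
      mhat <- m / (1 - st$beta1^st$t)
      vhat <- v / (1 - st$beta2^st$t)
      model$params$emb[rows, ] <- model$params$emb[rows, ] - st$lr * mhat / (sqrt(vhat) + st$eps)
    } else {
      vel <- st$m[[key]]
      if (is.null(vel) || nrow(vel) != length(rows)) vel <- gr * 0
      vel <- st$momentum * vel - st$lr * gr
      st$m[[key]] <- vel
      model$params$emb[rows, ] <- model$params$emb[rows, ] + vel
    }
  }
  invisible(model)
}
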