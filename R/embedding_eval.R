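## Quantitative evaluation of taxon embedding spaces: mean contextualized
## embeddings over a corpus, k-means purity curves against a taxonomy rank,
## Spearman screens of embedding dimensions against pathway membership with
## permutation significance, and two-sample tests comparing the magnitude
## distributions of significant correlations between embedding spaces.

#' Mean contextualized taxon embeddings
#'
#' Restricts to the `top_n` most frequent taxa of the corpus (ties broken by
#' ascending token index) and averages each taxon's final-encoder-block
#' state over every occurrence (inference mode).
#'
#' @param model pre-trained `encoder_model`
#' @param seqs list of token sequences
#' @param top_n number of most frequent taxa to embed
#' @param vocab optional `taxon_vocabulary`; when given, rows are named by
#'   taxon id instead of token index
#' @param batch_size inference batch size
#' @return list with `embeddings` (taxa x hidden matrix) and `counts`
#'   (occurrences per taxon)
#' @export
mean_contextual_embeddings <- function(model, seqs, top_n = 5000L, vocab = NULL,
                                       batch_size = 64L) {
  stopifnot(is_count(top_n))
  occ <- table(unlist(lapply(seqs, function(s) s[s > 3L])))
  taxa <- as.integer(names(occ))
  ord <- order(-as.vector(occ), taxa)
  keep <- taxa[utils::head(ord, top_n)]
  h <- model$config$hidden_dim
  sums <- matrix(0, length(keep), h)
  cnt <- integer(length(keep))
  pos_of <- integer(max(keep)); pos_of[keep] <- seq_along(keep)
  for (ix in chunk_indices(length(seqs), batch_size)) {
    batch <- seqs[ix]
    pb <- pad_batch(batch)
    fwd <- forward_encoder(model, pb$tok, pb$lens, train = FALSE, keep_cache = FALSE)
    B <- length(batch)
    for (b in seq_len(B)) {
      s <- batch[[b]]
      sel <- which(s %in% keep)
      if (length(sel) == 0) next
      rows <- flat_rows(b, sel, B)
      tgt <- pos_of[s[sel]]
      acc <- rowsum(fwd$H[rows, , drop = FALSE], tgt)
      gidx <- as.integer(rownames(acc))
      sums[gidx, ] <- sums[gidx, ] + acc
      tab <- tabulate(tgt, nbins = length(keep))
      cnt <- cnt + tab
    }
  }
  emb <- sums / cnt
  rownames(emb) <- if (!is.null(vocab)) vocab_taxon(vocab, keep) else as.character(keep)
  list(embeddings = emb, counts = setNames(cnt, rownames(emb)))
}

## k-means++ seeding: spreads initial centers by sampling points with
## probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1L, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - rep(X[i, ], each = n))^2))
  }
  centers
}

#' Cluster purity curve of an embedding space
#'
#' For each k, runs k-means (Euclidean, k-means++ seeding, best inertia over
#' `n_restarts` seeded restarts) and reports size-weighted purity: the
#' fraction of points whose cluster's majority label matches their own.
#'
#' @param embeddings numeric matrix (points x dims), rownames = taxon ids
#' @param labels character vector of labels (e.g. phylum per taxon), named
#'   by or aligned with the embedding rows
#' @param k_values integer vector of cluster counts
#' @param n_restarts restarts per k
#' @param seed seed for initialization
#' @return data.frame with `k` and `purity`
#' @export
purity_curve <- function(embeddings, labels, k_values, n_restarts = 10L, seed = 1L) {
  if (!is.null(names(labels))) labels <- labels[rownames(embeddings)]
  if (anyNA(labels)) {
    stopf("unlabeled taxa present: %s",
          paste(utils::head(rownames(embeddings)[is.na(labels)], 3), collapse = ", "))
  }
  stopifnot(length(labels) == nrow(embeddings), all(k_values >= 1),
            all(k_values <= nrow(embeddings)))
  labels <- as.integer(factor(labels))
  out <- vapply(k_values, function(k) {
    if (k == nrow(embeddings)) {
      ## one point per cluster: purity is 1 by construction
      return(1)
    }
    fit <- with_seed(derive_seed(seed, paste0("k", k)), {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        cent <- kmeanspp_centers(embeddings, k)
        cent <- cent[!duplicated(cent), , drop = FALSE]
        km <- suppressWarnings(stats::kmeans(embeddings, centers = cent, iter.max = 50))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best
    })
    cl <- fit$cluster
    sum(vapply(split(labels, cl), function(v) max(tabulate(v)), numeric(1))) / length(labels)
  }, numeric(1))
  data.frame(k = k_values, purity = out)
}

#' Spearman correlations between embedding dimensions and pathways
#'
#' Entry (i, j) is the Spearman rank correlation between embedding
#' dimension i and binary pathway column j over the taxa shared by both
#' inputs. Constant pathway columns (rank correlation undefined) are
#' recorded as 0 and flagged.
#'
#' @param embeddings taxa x dims matrix (rownames = taxon ids)
#' @param pathways taxa x pathways binary matrix (rownames = taxon ids)
#' @return list with `r` (dims x pathways matrix), `constant` (logical per
#'   pathway), `taxa` (shared taxon ids used)
#' @export
pathway_correlations <- function(embeddings, pathways) {
  shared <- intersect(rownames(embeddings), rownames(pathways))
  if (length(shared) < 3) stopf("need at least 3 shared taxa")
  E <- embeddings[shared, , drop = FALSE]
  P <- pathways[shared, , drop = FALSE]
  constant <- apply(P, 2, function(v) length(unique(v)) == 1)
  r <- suppressWarnings(stats::cor(E, P, method = "spearman"))
  r[, constant] <- 0
  r[is.na(r)] <- 0
  list(r = r, constant = constant, taxa = shared)
}

#' Permutation significance mask for pathway correlations
#'
#' Builds a null by permuting the taxon order of the embedding table
#' `n_perm` times and recomputing the full correlation matrix each time. By
#' default the null magnitudes of all dims x pathways x permutations are
#' pooled, and a cell is significant iff its |r| strictly exceeds every
#' pooled null value (the strictest reading; effectively p < 1/n_perm). The
#' `per_cell` variant compares each cell against its own permutation
#' distribution at level `1/(n_perm+1)`.
#'
#' @inheritParams pathway_correlations
#' @param n_perm number of permutations
#' @param seed seed for the permutations
#' @param method `"pooled_max"` (default) or `"per_cell"`
#' @return list with `mask` (logical dims x pathways), `r` (observed
#'   correlations), `null_max` (pooled null maximum |r|), `null_quantiles`
#' @export
permutation_mask <- function(embeddings, pathways, n_perm = 1000L, seed = 1L,
                             method = c("pooled_max", "per_cell")) {
  method <- match.arg(method)
  stopifnot(is_count(n_perm))
  obs <- pathway_correlations(embeddings, pathways)
  shared <- obs$taxa
  ## Spearman = Pearson on ranks; permuting taxa then ranking equals ranking
  ## then permuting rows, so rank once and permute rows of the ranked matrix.
  E <- apply(embeddings[shared, , drop = FALSE], 2, rank)
  P <- apply(pathways[shared, , drop = FALSE], 2, rank)
  Ec <- scale(E); Pc <- scale(P)
  Ec[is.na(Ec)] <- 0; Pc[is.na(Pc)] <- 0
  n <- length(shared)
  null_max <- -Inf
  exceed <- matrix(0L, ncol(E), ncol(P))
  qs <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample(n)
      rnull <- crossprod(Ec[pm, , drop = FALSE], Pc) / (n - 1)
      a <- abs(rnull)
      qs[b] <- max(a)
      if (method == "pooled_max") {
        null_max <- max(null_max, qs[b])
      } else {
        exceed <- exceed + (a >= abs(obs$r))
      }
    }
  })
  mask <- if (method == "pooled_max") abs(obs$r) > null_max else exceed == 0L
  mask[, obs$constant] <- FALSE
  list(mask = mask, r = obs$r, null_max = if (is.finite(null_max)) null_max else max(qs),
       null_quantiles = stats::quantile(qs, c(0.5, 0.95, 0.99)))
}

#' Cliff's delta effect size
#'
#' (#(a > b) - #(a < b)) / (n m) over all cross-set pairs.
#'
#' @param a,b numeric vectors
#' @return delta in \[-1, 1\]
#' @export
cliffs_delta <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ## O((n+m) log(n+m)) via ranks rather than the n*m outer comparison
  r <- rank(c(a, b))
  ra <- r[seq_along(a)]
  n <- length(a); m <- length(b)
  ## sum of "wins" of a over b with ties counting half:
  u <- sum(ra) - n * (n + 1) / 2
  2 * u / (n * m) - 1
}

#' Epps-Singleton two-sample test
#'
#' Characteristic-function omnibus test of equal distributions, evaluated
#' at points `t` scaled by the semi-interquartile range of the pooled
#' sample, with the standard small-sample correction when both samples have
#' fewer than 25 observations.
#'
#' @param x,y numeric samples (at least 5 observations each)
#' @param t evaluation points of the empirical characteristic function
#' @return list with `statistic`, `p_value`, `df`
#' @export
epps_singleton_test <- function(x, y, t = c(0.4, 0.8)) {
  nx <- length(x); ny <- length(y)
  if (nx < 5 || ny < 5) stopf("each sample needs at least 5 observations")
  n <- nx + ny
  sigma <- stats::IQR(c(x, y)) / 2
  if (sigma == 0) stopf("pooled sample has zero interquartile range")
  ts <- t / sigma
  gfun <- function(v) {
    out <- matrix(NA_real_, length(v), 2 * length(ts))
    for (j in seq_along(ts)) {
      out[, j] <- cos(ts[j] * v)
      out[, length(ts) + j] <- sin(ts[j] * v)
    }
    out
  }
  gx <- gfun(x); gy <- gfun(y)
  cov_b <- function(g) stats::cov(g) * (nrow(g) - 1) / nrow(g)
  est_cov <- (n / nx) * cov_b(gx) + (n / ny) * cov_b(gy)
  qrc <- qr(est_cov)
  r <- qrc$rank
  inv <- tryCatch(solve(est_cov), error = function(e) {
    ## Moore-Penrose fallback via SVD for rank-deficient covariance
    s <- svd(est_cov)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
  })
  g_diff <- colMeans(gx) - colMeans(gy)
  w <- n * as.numeric(t(g_diff) %*% inv %*% g_diff)
  if (max(nx, ny) < 25) {
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  }
  list(statistic = w, p_value = stats::pchisq(w, df = r, lower.tail = FALSE), df = r)
}

#' Compare magnitude distributions of significant correlations
#'
#' Given the |r| values flagged significant for two embedding spaces,
#' reports the two-sample Kolmogorov-Smirnov p-value, the Epps-Singleton
#' p-value (omitted with a warning when a set has fewer than 5 values), and
#' Cliff's delta of A versus B.
#'
#' @param sig_a,sig_b numeric vectors of significant |r| values
#' @return list with `ks_p`, `es_p` (may be NA), `cliffs_delta`, `n_a`, `n_b`
#' @export
compare_magnitude_distributions <- function(sig_a, sig_b) {
  stopifnot(length(sig_a) > 0, length(sig_b) > 0)
  ks <- suppressWarnings(stats::ks.test(sig_a, sig_b))
  es <- if (length(sig_a) >= 5 && length(sig_b) >= 5) {
    epps_singleton_test(sig_a, sig_b)$p_value
  } else {
    warnf("fewer than 5 values in a set; Epps-Singleton omitted")
    NA_real_
  }
  list(ks_p = unname(ks$p.value), es_p = es,
       cliffs_delta = cliffs_delta(sig_a, sig_b),
       n_a = length(sig_a), n_b = length(sig_b))
}
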