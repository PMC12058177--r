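test_that("ablation removes exactly one taxon, preserves order and commutes", {
  s <- c(1L, 4L, 7L, 5L, 9L)
  expect_identical(ablate(s, 7L), c(1L, 4L, 5L, 9L))
  expect_length(ablate(s, 9L), length(s) - 1L)
  expect_error(ablate(s, 6L), "not present")
  expect_identical(ablate(ablate(s, 4L), 9L), ablate(ablate(s, 9L), 4L))
})

test_that("attribution is the mean probability change over supporting samples", {
  ## constant model -> zero attribution
  seqs <- list(c(1L, 4L, 5L), c(1L, 4L), c(1L, 5L))
  rec <- attribute_taxon(function(s) 0.7, seqs, 4L)
  expect_equal(rec$a_value, 0)
  expect_identical(rec$support, 2L)

  ## single sample, hand-computed difference
  score <- function(s) if (5L %in% s) 0.9 else 0.7
  rec2 <- attribute_taxon(score, list(c(1L, 4L, 5L)), 5L)
  expect_equal(rec2$a_value, 0.2)
  expect_error(attribute_taxon(score, seqs, 99L), "no sample")
})

test_that("attribute_taxon matches a brute-force re-tokenizing oracle within 1e-9", {
  w <- small_world(); seqs <- small_seqs()
  tm_cfg <- model_config(w$vocab$size, embed_dim = 16L, hidden_dim = 16L,
                         n_blocks = 2L, n_heads = 2L, ff_dim = 32L,
                         max_positions = 60L, head_hidden = 12L, dropout = 0)
  clf <- build_model(tm_cfg, w$vocab, w$embeddings, head = "cls_binary", seed = 33L)

  ab <- unclass(w$abundance)
  set.seed(21)
  n_checked <- 0L
  while (n_checked < 60L) {
    i <- sample(nrow(ab), 1)
    present <- which(ab[i, ] > 0)
    if (length(present) < 2) next
    j <- sample(present, 1)
    m_idx <- vocab_index(w$vocab, colnames(ab)[j])
    ## oracle: zero the taxon in the abundance row and re-tokenize from scratch
    row2 <- ab[i, ]; row2[j] <- 0
    oracle_diff <- classify_sample(clf, rank_tokenize(ab[i, ], w$vocab)) -
      classify_sample(clf, rank_tokenize(row2, w$vocab))
    rec <- attribute_taxon(clf, seqs[i], m_idx)
    expect_lt(abs(rec$a_value - oracle_diff), 1e-9)
    n_checked <- n_checked + 1L
  }
})

test_that("attribution signs recover the weights of a linear-presence scorer", {
  set.seed(13)
  V <- 15L
  wgt <- rnorm(V)
  scorer <- function(s) {
    taxa <- s[s > 3L] - 3L
    stats::plogis(sum(wgt[taxa]))
  }
  seqs <- lapply(1:150, function(i) c(1L, sample(4:(V + 3L), sample(4:10, 1))))
  att <- attribute_all(scorer, seqs)
  expect_identical(nrow(att), V)
  expect_identical(sign(att$a_value), sign(wgt[att$taxon - 3L]))
  ## agreement with the one-taxon route
  one <- attribute_taxon(scorer, seqs, 7L)
  expect_equal(att$a_value[att$taxon == 7L], one$a_value)
  expect_equal(att$support[att$taxon == 7L], one$support)
})

test_that("confident-correct filtering keeps the top-confidence half of correct calls", {
  ## scores engineered so ranks are unambiguous
  p <- c(0.95, 0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.05, 0.6, 0.35)
  y <- c(1L,   1L,  1L,  0L,  0L,  0L,  0L,  1L,   1L,  1L)
  clf <- function(s) p[s[2] - 3L]
  seqs <- lapply(1:10, function(i) c(1L, i + 3L))
  keep <- filter_confident_correct(clf, seqs, y, quantile = 0.5)
  ## correct calls: 1,2,3 (pos side), 5,6,7 (neg side), 9 -> 7 samples with
  ## confidences .95 .9 .8 .7 .8 .9 .6; top ceil(3.5) = 4 by confidence with
  ## index tie-break: samples 1, 2, 7 (conf .9 tie), 3 (conf .8 tie)
  expect_identical(keep, sort(c(1L, 2L, 7L, 3L)))
  all_wrong <- as.integer(p <= 0.5)  # label opposite to every prediction
  expect_warning(out <- filter_confident_correct(clf, seqs, all_wrong, quantile = 0.5),
                 "no correct")
  expect_length(out, 0L)
  ## all correct with distinct confidences, quantile .5 -> half retained
  p2 <- seq(0.99, 0.51, length.out = 10)
  clf2 <- function(s) p2[s[2] - 3L]
  keep2 <- filter_confident_correct(clf2, seqs, rep(1L, 10), quantile = 0.5)
  expect_identical(keep2, 1:5)
})

test_that("cross-dataset validation keeps sign-matching taxa with shrinking survivor counts", {
  set.seed(17)
  V <- 12L
  wgt_a <- rnorm(V); wgt_b <- wgt_a
  ## taxon 2 flips sign between datasets -> must be excluded
  wgt_b[2] <- -wgt_a[2]
  mk_scorer <- function(w) function(s) stats::plogis(sum(w[s[s > 3L] - 3L]))
  mk_ds <- function(n, seed) {
    set.seed(seed)
    seqs <- lapply(1:n, function(i) c(1L, sample(4:(V + 3L), sample(5:9, 1))))
    labels <- as.integer(vapply(seqs, mk_scorer(wgt_a), numeric(1)) > 0.5)
    list(seqs = seqs, labels = labels)
  }
  da <- mk_ds(80, 1); db <- mk_ds(80, 2)
  ## model behaves like A's scorer on both (sign flip enters via labels below)
  spec <- validation_filter_spec(min_prevalence = 0.05, min_support = 5L)
  res <- validate_attributions(mk_scorer(wgt_a), da, db, spec)
  st <- res$stages
  expect_true(all(diff(c(st[["taxa_total"]], st[["after_prevalence"]],
                         st[["after_support"]], st[["after_sign_match"]])) <= 0))
  ## same model on both datasets: every surviving taxon sign-matches
  expect_identical(st[["after_support"]], st[["after_sign_match"]])
  ## ranked by magnitude within sign: positives first, descending |a|
  tab <- res$table
  pos <- tab[tab$sign > 0, ]
  expect_true(!is.unsorted(rev(pos$a_combined)))

  ## a genuinely sign-flipping model across datasets excludes the taxon:
  ## compare attributions computed separately
  att_a <- attribute_all(mk_scorer(wgt_a), da$seqs, taxa = 4:(V + 3L))
  att_b <- attribute_all(mk_scorer(wgt_b), db$seqs, taxa = 4:(V + 3L))
  expect_true(sign(att_a$a_value[att_a$taxon == 5L]) !=
                sign(att_b$a_value[att_b$taxon == 5L]))
})

test_that("permissive filters validate every taxon on a duplicated dataset", {
  set.seed(23)
  V <- 8L
  wgt <- rnorm(V)
  scorer <- function(s) stats::plogis(sum(wgt[s[s > 3L] - 3L]))
  seqs <- lapply(1:40, function(i) c(1L, sample(4:(V + 3L), sample(3:6, 1))))
  labels <- as.integer(vapply(seqs, scorer, numeric(1)) > 0.5)
  ds <- list(seqs = seqs, labels = labels)
  spec <- validation_filter_spec(confidence_quantile = 1, min_prevalence = 0,
                                 min_support = 1L)
  res <- validate_attributions(scorer, ds, ds, spec)
  occurring <- sort(unique(unlist(lapply(seqs, function(s) s[s > 3L]))))
  expect_setequal(res$table$taxon, occurring)
  expect_equal(res$table$a_a, res$table$a_b)
})
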