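## Feature-ablation attribution. For a probability-valued classifier M and
## taxon m, the attribution a(m) is the mean of M(X) - M(X \ m) over the
## samples X containing m: the expected drop in predicted positive
## probability when the taxon is deleted. The cross-study validation
## pipeline keeps only attributions whose sign replicates between two
## independently collected datasets, after confidence and prevalence
## filters.

#' Delete one taxon from a token sequence
#'
#' Removes the taxon and compacts positions (the survivor at rank i sits at
#' position i), so the result is itself a valid rank-ordered sequence.
#'
#' @param tokens token sequence (CLS first)
#' @param taxon integer token index to remove
#' @return shortened token sequence
#' @export
ablate <- function(tokens, taxon) {
  hit <- which(tokens == taxon)
  if (length(hit) == 0) stopf("taxon %d not present in sequence", taxon)
  tokens[-hit]
}

#' Feature-ablation attribution of one taxon
#'
#' @param model any probability-valued classifier accepted by
#'   [predict_proba()] (fine-tuned classifier, ensemble, or function)
#' @param seqs list of token sequences (the dataset D)
#' @param taxon integer token index of the taxon m
#' @return an `attribution_record` data.frame row: `taxon`, `a_value`
#'   (mean probability change), `support` (number of samples containing m)
#' @export
attribute_taxon <- function(model, seqs, taxon) {
  has <- vapply(seqs, function(s) any(s == taxon), logical(1))
  if (!any(has)) stopf("taxon %d appears in no sample", taxon)
  d <- seqs[has]
  p0 <- predict_proba(model, d)
  p1 <- predict_proba(model, lapply(d, ablate, taxon = taxon))
  data.frame(taxon = taxon, a_value = mean(p0 - p1), support = length(d))
}

#' Feature-ablation attributions for many taxa
#'
#' Computes a(m) for every requested taxon in one pass: each sample is
#' scored once intact, and once per contained candidate taxon with that
#' taxon ablated (batched inference).
#'
#' @param model probability-valued classifier
#' @param seqs list of token sequences
#' @param taxa integer token indices to attribute; default all taxa
#'   occurring in `seqs`
#' @param batch_size inference batch size
#' @return data.frame with `taxon`, `a_value`, `support`
#' @export
attribute_all <- function(model, seqs, taxa = NULL, batch_size = 64L) {
  occurring <- sort(unique(unlist(seqs)))
  occurring <- occurring[occurring > 3L]
  taxa <- if (is.null(taxa)) occurring else intersect(taxa, occurring)
  p0 <- predict_proba_batched(model, seqs, batch_size)
  taxa_set <- taxa
  jobs_seq <- integer(0); jobs_taxon <- integer(0)
  for (i in seq_along(seqs)) {
    present <- intersect(seqs[[i]], taxa_set)
    jobs_seq <- c(jobs_seq, rep.int(i, length(present)))
    jobs_taxon <- c(jobs_taxon, present)
  }
  abl <- vector("list", length(jobs_seq))
  for (j in seq_along(jobs_seq)) abl[[j]] <- ablate(seqs[[jobs_seq[j]]], jobs_taxon[j])
  p1 <- predict_proba_batched(model, abl, batch_size)
  diffs <- p0[jobs_seq] - p1
  agg <- rowsum(diffs, jobs_taxon)
  cnt <- as.vector(rowsum(rep(1, length(jobs_taxon)), jobs_taxon))
  out <- data.frame(taxon = as.integer(rownames(agg)),
                    a_value = as.vector(agg) / cnt, support = cnt)
  out[order(out$taxon), , drop = FALSE]
}

predict_proba_batched <- function(model, seqs, batch_size = 64L) {
  if (is.function(model)) return(vapply(seqs, model, numeric(1)))
  out <- numeric(length(seqs))
  for (ix in chunk_indices(length(seqs), batch_size)) {
    out[ix] <- predict_proba(model, seqs[ix])
  }
  out
}

#' Cross-study validation filter settings
#'
#' @param confidence_quantile keep correctly classified samples whose
#'   confidence ranks within this top fraction (pooled across classes)
#' @param min_prevalence drop taxa present in less than this fraction of
#'   all samples across the combined datasets (before confidence filtering)
#' @param min_support drop taxa appearing in fewer than this many filtered
#'   samples in either dataset
#' @param per_class_ranking rank confidence within each predicted class
#'   instead of pooled
#' @return a `validation_filter_spec` list
#' @export
validation_filter_spec <- function(confidence_quantile = 0.5,
                                   min_prevalence = 0.05,
                                   min_support = 5L,
                                   per_class_ranking = FALSE) {
  stopifnot(confidence_quantile > 0, confidence_quantile <= 1,
            min_prevalence >= 0, min_prevalence <= 1, is_count(min_support))
  structure(list(confidence_quantile = confidence_quantile,
                 min_prevalence = min_prevalence,
                 min_support = as.integer(min_support),
                 per_class_ranking = isTRUE(per_class_ranking)),
            class = "validation_filter_spec")
}

#' Keep confident, correctly classified samples
#'
#' A sample is kept when its prediction is correct at threshold 0.5 and its
#' confidence (predicted probability of the predicted class) ranks within
#' the top `quantile` among correct samples, pooled across classes.
#'
#' @param model probability-valued classifier
#' @param seqs list of token sequences
#' @param labels 0/1 labels
#' @param quantile top fraction retained
#' @param per_class rank within predicted class instead of pooled
#' @return integer indices of retained samples
#' @export
filter_confident_correct <- function(model, seqs, labels, quantile = 0.5,
                                     per_class = FALSE) {
  p <- predict_proba_batched(model, seqs)
  pred <- as.integer(p > 0.5)
  correct <- which(pred == labels)
  if (length(correct) == 0) {
    warnf("no correctly classified samples")
    return(integer(0))
  }
  conf <- ifelse(pred == 1, p, 1 - p)[correct]
  keep_top <- function(ix, cf) {
    k <- ceiling(quantile * length(ix))
    ix[order(-cf, ix)[seq_len(k)]]
  }
  if (per_class) {
    out <- c(keep_top(correct[pred[correct] == 1], conf[pred[correct] == 1]),
             keep_top(correct[pred[correct] == 0], conf[pred[correct] == 0]))
    sort(out)
  } else {
    sort(keep_top(correct, conf))
  }
}

#' Cross-dataset attribution validation
#'
#' Pipeline: (1) filter each dataset to confident-correct samples; (2) drop
#' taxa below the prevalence floor across the combined (unfiltered)
#' datasets; (3) compute per-dataset attributions and drop taxa with
#' support below the floor in either dataset; (4) keep taxa whose
#' attribution sign matches between datasets; (5) report the combined-mean
#' attribution over the pooled filtered samples, ranked by magnitude within
#' each sign.
#'
#' @param model probability-valued classifier applied to both datasets
#' @param dataset_a,dataset_b lists with `seqs` and `labels`
#' @param spec a [validation_filter_spec()]
#' @return list with `table` (validated attributions: taxon, a_combined,
#'   a_a, a_b, support_a, support_b, sign) and `stages` (survivor counts
#'   after each pipeline stage)
#' @export
validate_attributions <- function(model, dataset_a, dataset_b,
                                  spec = validation_filter_spec()) {
  keep_a <- filter_confident_correct(model, dataset_a$seqs, dataset_a$labels,
                                     spec$confidence_quantile, spec$per_class_ranking)
  keep_b <- filter_confident_correct(model, dataset_b$seqs, dataset_b$labels,
                                     spec$confidence_quantile, spec$per_class_ranking)
  fa <- dataset_a$seqs[keep_a]
  fb <- dataset_b$seqs[keep_b]

  all_seqs <- c(dataset_a$seqs, dataset_b$seqs)
  occ <- table(unlist(lapply(all_seqs, function(s) unique(s[s > 3L]))))
  prevalence <- as.vector(occ) / length(all_seqs)
  taxa_all <- as.integer(names(occ))
  stage1 <- taxa_all[prevalence >= spec$min_prevalence]

  att_a <- attribute_all(model, fa, taxa = stage1)
  att_b <- attribute_all(model, fb, taxa = stage1)
  m <- merge(att_a, att_b, by = "taxon", suffixes = c("_a", "_b"))
  stage2 <- m[m$support_a >= spec$min_support & m$support_b >= spec$min_support, ]
  stage3 <- stage2[sign(stage2$a_value_a) == sign(stage2$a_value_b) &
                     stage2$a_value_a != 0, ]

  if (nrow(stage3) > 0) {
    comb <- attribute_all(model, c(fa, fb), taxa = stage3$taxon)
    out <- merge(stage3, comb, by = "taxon")
    out <- data.frame(taxon = out$taxon, a_combined = out$a_value,
                      a_a = out$a_value_a, a_b = out$a_value_b,
                      support_a = out$support_a, support_b = out$support_b,
                      sign = sign(out$a_value))
    ## descending magnitude within positive sign first, then negative
    out <- out[order(-out$sign, -abs(out$a_combined), -pmax(out$support_a, out$support_b), out$taxon), ]
    rownames(out) <- NULL
  } else {
    out <- data.frame(taxon = integer(0), a_combined = numeric(0),
                      a_a = numeric(0), a_b = numeric(0),
                      support_a = integer(0), support_b = integer(0),
                      sign = numeric(0))
  }
  list(table = out,
       stages = c(taxa_total = length(taxa_all),
                  after_prevalence = length(stage1),
                  after_support = nrow(stage2),
                  after_sign_match = nrow(stage3)))
}
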