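## Token alphabet: three reserved special tokens followed by the taxa.
## Index layout is fixed: CLS = 1, MASK = 2, PAD = 3, taxa = 4 .. 3 + n_taxa.

#' Build a taxon vocabulary
#'
#' The discrete token alphabet consumed by the encoder: one integer index per
#' taxon identifier (ASV sequence, hash, or any unique string) plus reserved
#' `CLS`, `MASK` and `PAD` special tokens. Taxon indices are contiguous and
#' never collide with the special indices.
#'
#' @param taxon_ids character vector of unique taxon identifiers
#' @return an object of class `taxon_vocabulary`
#' @export
taxon_vocabulary <- function(taxon_ids) {
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(taxon_ids)) {
    stopf("duplicate taxon ids: %s", paste(head(unique(taxon_ids[duplicated(taxon_ids)]), 3), collapse = ", "))
  }
  if (length(taxon_ids) == 0) stopf("vocabulary needs at least one taxon")
  idx <- seq_along(taxon_ids) + 3L
  names(idx) <- taxon_ids
  structure(
    list(
      taxon_ids = taxon_ids,
      index = idx,
      cls_id = 1L, mask_id = 2L, pad_id = 3L,
      n_special = 3L,
      size = length(taxon_ids) + 3L
    ),
    class = "taxon_vocabulary"
  )
}

#' @export
print.taxon_vocabulary <- function(x, ...) {
  cat(sprintf("<taxon_vocabulary> %d taxa + 3 special tokens (CLS/MASK/PAD)\n", length(x$taxon_ids)))
  invisible(x)
}

#' Map taxon identifiers to token indices
#'
#' @param vocab a `taxon_vocabulary`
#' @param ids character vector of taxon identifiers
#' @return integer indices (NA for identifiers outside the vocabulary)
#' @export
vocab_index <- function(vocab, ids) {
  stopifnot(inherits(vocab, "taxon_vocabulary"))
  unname(vocab$index[as.character(ids)])
}

#' Map token indices back to taxon identifiers
#'
#' Special tokens map to `"<CLS>"`, `"<MASK>"`, `"<PAD>"`.
#'
#' @param vocab a `taxon_vocabulary`
#' @param idx integer token indices
#' @return character identifiers
#' @export
vocab_taxon <- function(vocab, idx) {
  stopifnot(inherits(vocab, "taxon_vocabulary"))
  out <- character(length(idx))
  special <- idx <= vocab$n_special
  out[special] <- c("<CLS>", "<MASK>", "<PAD>")[idx[special]]
  out[!special] <- vocab$taxon_ids[idx[!special] - vocab$n_special]
  out
}

vocab_hash <- function(vocab) object_digest(vocab$taxon_ids)
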