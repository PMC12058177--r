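## Readers/writers for the tabular artifacts of the pipeline and the
## rank-ordering step that turns an abundance profile into a token sequence.
## All writers emit files their own readers accept: identifiers bit-exactly,
## numeric values to within 1e-9.

#' Read a relative-abundance table
#'
#' TSV layout: samples as rows, taxa as columns, header row of taxon ids,
#' first column sample ids. The BIOM reader supports the dense/sparse JSON
#' dialect (via the biomformat package) with taxa as observation rows, which
#' are transposed to the samples-by-taxa orientation used throughout.
#' Rows are rescaled to sum to one; which rows needed rescaling is recorded
#' in the `renormalized` attribute.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom"`
#' @return an `abundance_table`: numeric samples-by-taxa matrix with
#'   attributes `renormalized` (sample ids that were rescaled)
#' @export
read_abundance <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2) stopf("abundance TSV needs a sample-id column plus at least one taxon column")
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("BIOM input requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    storage.mode(m) <- "double"
  }
  as_abundance_table(m)
}

#' Coerce a samples-by-taxa matrix to a normalized abundance table
#'
#' @param m numeric matrix, samples as rows (rownames) and taxa as columns
#'   (colnames), nonnegative entries
#' @return an `abundance_table`
#' @export
as_abundance_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  bad <- which(m < 0 | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf(
      "negative or non-finite abundance at sample '%s', taxon '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    )
  }
  rs <- rowSums(m)
  if (any(rs == 0)) stopf("all-zero sample row: '%s'", rownames(m)[which(rs == 0)[1]])
  off <- abs(rs - 1) > 1e-6
  m <- m / rs
  structure(m, renormalized = rownames(m)[off], class = c("abundance_table", "matrix", "array"))
}

#' Write an abundance table as TSV
#'
#' @param tab an `abundance_table` (or plain samples-by-taxa matrix)
#' @param path output path
#' @export
write_abundance <- function(tab, path) {
  df <- data.table::data.table(sample_id = rownames(tab))
  df <- cbind(df, data.table::as.data.table(unclass(tab)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `taxon_id, phylum, class, order, family, genus`; the
#' literal string `"NA"` (or an empty field) marks a missing rank.
#'
#' @param path file path
#' @return data.frame keyed by `taxon_id`, one row per taxon
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  need <- c("taxon_id", "phylum", "class", "order", "family", "genus")
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (!all(need %in% names(df))) {
    stopf("taxonomy header must contain: %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$taxon_id)) {
    stopf("duplicate taxon_id in taxonomy: '%s'", df$taxon_id[duplicated(df$taxon_id)][1])
  }
  rownames(df) <- df$taxon_id
  df
}

#' Write a taxonomy table as TSV
#' @param tax data.frame as returned by [read_taxonomy()]
#' @param path output path
#' @export
write_taxonomy <- function(tax, path) {
  data.table::fwrite(tax, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a taxon embedding matrix
#'
#' TSV: first column taxon id, remaining columns numeric embedding
#' coordinates. All rows must have the same dimension.
#'
#' @param path file path
#' @return numeric matrix, taxa as rows (rownames = taxon ids)
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2) stopf("embedding TSV needs taxon_id plus >= 1 numeric column")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stopf("non-numeric embedding entry in column %d", bad + 1L)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric embedding entry at row %d, column %d", bad[1], bad[2] + 1L)
  }
  rownames(m) <- ids
  colnames(m) <- paste0("d", seq_len(ncol(m)))
  m
}

#' Write a taxon embedding matrix as TSV
#' @param emb numeric matrix with taxon ids as rownames
#' @param path output path
#' @export
write_embeddings <- function(emb, path) {
  df <- data.table::data.table(taxon_id = rownames(emb))
  df <- cbind(df, data.table::as.data.table(emb))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a binary taxon-by-pathway membership matrix
#' @param path TSV: first column taxon id, remaining columns 0/1 pathway flags
#' @return binary matrix, taxa as rows, pathways as columns
#' @export
read_pathways <- function(path) {
  m <- read_embeddings(path)
  if (!all(m %in% c(0, 1))) stopf("pathway matrix entries must be 0/1")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE, nrows = 0)
  colnames(m) <- names(dt)[-1]
  m
}

#' Read phenotype labels
#' @param path TSV with columns `sample_id, label, patient_id`
#' @return data.frame with character sample/patient ids and integer 0/1 labels
#' @export
read_labels <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("sample_id", "patient_id")))
  need <- c("sample_id", "label", "patient_id")
  if (!all(need %in% names(df))) stopf("labels header must contain: %s", paste(need, collapse = ", "))
  if (!all(df$label %in% c(0, 1))) stopf("labels must be 0/1")
  df$label <- as.integer(df$label)
  df[, need]
}

#' Rank-tokenize one abundance profile
#'
#' Orders the taxa present in a sample by strictly decreasing relative
#' abundance (ties broken by ascending vocabulary index), keeps at most
#' `max_taxa` of the most abundant, and prepends the `CLS` token. This is the
#' "sample as sentence" representation the encoder consumes; the abundance
#' values themselves are discarded after ranking — rank order is the only
#' abundance information the model sees, carried by its absolute positional
#' embeddings.
#'
#' Taxa present in the sample but absent from the vocabulary are dropped and
#' counted in the `n_unknown` attribute (this is the normal situation when a
#' fixed training vocabulary is applied to an external study).
#'
#' @param abund named numeric vector of abundances (names = taxon ids), or a
#'   single row of an `abundance_table`
#' @param vocab a `taxon_vocabulary`
#' @param max_taxa cap on retained taxa (default 512); the CLS token does not
#'   count against the cap, so sequences have length at most `max_taxa + 1`
#' @return integer vector of token indices starting with CLS, with attribute
#'   `n_unknown`
#' @export
rank_tokenize <- function(abund, vocab, max_taxa = 512L) {
  stopifnot(inherits(vocab, "taxon_vocabulary"), is_count(max_taxa))
  present <- which(abund > 0)
  ids <- names(abund)[present]
  idx <- vocab$index[ids]
  known <- !is.na(idx)
  n_unknown <- sum(!known)
  if (n_unknown > 0) warnf("%d taxa not in vocabulary were dropped", n_unknown)
  a <- abund[present][known]
  idx <- unname(idx[known])
  ord <- order(-a, idx, method = "radix")
  keep <- head(ord, max_taxa)
  structure(c(vocab$cls_id, idx[keep]), n_unknown = n_unknown)
}

#' Rank-tokenize every sample of an abundance table
#'
#' @param tab an `abundance_table`
#' @inheritParams rank_tokenize
#' @return named list of token sequences (one per sample row)
#' @export
tokenize_table <- function(tab, vocab, max_taxa = 512L) {
  out <- vector("list", nrow(tab))
  names(out) <- rownames(tab)
  for (i in seq_len(nrow(tab))) {
    out[[i]] <- suppressWarnings(rank_tokenize(tab[i, ], vocab, max_taxa))
  }
  out
}
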