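## Ground-truth-known synthetic microbiome worlds. The generator emulates
## the statistical structure the pipeline assumes: sparse compositional
## samples with block co-occurrence guilds, a taxonomy nested around the
## guilds (phyla contain blocks), pathway annotations correlated with
## blocks, block-structured vocabulary embeddings, and planted
## phenotype-discriminative taxa whose prevalence differs between classes.

#' Synthetic world configuration
#'
#' Defaults give a desk-scale world: 300 taxa in 10 co-occurrence blocks,
#' 1,000 samples from 500 patients (2 samples each), a mean community
#' richness of about 36 taxa per sample, and 5 planted taxa present in 80%
#' of positive-class samples but only 10% of negatives.
#'
#' @param n_taxa number of taxa
#' @param n_samples number of samples
#' @param n_blocks number of co-occurrence blocks (guilds)
#' @param block_active_prob probability a block is active in a sample
#' @param base_prevalence presence probability of a taxon whose block is
#'   inactive
#' @param cooccurrence_boost multiplier on `base_prevalence` when the
#'   taxon's block is active in the sample
#' @param taxon_scale_sd sd of per-taxon log-abundance offsets (stable
#'   rank structure across samples)
#' @param abundance_sigma lognormal sdlog of per-(sample,taxon) abundance
#' @param n_phyla phyla in the generated taxonomy (blocks nest into phyla)
#' @param na_genus_rate fraction of taxa with missing genus annotation
#' @param n_pathways number of pathway columns
#' @param pathway_blocks_per blocks associated with each pathway
#' @param pathway_in_prob membership probability for taxa of an associated
#'   block
#' @param pathway_bg_prob background membership probability
#' @param embed_dim vocabulary embedding dimension
#' @param embed_block_sd sd of block-mean embedding vectors
#' @param embed_noise_sd sd of per-taxon embedding noise around block mean
#' @param planted_effects list of lists with `taxa` (ids or indices),
#'   `p_pos`, `p_neg` (presence prevalence per class); NULL plants the
#'   default 5-taxon 0.8/0.1 effect; an empty list disables planted signal
#' @param positive_fraction fraction of positive-class patients
#' @param samples_per_patient samples drawn per patient
#' @param seed world seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_taxa = 300L, n_samples = 1000L, n_blocks = 10L,
                             block_active_prob = 0.5, base_prevalence = 0.03,
                             cooccurrence_boost = 7,
                             taxon_scale_sd = 1, abundance_sigma = 1,
                             n_phyla = 4L, na_genus_rate = 0.10,
                             n_pathways = 30L, pathway_blocks_per = 2L,
                             pathway_in_prob = 0.7, pathway_bg_prob = 0.05,
                             embed_dim = 100L, embed_block_sd = 1,
                             embed_noise_sd = 0.5,
                             planted_effects = NULL,
                             positive_fraction = 0.35,
                             samples_per_patient = 2L, seed = 1L) {
  stopifnot(is_count(n_taxa), is_count(n_samples), is_count(n_blocks),
            n_blocks <= n_taxa,
            block_active_prob > 0, block_active_prob <= 1,
            base_prevalence > 0, base_prevalence <= 1,
            base_prevalence * cooccurrence_boost <= 1,
            is_count(n_phyla), n_phyla <= n_blocks,
            is_count(n_pathways), is_count(pathway_blocks_per),
            pathway_blocks_per <= n_blocks,
            is_count(embed_dim), positive_fraction > 0, positive_fraction < 1,
            is_count(samples_per_patient), n_samples %% samples_per_patient == 0)
  taxon_ids <- sprintf("taxon_%04d", seq_len(n_taxa))
  blocks <- ceiling(seq_len(n_taxa) / (n_taxa / n_blocks))
  if (is.null(planted_effects)) {
    ## first taxon of each of the first 5 blocks
    first_of_block <- match(seq_len(min(5L, n_blocks)), blocks)
    planted_effects <- list(list(taxa = taxon_ids[first_of_block],
                                 p_pos = 0.8, p_neg = 0.1))
  }
  for (pe in planted_effects) {
    stopifnot(all(pe$taxa %in% taxon_ids),
              pe$p_pos >= 0, pe$p_pos <= 1, pe$p_neg >= 0, pe$p_neg <= 1)
  }
  structure(list(
    n_taxa = as.integer(n_taxa), n_samples = as.integer(n_samples),
    n_blocks = as.integer(n_blocks), block_active_prob = block_active_prob,
    base_prevalence = base_prevalence, cooccurrence_boost = cooccurrence_boost,
    taxon_scale_sd = taxon_scale_sd, abundance_sigma = abundance_sigma,
    n_phyla = as.integer(n_phyla), na_genus_rate = na_genus_rate,
    n_pathways = as.integer(n_pathways),
    pathway_blocks_per = as.integer(pathway_blocks_per),
    pathway_in_prob = pathway_in_prob, pathway_bg_prob = pathway_bg_prob,
    embed_dim = as.integer(embed_dim), embed_block_sd = embed_block_sd,
    embed_noise_sd = embed_noise_sd, planted_effects = planted_effects,
    positive_fraction = positive_fraction,
    samples_per_patient = as.integer(samples_per_patient),
    seed = as.integer(seed),
    taxon_ids = taxon_ids, blocks = blocks
  ), class = "synthetic_config")
}

#' Generate a synthetic microbiome world
#'
#' Per sample: the patient's phenotype decides the presence prevalence of
#' planted taxa; every block is independently active or not; non-planted
#' taxa are present with the base prevalence, boosted when their block is
#' active; present taxa get lognormal abundances (stable per-taxon offsets
#' plus per-sample noise) renormalized to relative abundances.
#'
#' @param config a [synthetic_config()]
#' @return a `synthetic_world`: list with `abundance` (`abundance_table`),
#'   `labels` (sample_id/label/patient_id data.frame), `taxonomy`,
#'   `pathways` (binary matrix, taxa in no pathway dropped), `embeddings`,
#'   `vocab`, and `truth` (generative ground truth)
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples; nt <- cfg$n_taxa
    n_patients <- n %/% cfg$samples_per_patient
    patient_label <- rbinom(n_patients, 1, cfg$positive_fraction)
    ## guard: both classes must exist for a labeled world
    if (length(unique(patient_label)) == 1 && length(cfg$planted_effects) > 0) {
      patient_label[1] <- 1 - patient_label[1]
    }
    patient_of <- rep(seq_len(n_patients), each = cfg$samples_per_patient)
    y <- patient_label[patient_of]

    p_active <- min(1, cfg$base_prevalence * cfg$cooccurrence_boost)
    active <- matrix(rbinom(n * cfg$n_blocks, 1, cfg$block_active_prob),
                     n, cfg$n_blocks)
    prob <- cfg$base_prevalence +
      active[, cfg$blocks, drop = FALSE] * (p_active - cfg$base_prevalence)
    planted_ids <- character(0)
    for (pe in cfg$planted_effects) {
      j <- match(pe$taxa, cfg$taxon_ids)
      prob[, j] <- ifelse(y == 1, pe$p_pos, pe$p_neg)
      planted_ids <- c(planted_ids, pe$taxa)
    }
    present <- matrix(runif(n * nt), n, nt) < prob
    empty <- which(rowSums(present) == 0)
    for (i in empty) present[i, sample.int(nt, 1)] <- TRUE

    mu_t <- rnorm(nt, 0, cfg$taxon_scale_sd)
    vals <- matrix(0, n, nt)
    idx <- which(present)
    vals[idx] <- rlnorm(length(idx),
                        meanlog = mu_t[(idx - 1) %/% n + 1],
                        sdlog = cfg$abundance_sigma)
    rownames(vals) <- sprintf("S%05d", seq_len(n))
    colnames(vals) <- cfg$taxon_ids
    abundance <- as_abundance_table(vals)

    labels <- data.frame(sample_id = rownames(vals), label = as.integer(y),
                         patient_id = sprintf("P%05d", patient_of))

    ## taxonomy: contiguous block chunks nest into phyla; one class/order/
    ## family lineage per block; genus per taxon with missingness
    phylum_of_block <- ceiling(seq_len(cfg$n_blocks) / (cfg$n_blocks / cfg$n_phyla))
    tax <- data.frame(
      taxon_id = cfg$taxon_ids,
      phylum = sprintf("Phylum_%02d", phylum_of_block[cfg$blocks]),
      class = sprintf("Class_%02d", cfg$blocks),
      order = sprintf("Order_%02d", cfg$blocks),
      family = sprintf("Family_%02d", cfg$blocks),
      genus = sprintf("Genus_%04d", seq_len(nt)),
      stringsAsFactors = FALSE
    )
    tax$genus[runif(nt) < cfg$na_genus_rate] <- NA_character_
    rownames(tax) <- tax$taxon_id

    pathway_blocks <- lapply(seq_len(cfg$n_pathways), function(p) {
      sort(sample.int(cfg$n_blocks, cfg$pathway_blocks_per))
    })
    pw <- matrix(0L, nt, cfg$n_pathways,
                 dimnames = list(cfg$taxon_ids,
                                 sprintf("pathway_%03d", seq_len(cfg$n_pathways))))
    for (p in seq_len(cfg$n_pathways)) {
      pin <- cfg$blocks %in% pathway_blocks[[p]]
      pr <- ifelse(pin, cfg$pathway_in_prob, cfg$pathway_bg_prob)
      pw[, p] <- as.integer(runif(nt) < pr)
    }
    pw <- pw[rowSums(pw) > 0, , drop = FALSE]

    block_means <- matrix(rnorm(cfg$n_blocks * cfg$embed_dim, 0, cfg$embed_block_sd),
                          cfg$n_blocks, cfg$embed_dim)
    emb <- block_means[cfg$blocks, , drop = FALSE] +
      matrix(rnorm(nt * cfg$embed_dim, 0, cfg$embed_noise_sd), nt, cfg$embed_dim)
    rownames(emb) <- cfg$taxon_ids
    colnames(emb) <- paste0("d", seq_len(cfg$embed_dim))

    structure(list(
      abundance = abundance, labels = labels, taxonomy = tax,
      pathways = pw, embeddings = emb,
      vocab = taxon_vocabulary(cfg$taxon_ids),
      truth = list(config = cfg, blocks = setNames(cfg$blocks, cfg$taxon_ids),
                   planted = planted_ids, pathway_blocks = pathway_blocks,
                   patient_label = patient_label)
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d samples x %d taxa, %d blocks, %d planted taxa\n",
              nrow(x$abundance), ncol(x$abundance),
              x$truth$config$n_blocks, length(x$truth$planted)))
  invisible(x)
}

#' Summary report of a synthetic world
#'
#' The empirical numbers recovery tests compare against the configuration:
#' per-taxon prevalence, planted-taxon prevalence per class, class balance,
#' and mean within- versus between-block pairwise co-occurrence odds
#' ratios (on a seeded subsample of taxon pairs).
#'
#' @param world a `synthetic_world`
#' @param n_pairs pairs sampled per stratum for the odds-ratio summary
#' @param seed seed for pair sampling
#' @return list with `prevalence`, `planted_prevalence`, `class_balance`,
#'   `odds_ratio` (within/between means), `richness` (mean taxa per sample)
#' @export
world_report <- function(world, n_pairs = 400L, seed = 1L) {
  present <- unclass(world$abundance) > 0
  prevalence <- colMeans(present)
  y <- world$labels$label
  planted <- world$truth$planted
  planted_prev <- if (length(planted) > 0) {
    data.frame(
      taxon_id = planted,
      prev_pos = colMeans(present[y == 1, planted, drop = FALSE]),
      prev_neg = colMeans(present[y == 0, planted, drop = FALSE])
    )
  } else {
    data.frame(taxon_id = character(0), prev_pos = numeric(0), prev_neg = numeric(0))
  }
  blocks <- world$truth$blocks
  lor <- function(i, j) {
    a <- sum(present[, i] & present[, j]) + 0.5
    b <- sum(present[, i] & !present[, j]) + 0.5
    c <- sum(!present[, i] & present[, j]) + 0.5
    d <- sum(!present[, i] & !present[, j]) + 0.5
    log(a * d / (b * c))
  }
  ors <- with_seed(seed, {
    nt <- length(blocks)
    within <- replicate(n_pairs, {
      b <- sample(unique(blocks), 1)
      ij <- sample(which(blocks == b), 2)
      lor(ij[1], ij[2])
    })
    between <- replicate(n_pairs, {
      bs <- sample(unique(blocks), 2)
      lor(sample(which(blocks == bs[1]), 1), sample(which(blocks == bs[2]), 1))
    })
    c(within = mean(within), between = mean(between))
  })
  list(prevalence = prevalence, planted_prevalence = planted_prev,
       class_balance = mean(y), odds_ratio = ors,
       richness = mean(rowSums(present)))
}

#' Write a synthetic world to disk
#'
#' Emits `abundance.tsv`, `labels.tsv`, `taxonomy.tsv`, `pathways.tsv`,
#' `embeddings.tsv` and `truth.json`, all readable by the package loaders.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(world$abundance, file.path(dir, "abundance.tsv"))
  data.table::fwrite(world$labels, file.path(dir, "labels.tsv"), sep = "\t")
  write_taxonomy(world$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_embeddings(world$pathways, file.path(dir, "pathways.tsv"))
  write_embeddings(world$embeddings, file.path(dir, "embeddings.tsv"))
  truth <- world$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a synthetic world from disk
#'
#' @param dir directory written by [write_world()]
#' @return list with the same table components as a `synthetic_world`
#'   (ground truth reloaded from `truth.json`)
#' @export
load_world <- function(dir) {
  list(
    abundance = read_abundance(file.path(dir, "abundance.tsv")),
    labels = read_labels(file.path(dir, "labels.tsv")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    pathways = read_pathways(file.path(dir, "pathways.tsv")),
    embeddings = read_embeddings(file.path(dir, "embeddings.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  )
}
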