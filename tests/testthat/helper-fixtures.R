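## Shared fixtures, memoized so expensive objects (the pre-trained encoder,
## the fine-tuned classifier) are built once per test session.

fx <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (!exists(name, envir = fx, inherits = FALSE)) assign(name, fn(), envir = fx)
  get(name, envir = fx)
}

## ---- tiny building blocks for unit tests ----------------------------------

tiny_vocab <- function(n = 12L) taxon_vocabulary(sprintf("t%02d", seq_len(n)))

tiny_embeddings <- function(vocab, d = 8L, seed = 1L) {
  n <- length(vocab$taxon_ids)
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), n, d)
  rownames(m) <- vocab$taxon_ids
  m
}

tiny_model <- function(head = "cls_binary", n = 12L, seed = 3L, dropout = 0, ...) {
  vocab <- tiny_vocab(n)
  emb <- tiny_embeddings(vocab, d = 8L)
  cfg <- model_config(vocab$size, embed_dim = 8L, hidden_dim = 16L, n_blocks = 2L,
                      n_heads = 2L, ff_dim = 32L, max_positions = 20L,
                      head_hidden = 12L, dropout = dropout, ...)
  list(model = build_model(cfg, vocab, emb, head = head, seed = seed),
       vocab = vocab, emb = emb, cfg = cfg)
}

rand_seq <- function(vocab, len) c(vocab$cls_id, sample(seq_along(vocab$taxon_ids) + 3L, len))

## ---- small learnable world (fast training unit tests) ---------------------

small_world <- function() memo("small_world", function() {
  generate_world(synthetic_config(
    n_taxa = 60L, n_samples = 200L, n_blocks = 6L, n_pathways = 12L,
    embed_dim = 16L, seed = 5L))
})

small_seqs <- function() memo("small_seqs", function() {
  w <- small_world()
  tokenize_table(w$abundance, w$vocab)
})

## untrained encoder at an SGD-friendly initialization scale (a random
## encoder at the default BERT-style init_sd is only fine-tunable after
## Adam pre-training has grown its weights; init_sd 0.2 makes it trainable
## directly, which keeps the fast training unit tests self-contained)
small_encoder <- function() memo("small_encoder", function() {
  w <- small_world()
  cfg <- model_config(w$vocab$size, embed_dim = 16L, hidden_dim = 24L,
                      n_blocks = 2L, n_heads = 2L, ff_dim = 96L,
                      max_positions = 60L, head_hidden = 24L, dropout = 0,
                      init_sd = 0.2)
  build_model(cfg, w$vocab, w$embeddings, head = "token_binary", seed = 21L)
})

## ---- the study-scale fixture shared by the acceptance suite ---------------
## Default synthetic world; encoder pre-trained with the ELECTRA curriculum
## at scaled epoch counts (24 generator epochs / checkpoint every 3; 48
## discriminator epochs / swap every 6 -> the same 8-checkpoint structure as
## the reference 240/30/120/15 schedule).

acc_world <- function() memo("acc_world", function() generate_world(synthetic_config()))

acc_seqs <- function() memo("acc_seqs", function() {
  w <- acc_world()
  tokenize_table(w$abundance, w$vocab)
})

acc_model_config <- function() {
  w <- acc_world()
  model_config(w$vocab$size, embed_dim = 100L, hidden_dim = 64L, n_blocks = 2L,
               n_heads = 4L, ff_dim = 256L, max_positions = 160L,
               head_hidden = 64L, dropout = 0)
}

acc_schedule <- function() {
  pretrain_schedule(generator_epochs = 24L, generator_checkpoint_every = 3L,
                    discriminator_epochs = 48L, generator_swap_every = 6L,
                    batch_size = 64L, lr = 1e-3)
}

acc_train_ix <- 1:800
acc_heldout_ix <- 801:1000

acc_pretrained <- function() memo("acc_pretrained", function() {
  w <- acc_world()
  pretrain(acc_seqs()[acc_train_ix], w$vocab, w$embeddings,
           acc_model_config(), acc_schedule(), seed = 20240901L)
})

## scaled fine-tuning regime: reference optimizer/loss/augmentation with a
## step size and epoch budget matched to the desk-scale corpus
acc_finetune_config <- function(epochs = 10L, ...) {
  finetune_config(learning_rate = 0.1, epochs = epochs, ...)
}

acc_split <- function() memo("acc_split", function() {
  patient_blocked_split(acc_world()$labels, seed = 31L)
})

acc_single <- function() memo("acc_single", function() {
  w <- acc_world(); sp <- acc_split()
  nontest <- c(sp$train, sp$val)
  finetune(acc_pretrained()$discriminator, acc_seqs()[nontest],
           w$labels$label[nontest], acc_finetune_config(),
           stopping_epoch = 10L, seed = 41L)
})

## shifted companion world: attenuated planted effect, shifted composition
## statistics, ~50% vocabulary overlap with the training world
acc_shifted <- function() memo("acc_shifted", function() {
  w <- acc_world()
  cfg <- synthetic_config(
    block_active_prob = 0.6, base_prevalence = 0.04, cooccurrence_boost = 6,
    abundance_sigma = 1.3, positive_fraction = 0.6,
    planted_effects = list(list(taxa = sprintf("taxon_%04d", c(1, 31, 61, 91, 121)),
                                p_pos = 0.7, p_neg = 0.15)),
    n_samples = 400L, seed = 77L)
  ws <- generate_world(cfg)
  ab <- unclass(ws$abundance)
  set.seed(177)
  novel <- sample(setdiff(colnames(ab), ws$truth$planted), 150)
  colnames(ab)[match(novel, colnames(ab))] <- sprintf("novel_%04d", seq_along(novel))
  list(seqs = suppressWarnings(tokenize_table(as_abundance_table(ab), w$vocab)),
       labels = ws$labels$label)
})
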