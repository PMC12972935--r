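# Shared fixtures: tiny corpora, models and tokenizers built in code.

tiny_corpus <- function(n = 60L, seed = 7L, rho = 0.7,
                        imbalance = c(mild = 0.45, moderate = 0.35,
                                      severe = 0.20),
                        strength = "strong") {
  generate_corpus(generator_config(
    n_records = n, score_correlation = rho, imbalance = imbalance,
    lexicon = default_lexicon(strength), seed = seed))
}

tiny_model_fixture <- function(seed = 3L, vocab_size = 40L) {
  spec <- encoder_spec("tiny_random", n_layers = 2L, n_heads = 2L,
                       hidden_dim = 8L, ff_dim = 16L, max_len = 24L,
                       vocab_size = vocab_size, mlp_hidden = 12L,
                       mlp_out = 10L)
  init_multitask_model(spec, seed = seed)
}

# Training profile for small randomly initialized encoders: higher learning
# rate and lighter dropout than the fine-tuning defaults.
desk_train_config <- function(seed, epochs = 15L) {
  train_config(epochs = epochs, batch_size = 58L, lr_max = 3e-3,
               lr_min = 3e-4, dropout = 0.1, stochastic_depth_rate = 0.1,
               patience = 5L, seed = seed)
}

write_tmp_jsonl <- function(df, lines_extra = NULL) {
  path <- tempfile(fileext = ".jsonl")
  write_corpus(df, path)
  if (!is.null(lines_extra)) {
    cat(lines_extra, file = path, append = TRUE, sep = "\n")
  }
  path
}
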