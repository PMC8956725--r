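# Shared fixtures: one small synthetic corpus and one small embedding model,
# built once per test run. Sizes are deliberately modest; the acceptance
# tests exercise the full default configuration.

small_config <- function(seed = 42L, ...) {
  synthetic_config(n_posts = 400, n_accounts = 60, tokens_per_post = c(8, 14),
                   seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

fixture_corpus <- function() {
  if (is.null(.fixtures$gen)) .fixtures$gen <- generate_corpus(small_config())
  .fixtures$gen
}

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_skipgram(fixture_corpus()$pool, dim = 48, window = 5,
                                      min_count = 3, epochs = 8, seed = 1L)
  }
  .fixtures$model
}

# Field pool for one theme of the fixture corpus, labelled with its code.
fixture_theme_pool <- function(theme = "IF-PE") {
  gen <- fixture_corpus()
  ids <- gen$truth$posts$post_id[!is.na(gen$truth$posts$theme) &
                                   gen$truth$posts$theme == theme]
  pool <- gen$pool[gen$pool$id %in% ids, ]
  pool <- post_pool(pool)
  pool$theme_code <- theme
  pool
}

# Hand-built pool for I/O and filter tests.
toy_pool <- function(follower_counts = c(10, 20, 30)) {
  n <- length(follower_counts)
  post_pool(tibble::tibble(
    id = paste0("p", seq_len(n)),
    account_id = paste0("a", seq_len(n)),
    follower_count = follower_counts,
    date = rep("2015-06-01", n),
    text = paste("alpha beta", seq_len(n)),
    tokens = lapply(seq_len(n), function(i) c("alpha", "beta", paste0("tok", i))),
    pos_tags = lapply(seq_len(n), function(i) c("n", "n", "v"))
  ))
}

# Hand-built embedding model with explicit vectors (rownames are tokens).
toy_model <- function(vectors) {
  structure(list(vectors = vectors, counts = NULL, dim = ncol(vectors),
                 window = NA_integer_, min_count = NA_integer_,
                 epochs = NA_integer_, negative = NA_integer_,
                 seed = NA_integer_),
            class = "embedding_model")
}
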