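#' Train a skip-gram word-embedding model
#'
#' Trains word vectors on the tokenized posts of a pool with the skip-gram
#' objective and negative sampling. The defaults mirror the settings used
#' for the background-knowledge corpus: context window 10 and vector
#' dimension 400. Training is single-threaded with an internal seeded RNG,
#' so a given `(pool, parameters, seed)` always yields identical vectors.
#'
#' @param pool A tokenized [post_pool()].
#' @param dim Vector dimension (default 400).
#' @param window Maximum context window; the effective window per position
#'   is drawn uniformly from `1..window` as usual for skip-gram.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @param seed Integer seed.
#' @return An `embedding_model`: list with `vectors` (vocab x dim matrix,
#'   rownames are tokens), `counts`, and the training parameters.
#' @export
train_skipgram <- function(pool, dim = 400, window = 10, min_count = 5,
                           epochs = 5, negative = 5,
                           alpha = 0.025, min_alpha = 1e-4, seed = 1L) {
  sentences <- pool$tokens[lengths(pool$tokens) >= 2]
  if (length(sentences) == 0) {
    stop("pool has no post with >= 2 tokens; tokenize it first", call. = FALSE)
  }
  freq <- table(unlist(sentences))
  freq <- freq[freq >= min_count]
  if (length(freq) == 0) {
    stop("empty effective vocabulary: no token reaches min_count = ",
         min_count, call. = FALSE)
  }
  # deterministic vocabulary order: frequency desc, then token
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  vocab <- names(freq)[ord]
  counts <- as.integer(freq)[ord]
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  enc <- lapply(sentences, function(toks) {
    ids <- idx[toks]
    as.integer(ids[!is.na(ids)])
  })
  enc <- enc[lengths(enc) >= 2]
  if (length(enc) == 0) {
    stop("empty effective vocabulary: no sentence retains >= 2 in-vocabulary tokens",
         call. = FALSE)
  }
  mat <- sgns_train_cpp(enc, counts, as.integer(dim), as.integer(window),
                        as.integer(epochs), as.integer(negative),
                        alpha, min_alpha, as.integer(seed))
  rownames(mat) <- vocab
  structure(list(vectors = mat, counts = stats::setNames(counts, vocab),
                 dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count), epochs = as.integer(epochs),
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", nrow(x$vectors), " tokens x ", x$dim,
      " dims (window ", x$window, ", min_count ", x$min_count, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Vocabulary of an embedding model
#' @param model An `embedding_model`.
#' @return Character vector of tokens.
#' @export
embedding_vocabulary <- function(model) rownames(model$vectors)

embedding_vector <- function(model, token) {
  if (!token %in% rownames(model$vectors)) {
    stop("token not in embedding vocabulary: ", token, call. = FALSE)
  }
  model$vectors[token, ]
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Cosine similarity and distance between vocabulary tokens
#'
#' `embedding_distance()` is `1 - cos(vec(w1), vec(w2))`: symmetric, zero
#' for identical tokens, and bounded by `[0, 2]`.
#'
#' @param model An `embedding_model`.
#' @param w1,w2 Vocabulary tokens.
#' @return A single number.
#' @export
embedding_distance <- function(model, w1, w2) {
  1 - embedding_similarity(model, w1, w2)
}

#' @rdname embedding_distance
#' @export
embedding_similarity <- function(model, w1, w2) {
  if (identical(w1, w2)) {
    embedding_vector(model, w1)  # still error on OOV
    return(1)
  }
  cosine_similarity(embedding_vector(model, w1), embedding_vector(model, w2))
}

#' Read and write models in the word2vec text format
#'
#' One header line `"<vocab> <dim>"` followed by one `token v1 ... vdim`
#' line per token, UTF-8.
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @return `read_word2vec()` returns an `embedding_model` (training
#'   parameters other than `dim` are unknown and stored as `NA`).
#' @export
write_word2vec <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dim), con)
  lines <- vapply(seq_len(nrow(model$vectors)), function(i) {
    paste(rownames(model$vectors)[i],
          paste(sprintf("%.17g", model$vectors[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- header[1]; dim <- header[2]
  if (length(lines) - 1 != n) {
    stop("word2vec file header declares ", n, " tokens but file has ",
         length(lines) - 1, call. = FALSE)
  }
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1)
  structure(list(vectors = mat, counts = NULL, dim = dim, window = NA_integer_,
                 min_count = NA_integer_, epochs = NA_integer_,
                 negative = NA_integer_, seed = NA_integer_),
            class = "embedding_model")
}
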