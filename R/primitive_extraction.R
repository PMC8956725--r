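#' Build the candidate set for primitive extraction
#'
#' Candidates for a theme's semantic primitives are the content words of the
#' field (theme) corpus: tokens that occur in the field pool, carry an
#' allowed part-of-speech tag, are not stop words, and are in the embedding
#' vocabulary (the intersection with the background corpus).
#'
#' @param field_pool The theme's [post_pool()], tokenized and POS-tagged.
#' @param model An `embedding_model` trained on the background corpus.
#' @param allowed_pos Parts of speech kept (Jieba-style tags; default nouns,
#'   verbs, adjectives).
#' @param stopwords Character vector of tokens to drop (default empty).
#' @return A `candidate_set`: sorted `tokens`, per-token field `counts`,
#'   and `source_theme` if the pool carries one.
#' @export
build_candidates <- function(field_pool, model,
                             allowed_pos = c("n", "v", "a"),
                             stopwords = character()) {
  toks <- unlist(field_pool$tokens)
  tags <- unlist(lapply(seq_len(nrow(field_pool)), function(i) {
    p <- field_pool$pos_tags[[i]]
    if (is.null(p)) rep(NA_character_, length(field_pool$tokens[[i]])) else p
  }))
  keep <- (is.na(tags) | tags %in% allowed_pos) & !(toks %in% stopwords) &
    toks %in% rownames(model$vectors)
  counts <- table(toks[keep])
  if (length(counts) == 0) {
    stop("empty candidate set: no field-corpus token survives the POS/stop-word/",
         "vocabulary filters; loosen allowed_pos or stopwords", call. = FALSE)
  }
  tokens <- sort(names(counts), method = "radix")
  theme <- unique(field_pool$theme_code)
  theme <- theme[!is.na(theme)]
  structure(list(tokens = tokens,
                 counts = stats::setNames(as.integer(counts[tokens]), tokens),
                 source_theme = if (length(theme) == 1) theme else NA_character_),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", length(x$tokens), " candidate tokens",
      if (!is.na(x$source_theme)) paste0(" (theme ", x$source_theme, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Semantic frequency of a candidate token
#'
#' The relative frequency of the token among all candidate-token occurrences
#' in the field corpus; in (0, 1].
#'
#' @param token Candidate token.
#' @param candidates A `candidate_set` from [build_candidates()].
#' @return A single number.
#' @export
semantic_frequency <- function(token, candidates) {
  count <- candidates$counts[token]
  if (is.na(count) || count == 0) {
    stop("token has zero count in the candidate set: ", token, call. = FALSE)
  }
  unname(count / sum(candidates$counts))
}

#' Semantic active index of a candidate token
#'
#' Measures how coherent a token is with the rest of the field corpus: the
#' mean cosine similarity between the token's embedding vector and the
#' vector of every *other* candidate; in [-1, 1].
#'
#' @param token Candidate token.
#' @param candidates A `candidate_set`.
#' @param model An `embedding_model` covering the candidates.
#' @return A single number.
#' @export
semantic_active_index <- function(token, candidates, model) {
  others <- setdiff(candidates$tokens, token)
  if (length(others) == 0) {
    stop("semantic_active_index needs >= 2 candidates", call. = FALSE)
  }
  v <- embedding_vector(model, token)
  sims <- vapply(others, function(o) {
    cosine_similarity(v, embedding_vector(model, o))
  }, numeric(1))
  mean(sims)
}

# Vectorized SF and SAI over the whole candidate set (same definitions as
# the per-token operations, computed in one pass).
score_candidates <- function(candidates, model) {
  sf <- candidates$counts / sum(candidates$counts)
  mat <- model$vectors[candidates$tokens, , drop = FALSE]
  norms <- sqrt(rowSums(mat^2))
  norms[norms == 0] <- 1
  unit <- mat / norms
  sims <- tcrossprod(unit)           # pairwise cosine similarities
  n <- nrow(sims)
  sai <- (rowSums(sims) - diag(sims)) / (n - 1)
  tibble::tibble(token = candidates$tokens, sf = as.numeric(sf),
                 sai = as.numeric(sai))
}

minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(1, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Extract the top-ranked semantic primitives of a field corpus
#'
#' Scores every candidate token by the combined semantic-frequency /
#' semantic-active-index (SF-SAI) criterion: SF and SAI are each min-max
#' normalized to [0, 1] over the candidate set and combined (product by
#' default). The top `k` candidates by combined score are returned; ties
#' break lexicographically. Both component scores and the combiner are
#' pluggable.
#'
#' @inheritParams build_candidates
#' @param k Number of primitives to return (capped at the candidate count;
#'   default 30).
#' @param combiner Function of two numeric vectors (normalized SF, SAI)
#'   returning the combined score; default elementwise product.
#' @return A tibble of class `primitive_table`: `token`, `sf`, `sai`
#'   (raw scores), `score` (combined, in [0, 1]), `rank`, `theme`, plus the
#'   embedding vectors in `attr(, "vectors")`.
#' @export
extract_primitives <- function(field_pool, model, k = 30,
                               combiner = `*`,
                               allowed_pos = c("n", "v", "a"),
                               stopwords = character()) {
  if (length(k) != 1 || is.na(k) || k <= 0) stop("k must be a positive integer", call. = FALSE)
  candidates <- build_candidates(field_pool, model, allowed_pos, stopwords)
  scored <- score_candidates(candidates, model)
  scored$score <- combiner(minmax(scored$sf), minmax(scored$sai))
  ord <- order(-scored$score, scored$token, method = "radix")
  scored <- scored[ord, ]
  scored$rank <- seq_len(nrow(scored))
  scored$theme <- candidates$source_theme
  out <- scored[seq_len(min(k, nrow(scored))), ]
  attr(out, "vectors") <- model$vectors[out$token, , drop = FALSE]
  class(out) <- c("primitive_table", class(out))
  out
}

#' Write a primitive table to CSV
#'
#' @param primitives A `primitive_table` from [extract_primitives()].
#' @param path Output CSV (columns token, sf, sai, score, rank, theme).
#' @export
write_primitives <- function(primitives, path) {
  readr::write_csv(tibble::as_tibble(primitives[, c("token", "sf", "sai", "score", "rank", "theme")]),
                   path, progress = FALSE)
  invisible(path)
}
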