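pos_pool <- function(tokens, tags, theme = "IF-PE") {
  pool <- post_pool(tibble::tibble(
    id = paste0("p", seq_along(tokens)), account_id = "a", follower_count = 0L,
    text = vapply(tokens, paste, character(1), collapse = " "),
    tokens = tokens, pos_tags = tags))
  pool$theme_code <- theme
  pool
}

test_that("candidate construction applies POS, stop-word and vocabulary filters", {
  m <- toy_model(rbind(noun1 = c(1, 0), noun2 = c(0, 1), verb1 = c(1, 1),
                       stopw = c(2, 0)))
  pool <- pos_pool(list(c("noun1", "verb1", "part1", "stopw"),
                        c("noun2", "oov1")),
                   list(c("n", "v", "x", "n"), c("n", "n")))
  cand <- build_candidates(pool, m, allowed_pos = c("n", "v"),
                           stopwords = "stopw")
  expect_setequal(cand$tokens, c("noun1", "noun2", "verb1"))  # no particle,
  expect_equal(cand$source_theme, "IF-PE")                    # stopword, OOV
  cand_n <- build_candidates(pool, m, allowed_pos = "n")
  expect_false("verb1" %in% cand_n$tokens)
  expect_error(build_candidates(pool, m, allowed_pos = "zz"), "loosen")
})

test_that("semantic frequency is the relative candidate-token frequency", {
  m <- toy_model(matrix(stats::rnorm(20), 10, 2,
                        dimnames = list(paste0("t", 1:10), NULL)))
  tokens <- c(rep("t1", 10), rep("t2", 45), rep("t3", 45))
  pool <- pos_pool(list(tokens), list(rep("n", length(tokens))))
  cand <- build_candidates(pool, m)
  expect_equal(semantic_frequency("t1", cand), 0.10)
  expect_equal(semantic_frequency("t2", cand), semantic_frequency("t3", cand))
  expect_error(semantic_frequency("t9", cand), "zero count")
  solo <- build_candidates(pos_pool(list(rep("t1", 3)), list(rep("n", 3))), m)
  expect_equal(semantic_frequency("t1", solo), 1)
})

test_that("semantic active index is the mean cosine to the other candidates", {
  m <- toy_model(rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1),
                       a2 = c(2, 0, 0)))
  pool <- pos_pool(list(c("a", "b", "c")), list(rep("n", 3)))
  cand <- build_candidates(pool, m)
  # three mutually orthogonal candidates: coherence 0 for each
  for (tok in c("a", "b", "c")) {
    expect_equal(semantic_active_index(tok, cand, m), 0)
  }
  # token parallel to every other candidate: coherence 1
  pool2 <- pos_pool(list(c("a", "a2")), list(rep("n", 2)))
  cand2 <- build_candidates(pool2, m)
  expect_equal(semantic_active_index("a", cand2, m), 1)
  expect_error(semantic_active_index("a", build_candidates(
    pos_pool(list("a"), list("n")), m), m), ">= 2")
})

test_that("the index matches a brute-force pairwise loop on hand-set vectors", {
  vecs <- rbind(w = c(0.3, -1.2, 0.5), x = c(1.1, 0.4, -0.2),
                y = c(-0.7, 0.9, 0.8), z = c(0.2, 0.2, 0.2))
  m <- toy_model(vecs)
  pool <- pos_pool(list(c("w", "x", "y", "z")), list(rep("n", 4)))
  cand <- build_candidates(pool, m)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (tok in rownames(vecs)) {
    manual <- mean(vapply(setdiff(rownames(vecs), tok),
                          function(o) cos(vecs[tok, ], vecs[o, ]), numeric(1)))
    expect_equal(semantic_active_index(tok, cand, m), manual, tolerance = 1e-12)
  }
})

test_that("planted core tokens dominate the extracted primitives", {
  pool <- fixture_theme_pool("IF-PE")
  m <- fixture_model()
  prims <- extract_primitives(pool, m, k = 10)
  planted <- fixture_corpus()$truth$theme_primitives[["IF-PE"]]
  expect_gte(sum(prims$token %in% planted), 9)
  expect_equal(prims$rank, 1:10)
  expect_true(all(prims$score >= 0 & prims$score <= 1))
})

test_that("extraction is deterministic and invariant to corpus duplication", {
  pool <- fixture_theme_pool("IF-PE")
  m <- fixture_model()
  a <- extract_primitives(pool, m, k = 15)
  b <- extract_primitives(pool, m, k = 15)
  expect_identical(a$token, b$token)
  doubled <- post_pool(tibble::tibble(
    id = c(pool$id, paste0(pool$id, "_dup")),
    account_id = rep(pool$account_id, 2),
    follower_count = rep(pool$follower_count, 2),
    text = rep(pool$text, 2),
    tokens = c(pool$tokens, pool$tokens),
    pos_tags = c(pool$pos_tags, pool$pos_tags)))
  doubled$theme_code <- "IF-PE"
  d <- extract_primitives(doubled, m, k = 15)
  expect_identical(a$token, d$token)
  expect_equal(a$sf, d$sf)
  expect_equal(a$sai, d$sai)
})

test_that("exactly tied candidates fall back to lexicographic order", {
  m <- toy_model(rbind(zeta = c(1, 1), alpha = c(1, 1), mid = c(1, 1)))
  pool <- pos_pool(list(c("zeta", "alpha", "mid")), list(rep("n", 3)))
  prims <- extract_primitives(pool, m, k = 3)
  expect_equal(prims$token, c("alpha", "mid", "zeta"))
})

test_that("k is validated and capped at the candidate count", {
  pool <- fixture_theme_pool("IF-PE")
  m <- fixture_model()
  expect_error(extract_primitives(pool, m, k = 0), "positive")
  all_prims <- extract_primitives(pool, m, k = 10000)
  cand <- build_candidates(pool, m)
  expect_equal(nrow(all_prims), length(cand$tokens))
})
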