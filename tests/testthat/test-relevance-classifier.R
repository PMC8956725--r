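make_feature_pool <- function(tokens) {
  post_pool(tibble::tibble(id = paste0("p", seq_along(tokens)),
                           account_id = "a", follower_count = 0L,
                           text = vapply(tokens, paste, character(1), collapse = " "),
                           tokens = tokens))
}

test_that("embedding-mean features follow mean and fallback semantics", {
  m <- toy_model(rbind(u = c(1, 0, 0), v = c(0, 1, 0), w = c(0, 0, 4)))
  pool <- make_feature_pool(list("u", c("u", "v"), c("zz", "qq"),
                                 c("v", "u"), c("u", "u", "v", "v")))
  f <- vectorize_posts(pool, m)
  expect_equal(f$vectors[1, ], c(1, 0, 0))              # single token: its vector
  expect_equal(f$vectors[2, ], c(0.5, 0.5, 0))          # mean of two
  expect_equal(f$vectors[3, ], c(0, 0, 0))              # nothing in vocabulary
  expect_equal(attr(f, "warnings"), "p3")
  expect_equal(f$vectors[2, ], f$vectors[4, ])          # order invariance
  expect_equal(f$vectors[2, ], f$vectors[5, ])          # multiset mean equal
})

test_that("bag-of-words features count tokens over a fixed vocabulary", {
  pool <- make_feature_pool(list(c("a", "b", "a"), "b"))
  f <- vectorize_posts(pool, model = c("a", "b", "c"), method = "bag_of_words")
  expect_equal(unname(f$vectors[1, ]), c(2, 1, 0))
  expect_equal(unname(f$vectors[2, ]), c(0, 1, 0))
})

test_that("untokenized posts are rejected at vectorization", {
  pool <- make_feature_pool(list("u", "v"))
  pool$tokens[[2]] <- character(0)
  expect_error(vectorize_posts(pool, toy_model(rbind(u = c(1, 0)))), "p2")
})

test_that("a separable planted problem is learned perfectly", {
  m <- toy_model(rbind(pos = c(1, 0), neg = c(-1, 0), n1 = c(0, 0.1), n2 = c(0, -0.1)))
  tokens <- c(replicate(20, c("pos", sample(c("n1", "n2"), 1)), simplify = FALSE),
              replicate(20, c("neg", sample(c("n1", "n2"), 1)), simplify = FALSE))
  pool <- make_feature_pool(tokens)
  labels <- rep(c("target", "off_target"), each = 20)
  f <- vectorize_posts(pool, m)
  clf <- train_classifier(f, labels, seed = 1L)
  rep <- evaluate_classifier(clf, f, labels)
  expect_equal(rep$accuracy, 1)
  expect_equal(sum(rep$confusion), rep$n_eval)
})

test_that("degenerate label sets are rejected", {
  m <- toy_model(rbind(u = c(1, 0), v = c(0, 1)))
  pool <- make_feature_pool(list("u", "v", "u", "v"))
  f <- vectorize_posts(pool, m)
  expect_error(train_classifier(f, rep("target", 4)), "both classes")
  expect_error(train_classifier(f, c("target", "target", "target", "off_target")),
               ">= 2 examples")
  expect_error(train_classifier(f, c("a", "b")), "length")
})

test_that("evaluation matches a brute-force prediction count", {
  gen <- fixture_corpus()
  m <- fixture_model()
  labels <- gen$truth$posts$relevance[match(gen$pool$id, gen$truth$posts$post_id)]
  f <- vectorize_posts(gen$pool, m)
  split <- train_eval_split(nrow(gen$pool), 0.8, seed = 4L)
  clf <- train_classifier(subset_features(f, split$train), labels[split$train])
  feval <- subset_features(f, split$eval)
  rep <- evaluate_classifier(clf, feval, labels[split$eval])
  pred <- predict(clf, feval)
  manual <- 0L
  for (i in seq_along(pred)) {
    if (as.character(pred[i]) == labels[split$eval][i]) manual <- manual + 1L
  }
  expect_equal(rep$accuracy, manual / length(pred))
  expect_equal(rep$n_eval, length(split$eval))
})

test_that("a hand-scored evaluation of 8 correct in 10 gives accuracy 0.8", {
  m <- toy_model(rbind(pos = c(1, 0), neg = c(-1, 0)))
  train <- make_feature_pool(c(replicate(10, "pos", simplify = FALSE),
                               replicate(10, "neg", simplify = FALSE)))
  f <- vectorize_posts(train, m)
  clf <- train_classifier(f, rep(c("target", "off_target"), each = 10))
  eval_pool <- make_feature_pool(c(replicate(5, "pos", simplify = FALSE),
                                   replicate(5, "neg", simplify = FALSE)))
  fe <- vectorize_posts(eval_pool, m)
  labels <- c(rep("target", 4), "off_target", rep("off_target", 4), "target")
  rep <- evaluate_classifier(clf, fe, labels)   # 2 labels deliberately flipped
  expect_equal(rep$accuracy, 0.8)
})

test_that("an all-target predictor on a balanced set scores one half", {
  m <- toy_model(rbind(pos = c(1, 0), far = c(5, 0), neg = c(-1, 0)))
  train <- make_feature_pool(c(replicate(5, "pos", simplify = FALSE),
                               replicate(5, "neg", simplify = FALSE)))
  clf <- train_classifier(vectorize_posts(train, m),
                          rep(c("target", "off_target"), each = 5))
  eval_pool <- make_feature_pool(replicate(10, "far", simplify = FALSE))
  labels <- rep(c("target", "off_target"), each = 5)
  rep <- evaluate_classifier(clf, vectorize_posts(eval_pool, m), labels)
  expect_equal(rep$accuracy, 0.5)
  # every prediction falls in one column of the confusion table
  expect_true(any(colSums(rep$confusion) == rep$n_eval))
})

test_that("held-out accuracy on the synthetic corpus is high", {
  gen <- fixture_corpus()
  m <- fixture_model()
  labels <- gen$truth$posts$relevance[match(gen$pool$id, gen$truth$posts$post_id)]
  f <- vectorize_posts(gen$pool, m)
  split <- train_eval_split(nrow(gen$pool), 0.8, seed = 2L)
  clf <- train_classifier(subset_features(f, split$train), labels[split$train])
  rep <- evaluate_classifier(clf, subset_features(f, split$eval), labels[split$eval])
  expect_gt(rep$accuracy, 0.9)
})

test_that("dimension mismatches are caught at prediction", {
  m <- toy_model(rbind(u = c(1, 0), v = c(0, 1)))
  pool <- make_feature_pool(list("u", "v", "u", "v"))
  clf <- train_classifier(vectorize_posts(pool, m),
                          c("target", "off_target", "target", "off_target"))
  m3 <- toy_model(rbind(u = c(1, 0, 0), v = c(0, 1, 0)))
  expect_error(predict(clf, vectorize_posts(pool, m3)), "dimensionality")
})
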