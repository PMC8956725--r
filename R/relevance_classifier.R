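#' Vectorize posts for classification
#'
#' Turns each tokenized post into one fixed-length numeric vector:
#' `"embedding_mean"` averages the in-vocabulary token vectors of the post
#' (zero vector when none are in vocabulary, collected in a `warnings`
#' attribute); `"bag_of_words"` counts tokens over a fixed vocabulary. Both
#' are invariant to token order within a post.
#'
#' @param pool A tokenized [post_pool()].
#' @param model An `embedding_model` (for `"embedding_mean"`) or a character
#'   vocabulary (for `"bag_of_words"`; defaults to the pool's vocabulary).
#' @param method `"embedding_mean"` or `"bag_of_words"`.
#' @return A `feature_matrix`: list with `post_ids`, `vectors` (one row per
#'   post), `method`; posts with no usable token are named in
#'   `attr(, "warnings")`.
#' @export
vectorize_posts <- function(pool, model = NULL,
                            method = c("embedding_mean", "bag_of_words")) {
  method <- match.arg(method)
  untok <- lengths(pool$tokens) == 0
  if (any(untok)) {
    stop("post ", pool$id[which(untok)[1]], " is untokenized", call. = FALSE)
  }
  if (method == "embedding_mean") {
    if (!inherits(model, "embedding_model")) {
      stop("embedding_mean vectorization requires an embedding_model", call. = FALSE)
    }
    vocab <- rownames(model$vectors)
    vecs <- matrix(0, nrow = nrow(pool), ncol = model$dim)
    empty <- character(0)
    for (i in seq_len(nrow(pool))) {
      toks <- pool$tokens[[i]]
      toks <- toks[toks %in% vocab]
      if (length(toks) == 0) {
        empty <- c(empty, pool$id[i])
      } else {
        vecs[i, ] <- colMeans(model$vectors[toks, , drop = FALSE])
      }
    }
  } else {
    vocab <- if (is.null(model)) sort(unique(unlist(pool$tokens)))
             else if (inherits(model, "embedding_model")) rownames(model$vectors)
             else as.character(model)
    vecs <- matrix(0L, nrow = nrow(pool), ncol = length(vocab),
                   dimnames = list(NULL, vocab))
    empty <- character(0)
    for (i in seq_len(nrow(pool))) {
      tab <- table(factor(pool$tokens[[i]], levels = vocab))
      if (sum(tab) == 0) empty <- c(empty, pool$id[i])
      vecs[i, ] <- as.integer(tab)
    }
  }
  structure(list(post_ids = pool$id, vectors = vecs, method = method),
            class = "feature_matrix", warnings = empty)
}

#' Train the target / off-target post classifier
#'
#' Fits a maximum-margin (support vector machine) binary classifier
#' distinguishing posts about the research subject from noise posts
#' (advertisements, aphorisms, running commentary). Linear kernel with cost
#' `C = 1` by default; training is deterministic given the input order and
#' seed.
#'
#' @param features A `feature_matrix` from [vectorize_posts()].
#' @param labels Character/factor vector aligned with `features$post_ids`,
#'   with two levels (canonically `"target"` / `"off_target"`).
#' @param seed Integer seed.
#' @param kernel,cost Passed to [e1071::svm()].
#' @return A `relevance_classifier` wrapping the fitted SVM.
#' @export
train_classifier <- function(features, labels, seed = 1L,
                             kernel = "linear", cost = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- factor(labels)
  if (length(labels) != length(features$post_ids)) {
    stop("labels length (", length(labels), ") does not match feature rows (",
         length(features$post_ids), ")", call. = FALSE)
  }
  if (nlevels(droplevels(labels)) < 2) {
    stop("training requires examples of both classes", call. = FALSE)
  }
  if (min(table(droplevels(labels))) < 2) {
    stop("training requires >= 2 examples per class", call. = FALSE)
  }
  fit <- withr::with_seed(seed, {
    e1071::svm(x = features$vectors, y = droplevels(labels),
               kernel = kernel, cost = cost, scale = FALSE)
  })
  structure(list(fit = fit, method = features$method,
                 dim = ncol(features$vectors), seed = as.integer(seed),
                 levels = levels(droplevels(labels))),
            class = "relevance_classifier")
}

#' @export
print.relevance_classifier <- function(x, ...) {
  cat("<relevance_classifier> SVM (", x$fit$kernel, " kernel) over ",
      x$dim, "-dim ", x$method, " features; classes: ",
      paste(x$levels, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Predict relevance labels
#'
#' @param object A `relevance_classifier`.
#' @param features A `feature_matrix` with the same dimensionality as used
#'   in training.
#' @param ... Unused.
#' @return Factor of predicted labels aligned with `features$post_ids`.
#' @export
predict.relevance_classifier <- function(object, features, ...) {
  stopifnot(inherits(features, "feature_matrix"))
  if (ncol(features$vectors) != object$dim) {
    stop("feature dimensionality (", ncol(features$vectors),
         ") does not match the classifier (", object$dim, ")", call. = FALSE)
  }
  unname(stats::predict(object$fit, features$vectors))
}

#' Evaluate a classifier
#'
#' @param classifier A `relevance_classifier`.
#' @param features Evaluation `feature_matrix`.
#' @param labels True labels aligned with `features$post_ids`.
#' @return A `classifier_report`: `accuracy`, `n_eval`, and the 2x2
#'   `confusion` table (rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(classifier, features, labels) {
  if (length(labels) != length(features$post_ids)) {
    stop("labels length does not match feature rows", call. = FALSE)
  }
  pred <- predict(classifier, features)
  truth <- factor(labels, levels = classifier$levels)
  pred <- factor(pred, levels = classifier$levels)
  confusion <- table(truth = truth, prediction = pred)
  n_eval <- length(truth)
  structure(list(accuracy = sum(diag(confusion)) / n_eval,
                 n_eval = n_eval, confusion = confusion),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.4f on %d posts\n",
              x$accuracy, x$n_eval))
  print(x$confusion)
  invisible(x)
}

#' Seeded train/evaluation split
#'
#' @param n Number of posts.
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `eval`.
#' @export
train_eval_split <- function(n, train_fraction = 0.8, seed = 1L) {
  withr::with_seed(seed, {
    train <- sort(sample.int(n, round(n * train_fraction)))
  })
  list(train = train, eval = setdiff(seq_len(n), train))
}

#' Row-subset a feature matrix
#'
#' @param features A `feature_matrix`.
#' @param idx Integer row indices.
#' @return A `feature_matrix` over the selected posts.
#' @export
subset_features <- function(features, idx) {
  structure(list(post_ids = features$post_ids[idx],
                 vectors = features$vectors[idx, , drop = FALSE],
                 method = features$method),
            class = "feature_matrix")
}
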