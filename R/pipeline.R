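#' Pipeline configuration
#'
#' One object drives the full analysis: corpus source (synthetic generator
#' or files on disk), the follower threshold, the head keyword and keyword
#' table, classifier settings, embedding hyperparameters (window 10,
#' dimension 400 by default), primitive extraction, atlas, and theme-coding
#' settings. Every random stage has an explicit seed derived from the
#' top-level `seed`.
#'
#' @param synthetic A [synthetic_config()], or `NULL` to read `corpus_path`.
#' @param corpus_path JSONL corpus to read when `synthetic` is `NULL`.
#' @param keyword_table Path to an attribute-keyword CSV, or `NULL` for the
#'   packaged table.
#' @param follower_threshold Marketing-account cutoff (default 5000).
#' @param head_keyword Head keyword; default matches the corpus language
#'   (ASCII transliteration for the synthetic default).
#' @param classifier_method Post vectorization method.
#' @param train_fraction Train share of the labelled split.
#' @param embedding_dim,embedding_window,embedding_min_count,embedding_epochs
#'   Skip-gram settings (defaults 400 / 10 / 5 / 5).
#' @param k_primitives Primitives per theme (default 30).
#' @param perplexity t-SNE perplexity (default 5).
#' @param themes Theme codes to map; default the four most frequent in the
#'   coded sample.
#' @param per_year,n_check Theme-coding sample sizes (defaults 200 / 140).
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            corpus_path = NULL,
                            keyword_table = NULL,
                            follower_threshold = 5000,
                            head_keyword = NULL,
                            classifier_method = c("embedding_mean", "bag_of_words"),
                            train_fraction = 0.8,
                            embedding_dim = 400,
                            embedding_window = 10,
                            embedding_min_count = 5,
                            embedding_epochs = 5,
                            k_primitives = 30,
                            perplexity = 5,
                            themes = NULL,
                            per_year = 200,
                            n_check = 140,
                            out_dir = NULL,
                            seed = 1L) {
  cfg <- list(synthetic = synthetic, corpus_path = corpus_path,
              keyword_table = keyword_table,
              follower_threshold = follower_threshold,
              head_keyword = head_keyword,
              classifier_method = match.arg(classifier_method),
              train_fraction = train_fraction,
              embedding_dim = as.integer(embedding_dim),
              embedding_window = as.integer(embedding_window),
              embedding_min_count = as.integer(embedding_min_count),
              embedding_epochs = as.integer(embedding_epochs),
              k_primitives = as.integer(k_primitives),
              perplexity = perplexity,
              themes = themes,
              per_year = as.integer(per_year),
              n_check = as.integer(n_check),
              out_dir = out_dir,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read and write a pipeline configuration as YAML
#'
#' The file form round-trips losslessly through [pipeline_config()].
#'
#' @param config A `pipeline_config`.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  if (!is.null(lst$synthetic)) {
    lst$synthetic <- unclass(lst$synthetic)
    lst$synthetic$theme_weights <- as.list(lst$synthetic$theme_weights)
  }
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$synthetic)) {
    syn <- lst$synthetic
    syn$theme_weights <- unlist(syn$theme_weights)
    syn$tokens_per_post <- unlist(syn$tokens_per_post)
    lst$synthetic <- do.call(synthetic_config, syn)
  }
  do.call(pipeline_config, lst)
}

stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes, in order: corpus load (or synthetic generation) -> marketing
#' filter -> union of keyword and ontology selection -> relevance
#' classification -> skip-gram embedding on the retained pool -> theme
#' coding (stratified sample, theme distribution, rater-consistency kappa)
#' -> per-theme SF-SAI primitive extraction -> semantic map with closeness
#' report. Per-stage post counts are collected in the returned report; when
#' `config$out_dir` is set the artifacts (corpus, ground truth, model,
#' primitive tables, maps, report JSON) are written there.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage counts as the run proceeds.
#' @return A `pipeline_report` list; see Details.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- list()
  t0 <- Sys.time()

  # -- corpus ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    gen <- generate_corpus(config$synthetic)
    pool <- gen$pool
    truth <- gen$truth
    ascii <- config$synthetic$ascii
  } else {
    if (is.null(config$corpus_path)) stop("no corpus: set synthetic or corpus_path", call. = FALSE)
    pool <- read_posts(config$corpus_path)
    truth <- NULL
    ascii <- TRUE
  }
  groups <- if (!is.null(config$keyword_table)) {
    read_attribute_groups(config$keyword_table)
  } else {
    read_attribute_groups(ascii = ascii)
  }
  head_kw <- config$head_keyword %||% head_keyword_token(ascii)
  counts$corpus <- nrow(pool)
  say("corpus: %d posts", counts$corpus)

  # -- marketing filter -----------------------------------------------------
  pool <- filter_marketing_accounts(pool, config$follower_threshold)
  counts$after_marketing_filter <- nrow(pool)
  say("after marketing filter: %d posts", counts$after_marketing_filter)

  # -- crawl-strategy union -------------------------------------------------
  pool <- union_select(pool, groups, head_kw)
  counts$after_union_select <- nrow(pool)
  say("after keyword/ontology union: %d posts", counts$after_union_select)

  # -- relevance classifier -------------------------------------------------
  # The classifier is trained on the labelled corpus (ground truth stands in
  # for the human-labelled sample) and is then available for cleaning
  # unlabelled data; on the synthetic corpus the union selection is already
  # noise-free, so classification is reported, not used to drop posts.
  classifier_report <- NULL
  embed_pool <- pool
  if (!is.null(truth)) {
    labelled <- restore_pool(
      gen$pool[gen$pool$id %in% truth$posts$post_id, , drop = FALSE], gen$pool)
    labels <- truth$posts$relevance[match(labelled$id, truth$posts$post_id)]
    model_bg <- train_skipgram(labelled,
                               dim = config$embedding_dim,
                               window = config$embedding_window,
                               min_count = config$embedding_min_count,
                               epochs = config$embedding_epochs,
                               seed = stage_seed(config$seed, 11L))
    feats <- vectorize_posts(labelled, model_bg, method = config$classifier_method)
    split <- train_eval_split(nrow(labelled), config$train_fraction,
                              seed = stage_seed(config$seed, 12L))
    clf <- train_classifier(subset_features(feats, split$train),
                            labels[split$train],
                            seed = stage_seed(config$seed, 13L))
    classifier_report <- evaluate_classifier(clf, subset_features(feats, split$eval),
                                             labels[split$eval])
    say("classifier held-out accuracy: %.4f on %d posts",
        classifier_report$accuracy, classifier_report$n_eval)
  } else {
    model_bg <- train_skipgram(pool,
                               dim = config$embedding_dim,
                               window = config$embedding_window,
                               min_count = config$embedding_min_count,
                               epochs = config$embedding_epochs,
                               seed = stage_seed(config$seed, 11L))
  }
  counts$embedding_vocabulary <- nrow(model_bg$vectors)
  say("embedding vocabulary: %d tokens", counts$embedding_vocabulary)

  # -- theme coding ---------------------------------------------------------
  theme_out <- NULL
  if (!is.null(truth)) {
    coded_ids <- truth$posts$post_id[!is.na(truth$posts$theme)]
    coded <- restore_pool(pool[pool$id %in% coded_ids, , drop = FALSE], pool)
    per_year <- config$per_year
    sampled <- stratified_sample(coded, per_year = per_year,
                                 seed = stage_seed(config$seed, 21L))
    sample_truth <- truth$posts$theme[match(sampled$id, truth$posts$post_id)]
    raters <- simulate_raters(
      stats::setNames(sample_truth, sampled$id),
      error_rate = config$synthetic$rater_error_rate,
      seed = stage_seed(config$seed, 22L),
      codes = names(config$synthetic$theme_weights))
    distribution <- theme_distribution(sample_truth)
    consistency <- verify_codebook(raters$rater1, raters$rater2,
                                   n_check = config$n_check,
                                   seed = stage_seed(config$seed, 23L))
    counts$coded_sample <- nrow(sampled)
    theme_out <- list(distribution = distribution, consistency = consistency,
                      sampled_ids = sampled$id, sample_truth = sample_truth)
    say("coded sample: %d posts; overall kappa %.4f",
        nrow(sampled), consistency$overall$kappa)
  }

  # -- primitives and semantic maps ----------------------------------------
  maps <- list()
  if (!is.null(truth)) {
    themes <- config$themes
    if (is.null(themes)) {
      tab <- sort(table(truth$posts$theme), decreasing = TRUE)
      themes <- names(tab)[seq_len(min(4, length(tab)))]
    }
    for (th in themes) {
      ids <- truth$posts$post_id[!is.na(truth$posts$theme) & truth$posts$theme == th]
      field <- restore_pool(pool[pool$id %in% ids, , drop = FALSE], pool)
      field$theme_code <- th
      prims <- extract_primitives(field, model_bg, k = config$k_primitives)
      map <- build_semantic_map(prims, perplexity = config$perplexity,
                                seed = stage_seed(config$seed, 31L))
      maps[[th]] <- list(primitives = prims, map = map,
                         closeness = map_closeness(map))
      say("theme %s: %d primitives, mean distance %.4f", th, nrow(prims),
          map$stats$mean)
    }
  }

  report <- structure(list(counts = counts,
                           classifier = classifier_report,
                           themes = theme_out,
                           maps = maps,
                           model = model_bg,
                           pool = pool,
                           truth = truth,
                           config = config,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-25s %d\n", nm, x$counts[[nm]]))
  if (!is.null(x$classifier)) {
    cat(sprintf("  classifier accuracy: %.4f (n = %d)\n",
                x$classifier$accuracy, x$classifier$n_eval))
  }
  if (!is.null(x$themes)) {
    cat(sprintf("  overall coding kappa: %.4f\n", x$themes$consistency$overall$kappa))
  }
  if (length(x$maps) > 0) {
    cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

write_pipeline_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_posts(report$pool, file.path(out_dir, "post_pool.jsonl"))
  if (!is.null(report$truth)) {
    readr::write_csv(report$truth$posts, file.path(out_dir, "ground_truth.csv"),
                     progress = FALSE)
  }
  write_word2vec(report$model, file.path(out_dir, "embedding.w2v"))
  for (th in names(report$maps)) {
    m <- report$maps[[th]]
    write_primitives(m$primitives, file.path(out_dir, sprintf("primitives_%s.csv", th)))
    write_map(m$map, dist_path = file.path(out_dir, sprintf("distances_%s.tsv", th)),
              stats_path = file.path(out_dir, sprintf("distance_stats_%s.json", th)))
  }
  summary <- list(counts = report$counts,
                  classifier_accuracy = report$classifier$accuracy %||% NA,
                  overall_kappa = if (!is.null(report$themes))
                    report$themes$consistency$overall$kappa else NA,
                  elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
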