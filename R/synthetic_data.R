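#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure of an inferiority-feelings microblog
#' corpus: two kinds of relevant posts (those naming the head keyword
#' directly and those matching the six-attribute conjunctive filter), plus
#' off-target noise posts (advertisement-like and aphorism-like), authored
#' by a mix of ordinary and high-follower marketing accounts over the years
#' 2011-2017, with eight planted theme clusters whose vocabularies drive a
#' predictable embedding geometry.
#'
#' Defaults: the keyword/attribute/off-target mix is 0.5/0.3/0.2 (an
#' off-target rate near the 20% observed when labelling real posts of this
#' kind), theme weights follow the observed cause distribution of the eight
#' themes, and each theme plants 10 core tokens against 90 shared filler
#' tokens.
#'
#' @param n_posts Number of posts to generate.
#' @param n_accounts Number of distinct author accounts.
#' @param marketing_fraction Fraction of accounts given > 5000 followers.
#' @param p_keyword_post,p_attribute_post,p_offtarget Post-type mix; must
#'   sum to 1.
#' @param theme_weights Named numeric vector over the 8 theme codes; must
#'   sum to 1.
#' @param n_core_tokens Planted core (primitive) tokens per theme.
#' @param n_filler_tokens Size of the shared filler vocabulary.
#' @param filler_rate Probability that a content token of a relevant post is
#'   drawn from the shared filler vocabulary rather than the theme cores.
#' @param tokens_per_post Integer range `c(min, max)` of post lengths.
#' @param rater_error_rate Per-rater mislabel probability for
#'   [simulate_raters()].
#' @param ascii Use transliterated ASCII attribute tokens (default) or the
#'   original Chinese forms.
#' @param seed Integer seed; the single source of all randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_posts = 4000,
                             n_accounts = 300,
                             marketing_fraction = 0.2,
                             p_keyword_post = 0.5,
                             p_attribute_post = 0.3,
                             p_offtarget = 0.2,
                             theme_weights = default_theme_weights(),
                             n_core_tokens = 10,
                             n_filler_tokens = 90,
                             filler_rate = 0.4,
                             tokens_per_post = c(8, 16),
                             rater_error_rate = 0.1,
                             ascii = TRUE,
                             seed = 1L) {
  cfg <- list(n_posts = as.integer(n_posts), n_accounts = as.integer(n_accounts),
              marketing_fraction = marketing_fraction,
              p_keyword_post = p_keyword_post, p_attribute_post = p_attribute_post,
              p_offtarget = p_offtarget, theme_weights = theme_weights,
              n_core_tokens = as.integer(n_core_tokens),
              n_filler_tokens = as.integer(n_filler_tokens),
              filler_rate = filler_rate,
              tokens_per_post = as.integer(tokens_per_post),
              rater_error_rate = rater_error_rate, ascii = isTRUE(ascii),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @export
default_theme_weights <- function() {
  counts <- c("IF-L" = 40, "IF-SI" = 110, "IF-LA" = 247, "IF-FB" = 25,
              "IF-PD" = 261, "IF-A" = 238, "IF-P" = 209, "IF-PE" = 270)
  counts / sum(counts)
}

validate_synthetic_config <- function(cfg) {
  p_sum <- cfg$p_keyword_post + cfg$p_attribute_post + cfg$p_offtarget
  if (abs(p_sum - 1) > 1e-9) {
    stop("post-type proportions must sum to 1 (got ", p_sum, ")", call. = FALSE)
  }
  if (abs(sum(cfg$theme_weights) - 1) > 1e-9) {
    stop("theme weights must sum to 1", call. = FALSE)
  }
  if (is.null(names(cfg$theme_weights)) || any(!nzchar(names(cfg$theme_weights)))) {
    stop("theme weights must be named by theme code", call. = FALSE)
  }
  if (cfg$marketing_fraction < 0 || cfg$marketing_fraction > 1) {
    stop("marketing_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(cfg$tokens_per_post) != 2 || any(cfg$tokens_per_post < 1) ||
      cfg$tokens_per_post[1] > cfg$tokens_per_post[2]) {
    stop("tokens_per_post must be an increasing positive range c(min, max)", call. = FALSE)
  }
  if (cfg$p_attribute_post > 0 && cfg$tokens_per_post[1] < 5) {
    stop("infeasible config: attribute posts need >= 5 tokens per post ",
         "(one hit for each of A1-A4 plus one of A5/A6)", call. = FALSE)
  }
  if (cfg$rater_error_rate < 0 || cfg$rater_error_rate > 1) {
    stop("rater_error_rate must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' The packaged attribute keyword groups
#'
#' Convenience wrapper over [read_attribute_groups()] returning the six
#' shipped groups, optionally transliterated to ASCII.
#'
#' @param ascii Emit ASCII transliterations.
#' @param seed Ignored; accepted so generator call sites can pass one seed
#'   everywhere.
#' @return Named list of six [attribute_group()]s.
#' @export
generate_keyword_tables <- function(seed = NULL, ascii = FALSE) {
  read_attribute_groups(ascii = ascii)
}

head_keyword_token <- function(ascii) if (ascii) "zibei" else "\u81ea\u5351"

# Fixed synthetic vocabulary: every token gets one part-of-speech tag
# (Jieba-style: n noun, v verb, a adjective, r pronoun).
synthetic_vocabulary <- function(cfg) {
  groups <- generate_keyword_tables(ascii = cfg$ascii)
  codes <- names(cfg$theme_weights)
  core <- lapply(codes, function(code) {
    sprintf("%s_core%02d", tolower(gsub("-", "", code)), seq_len(cfg$n_core_tokens))
  })
  names(core) <- codes
  filler <- sprintf("filler%03d", seq_len(cfg$n_filler_tokens))
  ad <- sprintf("advert%02d", 1:30)
  apho <- sprintf("aphorism%02d", 1:30)
  pos <- c(
    stats::setNames(rep("n", length(unlist(core))), unlist(core)),
    stats::setNames(rep(c("n", "v"), length.out = length(filler)), filler),
    stats::setNames(rep("n", length(ad)), ad),
    stats::setNames(rep("n", length(apho)), apho),
    stats::setNames("a", head_keyword_token(cfg$ascii)),
    stats::setNames(rep("v", length(groups$A1$members)), groups$A1$members),
    stats::setNames(rep("r", length(groups$A2$members)), groups$A2$members),
    stats::setNames(rep("v", length(groups$A3$members)), groups$A3$members),
    stats::setNames(rep("r", length(groups$A4$members)), groups$A4$members),
    stats::setNames(rep("a", length(groups$A5$members)), groups$A5$members),
    stats::setNames(rep("a", length(groups$A6$members)), groups$A6$members)
  )
  list(groups = groups, core = core, filler = filler, ad = ad, apho = apho,
       head_keyword = head_keyword_token(cfg$ascii), pos = pos)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Post types are assigned in exact proportions (largest-remainder rounding)
#' so that, e.g., `n_posts = 1000, p_attribute_post = 0.3` plants exactly
#' 300 attribute posts. Keyword posts contain the head keyword; attribute
#' posts contain one member of each of A1-A4 plus one member of A5 or A6
#' and never the head keyword; off-target posts draw from two disjoint
#' noise vocabularies (advertisement-like and aphorism-like) plus shared
#' filler, and by construction never satisfy the attribute conjunction.
#' Relevant posts draw their content tokens from their theme's core
#' vocabulary and the shared filler, so within-theme tokens co-occur.
#'
#' @param config A [synthetic_config()].
#' @return `list(pool, truth)`: a [post_pool()] and a ground-truth object
#'   with per-post labels (`post_type`, `relevance`, `eq1_match`, `theme`,
#'   `is_marketing`) and the planted per-theme core-token sets.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  vocab <- synthetic_vocabulary(config)
  withr::with_seed(config$seed, {
    n <- config$n_posts
    # exact type counts, largest remainder
    p <- c(keyword = config$p_keyword_post, attribute = config$p_attribute_post,
           offtarget = config$p_offtarget)
    counts <- floor(p * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(p * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    post_type <- sample(rep(names(counts), counts))

    # accounts: first block are marketing accounts (> 5000 followers)
    n_marketing <- round(config$n_accounts * config$marketing_fraction)
    followers <- integer(config$n_accounts)
    if (n_marketing > 0) followers[seq_len(n_marketing)] <- sample(5001:50000, n_marketing, replace = TRUE)
    if (n_marketing < config$n_accounts) {
      followers[(n_marketing + 1):config$n_accounts] <- sample(0:5000, config$n_accounts - n_marketing, replace = TRUE)
    }
    account_idx <- sample.int(config$n_accounts, n, replace = TRUE)

    # balanced years 2011-2017, uniform day within year
    years <- rep(2011:2017, length.out = n)[sample.int(n)]
    dates <- vapply(years, function(y) {
      d0 <- as.Date(sprintf("%d-01-01", y))
      d1 <- as.Date(sprintf("%d-12-31", y))
      as.character(d0 + sample.int(as.integer(d1 - d0) + 1, 1) - 1)
    }, character(1))

    codes <- names(config$theme_weights)
    relevant <- post_type != "offtarget"
    theme <- rep(NA_character_, n)
    theme[relevant] <- sample(codes, sum(relevant), replace = TRUE,
                              prob = config$theme_weights)
    offtarget_class <- rep(NA_character_, n)
    offtarget_class[!relevant] <- sample(c("advertisement", "aphorism"),
                                         sum(!relevant), replace = TRUE)

    lengths_per_post <- sample(config$tokens_per_post[1]:config$tokens_per_post[2],
                               n, replace = TRUE)
    tokens <- vector("list", n)
    for (i in seq_len(n)) {
      L <- lengths_per_post[i]
      if (relevant[i]) {
        structural <- if (post_type[i] == "keyword") {
          vocab$head_keyword
        } else {
          affect <- sample(c(vocab$groups$A5$members, vocab$groups$A6$members), 1)
          c(vapply(c("A1", "A2", "A3", "A4"),
                   function(g) sample(vocab$groups[[g]]$members, 1), character(1)),
            affect)
        }
        n_content <- max(L - length(structural), 1)
        from_filler <- stats::runif(n_content) < config$filler_rate
        content <- character(n_content)
        content[from_filler] <- sample(vocab$filler, sum(from_filler), replace = TRUE)
        content[!from_filler] <- sample(vocab$core[[theme[i]]], sum(!from_filler), replace = TRUE)
        toks <- sample(c(structural, content))
      } else {
        noise_vocab <- if (offtarget_class[i] == "advertisement") vocab$ad else vocab$apho
        from_filler <- stats::runif(L) < 0.3
        toks <- character(L)
        toks[from_filler] <- sample(vocab$filler, sum(from_filler), replace = TRUE)
        toks[!from_filler] <- sample(noise_vocab, sum(!from_filler), replace = TRUE)
      }
      tokens[[i]] <- toks
    }
    pos_tags <- lapply(tokens, function(t) unname(vocab$pos[t]))

    ids <- sprintf("post%05d", seq_len(n))
    pool <- post_pool(tibble::tibble(
      id = ids,
      account_id = sprintf("acct%04d", account_idx),
      follower_count = followers[account_idx],
      date = dates,
      text = vapply(tokens, paste, character(1), collapse = " "),
      tokens = tokens,
      pos_tags = pos_tags
    ), provenance = sprintf("synthetic corpus: %d posts, seed %d", n, config$seed))

    truth <- structure(list(
      posts = tibble::tibble(
        post_id = ids,
        post_type = post_type,
        relevance = ifelse(relevant, "target", "off_target"),
        eq1_match = post_type == "attribute",
        theme = theme,
        offtarget_class = offtarget_class,
        is_marketing = account_idx <= n_marketing
      ),
      theme_primitives = vocab$core,
      head_keyword = vocab$head_keyword,
      groups = vocab$groups,
      config = config
    ), class = "ground_truth")
    list(pool = pool, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$posts), " posts; ",
      sum(x$posts$relevance == "target"), " target, ",
      sum(x$posts$eq1_match), " attribute-filter matches\n", sep = "")
  invisible(x)
}

#' Simulate two independent theme raters
#'
#' Stands in for the two human coders: each rater reports the true theme
#' code with probability `1 - error_rate` and otherwise a uniformly random
#' *other* code. Raters err independently.
#'
#' @param truth A ground-truth object from [generate_corpus()], or a
#'   character vector of true theme codes.
#' @param error_rate Per-rater mislabel probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param codes Codebook codes to draw errors from; defaults to the codes
#'   present in the truth.
#' @return A tibble with `post_id` (if available), `truth`, `rater1`,
#'   `rater2`.
#' @export
simulate_raters <- function(truth, error_rate, seed, codes = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]", call. = FALSE)
  if (inherits(truth, "ground_truth")) {
    keep <- !is.na(truth$posts$theme)
    ids <- truth$posts$post_id[keep]
    true_codes <- truth$posts$theme[keep]
    if (is.null(codes)) codes <- names(truth$config$theme_weights)
  } else {
    ids <- NULL
    true_codes <- as.character(truth)
    if (is.null(codes)) codes <- sort(unique(true_codes))
  }
  if (length(codes) < 2 && error_rate > 0) {
    stop("need at least 2 codes to simulate rater errors", call. = FALSE)
  }
  corrupt <- function(x) {
    err <- stats::runif(length(x)) < error_rate
    x[err] <- vapply(x[err], function(code) sample(setdiff(codes, code), 1), character(1))
    x
  }
  withr::with_seed(seed, {
    r1 <- corrupt(true_codes)
    r2 <- corrupt(true_codes)
  })
  out <- tibble::tibble(truth = true_codes, rater1 = r1, rater2 = r2)
  if (!is.null(ids)) out <- tibble::tibble(post_id = ids, out)
  out
}
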