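#' Construct a post pool
#'
#' A post pool is the package's core container: one row per microblog post,
#' with author metadata, raw text, a tokenized form, and optional labels.
#' It is a tibble of class `"post_pool"` carrying a `provenance` attribute
#' that records, in order, every filter applied to it.
#'
#' @param posts A data frame with at least the columns `id`, `account_id`,
#'   `follower_count` and `text`. Optional columns: `date` (ISO-8601 string),
#'   `tokens` (list of character vectors), `pos_tags` (list of character
#'   vectors aligned with `tokens`), `relevance_label` (`"target"` or
#'   `"off_target"`), `theme_code`.
#' @param provenance Character vector describing how the pool was built.
#'
#' @return A `post_pool` tibble.
#' @export
post_pool <- function(posts, provenance = character()) {
  posts <- tibble::as_tibble(posts)
  required <- c("id", "account_id", "follower_count", "text")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0) {
    stop("post pool is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"date" %in% names(posts)) posts$date <- NA_character_
  if (!"tokens" %in% names(posts)) posts$tokens <- replicate(nrow(posts), character(0), simplify = FALSE)
  if (!"pos_tags" %in% names(posts)) posts$pos_tags <- replicate(nrow(posts), NULL, simplify = FALSE)
  if (!"relevance_label" %in% names(posts)) posts$relevance_label <- NA_character_
  if (!"theme_code" %in% names(posts)) posts$theme_code <- NA_character_
  posts$id <- as.character(posts$id)
  posts$account_id <- as.character(posts$account_id)
  posts$follower_count <- as.integer(posts$follower_count)
  posts$date <- as.character(posts$date)
  posts$text <- as.character(posts$text)
  if (!is.list(posts$tokens)) posts$tokens <- strsplit(as.character(posts$tokens), "\\s+")
  out <- structure(posts, class = c("post_pool", class(tibble::tibble())),
                   provenance = as.character(provenance))
  validate_post_pool(out)
  out
}

validate_post_pool <- function(pool) {
  if (anyDuplicated(pool$id)) {
    dup <- pool$id[duplicated(pool$id)][1]
    stop("duplicate post id in pool: ", dup, call. = FALSE)
  }
  if (any(!is.na(pool$follower_count) & pool$follower_count < 0)) {
    stop("follower_count must be non-negative", call. = FALSE)
  }
  has_pos <- !vapply(pool$pos_tags, is.null, logical(1))
  bad <- which(has_pos &
    lengths(pool$pos_tags) != lengths(pool$tokens))
  if (length(bad) > 0) {
    stop("pos_tags length differs from tokens length for post id ",
         pool$id[bad[1]], call. = FALSE)
  }
  invisible(pool)
}

#' @export
print.post_pool <- function(x, ...) {
  cat("<post_pool> ", nrow(x), " posts\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat("provenance:\n", paste0("  - ", prov, "\n"), sep = "")
  NextMethod()
}

#' Provenance of a post pool
#'
#' @param pool A `post_pool`.
#' @return Character vector of filter descriptions, oldest first.
#' @export
pool_provenance <- function(pool) {
  attr(pool, "provenance") %||% character()
}

add_provenance <- function(pool, note) {
  attr(pool, "provenance") <- c(pool_provenance(pool), note)
  pool
}

# Subsetting a post_pool with dplyr drops attributes; re-attach them.
restore_pool <- function(new, old, note = NULL) {
  out <- structure(tibble::as_tibble(new),
                   class = c("post_pool", class(tibble::tibble())),
                   provenance = pool_provenance(old))
  if (!is.null(note)) out <- add_provenance(out, note)
  out
}

#' Read posts from JSONL or CSV
#'
#' JSONL carries one JSON object per line with `tokens`/`pos_tags` as arrays;
#' CSV carries them whitespace-joined (CSV has no native list type). Both are
#' read as UTF-8. Unknown fields are ignored.
#'
#' @param path File to read.
#' @param format `"jsonl"` or `"csv"`. Defaults from the file extension.
#' @return A [post_pool()].
#' @export
read_posts <- function(path, format = c("jsonl", "csv")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(post_pool(tibble::tibble(id = character(), account_id = character(),
                                      follower_count = integer(), text = character()),
                       provenance = paste0("read 0 posts from ", basename(path))))
    }
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec)) stop("malformed JSON on line ", i, " of ", path, call. = FALSE)
      for (f in c("id", "account_id", "follower_count", "text")) {
        if (is.null(rec[[f]])) {
          stop("record on line ", i, " lacks required field '", f, "'", call. = FALSE)
        }
      }
      recs[[i]] <- rec
    }
    grab <- function(f, default) {
      vapply(recs, function(r) {
        v <- r[[f]]
        if (is.null(v) || length(v) == 0) default else as.character(v)[1]
      }, character(1))
    }
    grab_list <- function(f) {
      lapply(recs, function(r) {
        v <- r[[f]]
        if (is.null(v)) NULL else as.character(v)
      })
    }
    tokens <- grab_list("tokens")
    tokens <- lapply(tokens, function(t) if (is.null(t)) character(0) else t)
    df <- tibble::tibble(
      id = grab("id", NA_character_),
      account_id = grab("account_id", NA_character_),
      follower_count = as.integer(vapply(recs, function(r) as.numeric(r$follower_count), numeric(1))),
      date = grab("date", NA_character_),
      text = grab("text", NA_character_),
      tokens = tokens,
      pos_tags = grab_list("pos_tags"),
      relevance_label = grab("relevance_label", NA_character_),
      theme_code = grab("theme_code", NA_character_)
    )
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    for (f in c("id", "account_id", "follower_count", "text")) {
      if (!f %in% names(df)) stop("CSV lacks required column '", f, "'", call. = FALSE)
      bad <- which(is.na(df[[f]]) & f != "text")
      if (length(bad) > 0) stop("record ", bad[1], " lacks required field '", f, "'", call. = FALSE)
    }
    df$follower_count <- as.integer(df$follower_count)
    split_ws <- function(x) {
      lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, " ", fixed = TRUE)[[1]]
      })
    }
    df$tokens <- if ("tokens" %in% names(df)) split_ws(df$tokens) else
      replicate(nrow(df), character(0), simplify = FALSE)
    df$pos_tags <- if ("pos_tags" %in% names(df)) {
      lapply(df$pos_tags, function(s) {
        if (is.na(s) || !nzchar(s)) NULL else strsplit(s, " ", fixed = TRUE)[[1]]
      })
    } else replicate(nrow(df), NULL, simplify = FALSE)
    if (is.null(df$date)) df$date <- NA_character_
  }
  post_pool(df, provenance = paste0("read ", nrow(df), " posts from ", basename(path)))
}

#' Write posts to JSONL or CSV
#'
#' Inverse of [read_posts()]: `read_posts(write_posts(pool, path))` reproduces
#' every field, byte-exact for UTF-8 token strings.
#'
#' @param pool A [post_pool()].
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_posts <- function(pool, path, format = c("jsonl", "csv")) {
  validate_post_pool(pool)
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(pool)), function(i) {
      rec <- list(id = pool$id[i], account_id = pool$account_id[i],
                  follower_count = pool$follower_count[i])
      if (!is.na(pool$date[i])) rec$date <- pool$date[i]
      rec$text <- pool$text[i]
      rec$tokens <- I(pool$tokens[[i]])
      if (!is.null(pool$pos_tags[[i]])) rec$pos_tags <- I(pool$pos_tags[[i]])
      if (!is.na(pool$relevance_label[i])) rec$relevance_label <- pool$relevance_label[i]
      if (!is.na(pool$theme_code[i])) rec$theme_code <- pool$theme_code[i]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con, useBytes = FALSE)
  } else {
    df <- tibble::tibble(
      id = pool$id, account_id = pool$account_id,
      follower_count = pool$follower_count, date = pool$date, text = pool$text,
      tokens = vapply(pool$tokens, paste, character(1), collapse = " "),
      pos_tags = vapply(pool$pos_tags, function(p) {
        if (is.null(p)) NA_character_ else paste(p, collapse = " ")
      }, character(1)),
      relevance_label = pool$relevance_label,
      theme_code = pool$theme_code
    )
    readr::write_csv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Drop posts from marketing accounts
#'
#' Accounts with more than `threshold` followers are treated as marketing
#' accounts whose posts are mostly advertisements; their posts are removed.
#' "More than" is strict: a post whose author has exactly `threshold`
#' followers is kept.
#'
#' @param pool A [post_pool()].
#' @param threshold Follower-count cutoff (default 5000).
#' @return The filtered pool, with provenance annotated.
#' @export
filter_marketing_accounts <- function(pool, threshold = 5000) {
  validate_post_pool(pool)
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  keep <- pool$follower_count <= threshold
  n_rm <- sum(!keep)
  pct <- if (nrow(pool) > 0) round(100 * n_rm / nrow(pool), 1) else 0
  restore_pool(pool[keep, , drop = FALSE], pool,
               note = sprintf("marketing filter (> %d followers): removed %d of %d posts (%s%%)",
                              as.integer(threshold), n_rm, nrow(pool), pct))
}

#' Restrict a pool to a date window
#'
#' @param pool A [post_pool()].
#' @param from,to Inclusive ISO-8601 date bounds.
#' @return The filtered pool.
#' @export
filter_date_window <- function(pool, from = "2011-01-01", to = "2018-01-01") {
  d <- as.Date(pool$date)
  keep <- !is.na(d) & d >= as.Date(from) & d <= as.Date(to)
  restore_pool(pool[keep, , drop = FALSE], pool,
               note = sprintf("date window %s..%s: kept %d of %d posts",
                              from, to, sum(keep), nrow(pool)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
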