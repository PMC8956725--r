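#' Attribute keyword groups
#'
#' The ontological attributes of inferiority feelings are operationalised as
#' six keyword groups A1..A6, each a head word plus its synonyms: A1
#' think/feel, A2 oneself/myself/I, A3 inferior-to/not-equal-to, A4 other
#' people/he/she/them, A5 feeling low and its synonyms, A6 sadness and its
#' synonyms. A post reveals inferiority without naming it when it hits all
#' of A1-A4 and at least one of the affect groups A5/A6 (the conjunctive
#' filter implemented by [eq1_filter()]).
#'
#' @param path CSV with columns `group`, `token`, `token_ascii`, `gloss`,
#'   `role`; defaults to the packaged table.
#' @param ascii If `TRUE`, use transliterated ASCII tokens (handy for
#'   readable tests); the group structure is identical.
#' @return A named list of `attribute_group` objects (`name`, `members`,
#'   `glosses`).
#' @export
read_attribute_groups <- function(path = NULL, ascii = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "attribute_keywords.csv", package = "inferatlas")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("group", "token")) {
    if (!col %in% names(tab)) stop("keyword table lacks column '", col, "'", call. = FALSE)
  }
  token_col <- if (ascii && "token_ascii" %in% names(tab)) "token_ascii" else "token"
  groups <- split(tab, tab$group)
  out <- lapply(groups, function(g) {
    attribute_group(g$group[1], g[[token_col]], glosses = g$gloss)
  })
  out[order(names(out))]
}

#' @rdname read_attribute_groups
#' @param name Group name (one of `"A1"`..`"A6"` for the shipped table).
#' @param members Non-empty character vector of member tokens.
#' @param glosses Optional English glosses aligned with `members`.
#' @export
attribute_group <- function(name, members, glosses = NULL) {
  members <- as.character(members)
  if (length(members) == 0) stop("attribute group '", name, "' has no members", call. = FALSE)
  structure(list(name = name, members = unique(members), glosses = glosses),
            class = "attribute_group")
}

#' @export
print.attribute_group <- function(x, ...) {
  cat("<attribute_group> ", x$name, ": ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Does a token sequence hit an attribute group?
#'
#' Exact string match of any token against any group member; no substring or
#' morphological matching ("低落感" does not hit the member
#' "低落").
#'
#' @param tokens Character vector of tokens.
#' @param group An [attribute_group()].
#' @return `TRUE` iff any token is a member of the group.
#' @export
matches_group <- function(tokens, group) {
  stopifnot(inherits(group, "attribute_group"))
  any(tokens %in% group$members)
}

#' Conjunctive ontology filter for one post
#'
#' A post is selected when it hits every core group A1-A4 and at least one
#' of the affect groups A5/A6: A1 & A2 & A3 & A4 & (A5 | A6). Matching is on
#' the segmented token list by default; set `use_text = TRUE` to match
#' members as substrings of the raw text instead (the mode a crawler over
#' unsegmented text would use).
#'
#' @param post One-row slice of a [post_pool()], or a list with `id`,
#'   `tokens`, and `text`.
#' @param groups Named list of the six [attribute_group()]s.
#' @param use_text Match on raw text substrings instead of tokens.
#' @return A `filter_verdict` list: `post_id`, `selected`, `matched_groups`,
#'   `strategy = "ontology"`.
#' @export
eq1_filter <- function(post, groups, use_text = FALSE) {
  needed <- c("A1", "A2", "A3", "A4", "A5", "A6")
  missing_g <- setdiff(needed, names(groups))
  if (length(missing_g) > 0) {
    stop("missing attribute group(s): ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(post)) {
    post <- list(id = post$id[1], tokens = post$tokens[[1]], text = post$text[1])
  }
  hit <- vapply(needed, function(nm) {
    g <- groups[[nm]]
    if (use_text) {
      any(vapply(g$members, function(m) grepl(m, post$text, fixed = TRUE), logical(1)))
    } else {
      matches_group(post$tokens, g)
    }
  }, logical(1))
  selected <- all(hit[c("A1", "A2", "A3", "A4")]) && (hit["A5"] || hit["A6"])
  structure(list(post_id = post$id, selected = unname(selected),
                 matched_groups = needed[hit], strategy = "ontology"),
            class = "filter_verdict")
}

#' Select posts containing the head keyword
#'
#' Emulates the direct keyword search: a post is selected when the head
#' keyword appears in its token list (exact token) or, for untokenized
#' posts, as a substring of the raw text.
#'
#' @param pool A [post_pool()].
#' @param head_keyword Non-empty keyword string (the shipped corpus uses
#'   `"zibei"` in ASCII mode).
#' @return The selected sub-pool.
#' @export
keyword_select <- function(pool, head_keyword) {
  if (!nzchar(head_keyword)) stop("head_keyword must be non-empty", call. = FALSE)
  keep <- vapply(seq_len(nrow(pool)), function(i) {
    toks <- pool$tokens[[i]]
    if (length(toks) > 0) head_keyword %in% toks
    else grepl(head_keyword, pool$text[i], fixed = TRUE)
  }, logical(1))
  restore_pool(pool[keep, , drop = FALSE], pool,
               note = sprintf("keyword search '%s': selected %d of %d posts",
                              head_keyword, sum(keep), nrow(pool)))
}

#' Apply the ontology filter to a whole pool
#'
#' @param pool A [post_pool()].
#' @param groups Named list of six [attribute_group()]s.
#' @param use_text See [eq1_filter()].
#' @return The selected sub-pool.
#' @export
ontology_select <- function(pool, groups, use_text = FALSE) {
  keep <- vapply(seq_len(nrow(pool)), function(i) {
    eq1_filter(list(id = pool$id[i], tokens = pool$tokens[[i]], text = pool$text[i]),
               groups, use_text = use_text)$selected
  }, logical(1))
  restore_pool(pool[keep, , drop = FALSE], pool,
               note = sprintf("ontology filter A1&A2&A3&A4&(A5|A6): selected %d of %d posts",
                              sum(keep), nrow(pool)))
}

#' Union of the two crawl strategies
#'
#' The corpus combines posts found by direct head-keyword search with posts
#' passing the conjunctive attribute filter; a post matching both is counted
#' once (set semantics by post id).
#'
#' @inheritParams ontology_select
#' @param head_keyword Head keyword for [keyword_select()].
#' @return The deduplicated union sub-pool, in original pool order.
#' @export
union_select <- function(pool, groups, head_keyword, use_text = FALSE) {
  kw <- keyword_select(pool, head_keyword)
  ont <- ontology_select(pool, groups, use_text = use_text)
  ids <- union(kw$id, ont$id)
  keep <- pool$id %in% ids
  restore_pool(pool[keep, , drop = FALSE], pool,
               note = sprintf("union of keyword (%d) and ontology (%d) selections: %d unique posts",
                              nrow(kw), nrow(ont), sum(keep)))
}
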