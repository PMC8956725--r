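#' The theme codebook
#'
#' Eight codes for the causes of inferiority feelings: physical defects
#' (IF-PD), love and affection (IF-LA), family background (IF-FB),
#' personality (IF-P), personal experiences (IF-PE), social interaction
#' (IF-SI), learning (IF-L), abilities (IF-A).
#'
#' @param path Optional CSV (columns `code`, `description`,
#'   `example_gloss`); defaults to the packaged codebook.
#' @return Tibble with one row per code.
#' @export
theme_codebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "theme_codebook.csv", package = "inferatlas")
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Yearly stratified sample of posts
#'
#' Draws `per_year` posts uniformly without replacement from each year's
#' block of the pool (e.g. 200 posts from each of 2011-2017 for a 1400-post
#' coding sample).
#'
#' @param pool A [post_pool()] with parseable dates.
#' @param per_year Posts to draw per year (default 200).
#' @param years Years to sample; default all years present in the pool.
#' @param seed Integer seed.
#' @return The sampled [post_pool()].
#' @export
stratified_sample <- function(pool, per_year = 200, years = NULL, seed = 1L) {
  if (per_year < 0) stop("per_year must be non-negative", call. = FALSE)
  yr <- as.integer(format(as.Date(pool$date), "%Y"))
  if (is.null(years)) years <- sort(unique(yr[!is.na(yr)]))
  idx <- integer(0)
  withr::with_seed(seed, {
    for (y in years) {
      block <- which(!is.na(yr) & yr == y)
      if (length(block) < per_year) {
        stop("year ", y, " has only ", length(block), " posts; ", per_year,
             " requested", call. = FALSE)
      }
      idx <- c(idx, sort(sample(block, per_year)))
    }
  })
  restore_pool(pool[idx, , drop = FALSE], pool,
               note = sprintf("stratified sample: %d posts per year x %d years (seed %d)",
                              per_year, length(years), seed))
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Theme distribution of coded posts
#'
#' Counts and percentages per theme code. Percentages are
#' `count / total * 100`, rounded half-up to 2 decimals (so 270 of 1400 is
#' 19.29); rounded percentages sum to 100 within 0.05 per-code rounding
#' slack.
#'
#' @param assignments Character/factor vector of theme codes (one per
#'   post), or a data frame with a `theme_code`/`theme`/`code` column.
#' @param codes Codebook codes; defaults to the shipped codebook. Unknown
#'   assigned codes are an error.
#' @return A tibble of class `theme_distribution`: `code`, `count`,
#'   `percentage`, with the sample size in `attr(, "total")`.
#' @export
theme_distribution <- function(assignments, codes = theme_codebook()$code) {
  if (is.data.frame(assignments)) {
    col <- intersect(c("theme_code", "theme", "code"), names(assignments))[1]
    if (is.na(col)) stop("no theme column found in assignments", call. = FALSE)
    assignments <- assignments[[col]]
  }
  assignments <- as.character(assignments)
  if (any(is.na(assignments))) stop("every post must be assigned a code", call. = FALSE)
  unknown <- setdiff(unique(assignments), codes)
  if (length(unknown) > 0) {
    stop("unknown theme code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  total <- length(assignments)
  if (total == 0) stop("no assignments", call. = FALSE)
  counts <- table(factor(assignments, levels = codes))
  out <- tibble::tibble(code = codes,
                        count = as.integer(counts),
                        percentage = round_half_up(100 * as.integer(counts) / total, 2))
  attr(out, "total") <- total
  class(out) <- c("theme_distribution", class(out))
  out
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` the fraction of identically coded posts and chance
#' agreement `pe` the sum over codes of the product of the raters' marginal
#' proportions.
#'
#' @param r1,r2 Equal-length label vectors.
#' @return A `kappa_result`: `po`, `pe`, `kappa`, `n`.
#' @export
cohens_kappa <- function(r1, r2) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  if (length(r1) != length(r2)) {
    stop("rater vectors differ in length (", length(r1), " vs ", length(r2), ")",
         call. = FALSE)
  }
  n <- length(r1)
  if (n == 0) stop("empty rater vectors", call. = FALSE)
  po <- mean(r1 == r2)
  codes <- union(r1, r2)
  p1 <- table(factor(r1, levels = codes)) / n
  p2 <- table(factor(r2, levels = codes)) / n
  pe <- sum(p1 * p2)
  kappa <- if (pe < 1) {
    (po - pe) / (1 - pe)
  } else if (po == 1) {
    1
  } else {
    stop("degenerate marginals: pe == 1 but po < 1", call. = FALSE)
  }
  structure(list(po = po, pe = unname(pe), kappa = unname(kappa), n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.4f (po %.4f, pe %.4f, n %d)\n",
              x$kappa, x$po, x$pe, x$n))
  invisible(x)
}

#' Codebook consistency check
#'
#' Mirrors the verification step of a coding exercise: draw `n_check` posts
#' (seeded, without replacement), compute the overall kappa between the two
#' raters on the drawn posts, plus a per-code one-vs-rest kappa (each code
#' against all others collapsed).
#'
#' @param assignments_r1,assignments_r2 Equal-length label vectors over the
#'   coded sample.
#' @param n_check Posts to draw (default 140).
#' @param seed Integer seed.
#' @return List with `overall` (a `kappa_result`) and `per_code` (tibble
#'   `code`, `kappa`).
#' @export
verify_codebook <- function(assignments_r1, assignments_r2, n_check = 140,
                            seed = 1L) {
  r1 <- as.character(assignments_r1); r2 <- as.character(assignments_r2)
  if (length(r1) != length(r2)) stop("rater vectors differ in length", call. = FALSE)
  if (n_check > length(r1)) {
    stop("n_check (", n_check, ") exceeds the coded sample size (", length(r1), ")",
         call. = FALSE)
  }
  idx <- withr::with_seed(seed, sort(sample.int(length(r1), n_check)))
  s1 <- r1[idx]; s2 <- r2[idx]
  overall <- cohens_kappa(s1, s2)
  codes <- sort(union(s1, s2))
  per_code <- tibble::tibble(code = codes, kappa = vapply(codes, function(code) {
    cohens_kappa(ifelse(s1 == code, code, "other"),
                 ifelse(s2 == code, code, "other"))$kappa
  }, numeric(1)))
  list(overall = overall, per_code = per_code, n_check = n_check)
}
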