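test_that("the shipped codebook has exactly the eight cause codes", {
  cb <- theme_codebook()
  expect_equal(nrow(cb), 8)
  expect_setequal(cb$code, c("IF-PD", "IF-LA", "IF-FB", "IF-P",
                             "IF-PE", "IF-SI", "IF-L", "IF-A"))
})

yearly_pool <- function(per_year_available = 300, years = 2011:2017) {
  rows <- do.call(rbind, lapply(years, function(y) {
    tibble::tibble(id = sprintf("y%d_%03d", y, seq_len(per_year_available)),
                   account_id = "a", follower_count = 0L,
                   date = sprintf("%d-06-15", y), text = "t")
  }))
  post_pool(rows)
}

test_that("stratified sampling draws the requested count from each year", {
  pool <- yearly_pool(300)
  s <- stratified_sample(pool, per_year = 200, seed = 1L)
  expect_equal(nrow(s), 1400)
  yr <- format(as.Date(s$date), "%Y")
  expect_true(all(table(yr) == 200))
  expect_identical(s$id, stratified_sample(pool, per_year = 200, seed = 1L)$id)
  expect_equal(nrow(stratified_sample(pool, per_year = 0, seed = 1L)), 0)
})

test_that("a short year is reported by name", {
  pool <- yearly_pool(300, years = 2011:2016)
  short <- yearly_pool(150, years = 2017)
  both <- post_pool(rbind(tibble::as_tibble(pool), tibble::as_tibble(short)))
  expect_error(stratified_sample(both, per_year = 200, seed = 1L), "2017")
})

test_that("the observed cause distribution reproduces its printed percentages", {
  counts <- c("IF-L" = 40, "IF-SI" = 110, "IF-LA" = 247, "IF-FB" = 25,
              "IF-PD" = 261, "IF-A" = 238, "IF-P" = 209, "IF-PE" = 270)
  assignments <- rep(names(counts), counts)
  dist <- theme_distribution(assignments)
  expect_equal(attr(dist, "total"), 1400)
  expect_equal(sum(dist$count), 1400)
  printed <- c("IF-L" = 2.86, "IF-SI" = 7.86, "IF-LA" = 17.64, "IF-FB" = 1.79,
               "IF-PD" = 18.64, "IF-A" = 17, "IF-P" = 14.93, "IF-PE" = 19.29)
  for (code in names(printed)) {
    expect_equal(dist$percentage[dist$code == code], unname(printed[code]),
                 info = code)
  }
  expect_lt(abs(sum(dist$percentage) - 100), 0.05)
})

test_that("degenerate distributions behave", {
  d <- theme_distribution(rep("IF-PE", 10))
  expect_equal(d$percentage[d$code == "IF-PE"], 100)
  expect_equal(sum(d$count), 10)
  expect_error(theme_distribution(c("IF-PE", "BOGUS")), "BOGUS")
  expect_error(theme_distribution(character(0)), "no assignments")
})

test_that("kappa reproduces hand-worked contingency examples", {
  expect_equal(cohens_kappa(letters[1:5], letters[1:5])$kappa, 1)
  # confusion [[20,5],[10,15]] over n = 50: po 0.70, pe 0.50, kappa 0.40
  r1 <- c(rep("A", 25), rep("B", 25))
  r2 <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 15))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$po, 0.70)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.40)
  # a constant rater carries no information beyond chance
  r1 <- rep(c("A", "B", "A", "A"), 10)
  expect_equal(cohens_kappa(r1, rep("A", 40))$kappa, 0)
  expect_error(cohens_kappa(c("A", "B"), "A"), "length")
})

test_that("kappa is symmetric in its raters", {
  withr::with_seed(2L, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      codes <- LETTERS[1:sample(2:5, 1)]
      r1 <- sample(codes, n, replace = TRUE)
      r2 <- sample(codes, n, replace = TRUE)
      a <- cohens_kappa(r1, r2)
      b <- cohens_kappa(r2, r1)
      expect_equal(a$kappa, b$kappa)
      expect_equal(a$po, b$po)
    }
  })
})

test_that("kappa matches a brute-force contingency computation on 1000 random cases", {
  brute_force_kappa <- function(r1, r2) {
    codes <- sort(unique(c(r1, r2)))
    n <- length(r1)
    tab <- matrix(0, length(codes), length(codes),
                  dimnames = list(codes, codes))
    for (i in seq_len(n)) tab[r1[i], r2[i]] <- tab[r1[i], r2[i]] + 1
    po <- sum(diag(tab)) / n
    pe <- sum((rowSums(tab) / n) * (colSums(tab) / n))
    (po - pe) / (1 - pe)
  }
  withr::with_seed(3L, {
    for (case in 1:1000) {
      n <- sample(4:30, 1)
      codes <- LETTERS[1:sample(2:6, 1)]
      r1 <- sample(codes, n, replace = TRUE)
      r2 <- sample(codes, n, replace = TRUE)
      oracle <- brute_force_kappa(r1, r2)
      if (!is.finite(oracle)) next  # degenerate pe == 1 draws
      expect_equal(cohens_kappa(r1, r2)$kappa, oracle, tolerance = 1e-12)
    }
  })
})

test_that("degenerate marginals are handled explicitly", {
  expect_equal(cohens_kappa(rep("A", 5), rep("A", 5))$kappa, 1)
})

test_that("codebook verification draws a seeded subset and one-vs-rest kappas", {
  gen <- fixture_corpus()
  r <- simulate_raters(gen$truth, error_rate = 0, seed = 1L)
  v <- verify_codebook(r$rater1, r$rater2, n_check = 50, seed = 2L)
  expect_equal(v$overall$kappa, 1)
  expect_true(all(v$per_code$kappa == 1))
  expect_error(verify_codebook(r$rater1, r$rater2, n_check = nrow(r) + 1),
               "exceeds")
  # drawing the full sample equals computing on everything
  v_full <- verify_codebook(r$rater1, r$rater2, n_check = nrow(r), seed = 3L)
  expect_equal(v_full$overall$kappa, cohens_kappa(r$rater1, r$rater2)$kappa)
})

test_that("verification detects pure-noise coding over many codes", {
  codes <- theme_codebook()$code
  truth <- sample(rep(codes, length.out = 4000))
  r <- simulate_raters(truth, error_rate = 1, seed = 5L, codes = codes)
  v <- verify_codebook(r$rater1, r$rater2, n_check = 4000, seed = 6L)
  expect_lt(abs(v$overall$kappa), 0.05)
})
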