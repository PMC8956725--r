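three_point_coords <- function() {
  matrix(c(0, 0, 0, 1, 1, 0), ncol = 2, byrow = TRUE,
         dimnames = list(c("a", "b", "c"), c("x", "y")))
}

test_that("2D reduction lands every primitive in the unit square, deterministically", {
  vecs <- withr::with_seed(1L, matrix(stats::rnorm(10 * 20), 10, 20,
                                      dimnames = list(paste0("t", 1:10), NULL)))
  co <- reduce_2d(vecs, perplexity = 3, seed = 42L)
  expect_equal(dim(co), c(10, 2))
  expect_true(all(co >= 0 & co <= 1))
  expect_identical(co, reduce_2d(vecs, perplexity = 3, seed = 42L))
  expect_false(identical(co, reduce_2d(vecs, perplexity = 3, seed = 43L)))
  expect_error(reduce_2d(vecs, perplexity = 10), "perplexity")
  expect_error(reduce_2d(vecs[1:2, ], perplexity = 1), ">= 3")
})

test_that("well-separated high-dimensional clusters stay separated on the map", {
  skip_if_not_installed("cluster")
  n <- 12
  vecs <- withr::with_seed(2L, rbind(
    matrix(stats::rnorm(n * 40, mean = 0, sd = 0.05), n, 40),
    matrix(stats::rnorm(n * 40, mean = 1, sd = 0.05), n, 40)))
  rownames(vecs) <- paste0("t", seq_len(2 * n))
  labels <- rep(1:2, each = n)
  co <- reduce_2d(vecs, perplexity = 5, seed = 42L)
  sil <- cluster::silhouette(labels, stats::dist(co))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("relative distances follow hand geometry", {
  d <- relative_distances(three_point_coords())
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["b", "c"], sqrt(2))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  same <- matrix(0, 2, 2, dimnames = list(c("p", "q"), c("x", "y")))
  expect_equal(relative_distances(same)["p", "q"], 0)
  expect_error(relative_distances(three_point_coords()[1, , drop = FALSE]),
               "at least 2")
})

test_that("distance statistics match hand computations and type-7 quartiles", {
  s <- distance_stats(relative_distances(three_point_coords()))
  expect_equal(s$mean, (2 + sqrt(2)) / 3, tolerance = 1e-12)
  expect_equal(s$median, 1)
  expect_equal(s$minimum, 1)
  expect_equal(s$maximum, sqrt(2))
  # all-equal distances collapse the summary
  sq <- matrix(c(0, 3, 3, 3, 0, 3, 3, 3, 0), 3, 3)
  se <- distance_stats(sq)
  expect_equal(c(se$minimum, se$lower_quartile, se$median, se$mean, se$maximum),
               rep(3, 5))
  # upper-triangle values {1,2,3,4}: type-7 lower quartile 1.75
  m4 <- matrix(0, 4, 4)
  m4[1, 2] <- 1; m4[1, 3] <- 2; m4[1, 4] <- 3; m4[2, 3] <- 4
  m4[2, 4] <- 2.5; m4[3, 4] <- 1.5
  m4 <- m4 + t(m4)
  vals <- sort(m4[upper.tri(m4)])
  expect_equal(distance_stats(m4)$lower_quartile,
               unname(stats::quantile(vals, 0.25, type = 7)))
  # linear interpolation by hand: values 1..6, Q1 index 1 + 0.25 * 5 = 2.25
  small <- matrix(0, 4, 4)
  small[upper.tri(small)] <- c(1, 2, 3, 4, 5, 6)
  small <- small + t(small)
  expect_equal(distance_stats(small)$lower_quartile, 2.25)
})

test_that("distance statistics agree with a sort-based brute-force oracle", {
  withr::with_seed(5L, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      co <- matrix(stats::runif(n * 2), n, 2,
                   dimnames = list(paste0("t", 1:n), NULL))
      d <- relative_distances(co)
      s <- distance_stats(d)
      vals <- c()
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        vals <- c(vals, sqrt(sum((co[i, ] - co[j, ])^2)))
      }
      vals <- sort(vals)
      expect_equal(s$minimum, vals[1])
      expect_equal(s$maximum, vals[length(vals)])
      expect_equal(s$mean, mean(vals))
      expect_equal(s$median, unname(stats::quantile(vals, 0.5, type = 7)))
      expect_equal(s$lower_quartile, unname(stats::quantile(vals, 0.25, type = 7)))
      expect_equal(s$n_pairs, n * (n - 1) / 2)
    }
  })
})

published_stats <- function(mean, q1) {
  structure(list(minimum = 0, lower_quartile = q1, median = NA_real_,
                 mean = mean, upper_quartile = NA_real_, maximum = 1,
                 n_pairs = NA_integer_),
            class = "distance_stats")
}

test_that("the closeness rule is strict in both published worked examples", {
  # personal-experience map: mean 0.1615, lower quartile 0.1002
  expect_true(is_close(0.0091, published_stats(0.1615, 0.1002))$close)
  expect_false(is_close(0.2, published_stats(0.1615, 0.1002))$close)
  # physical-defects map: a distance exactly at the lower quartile is not close
  expect_false(is_close(0.1060, published_stats(0.1775, 0.1060))$close)
  expect_error(is_close(-0.1, published_stats(0.2, 0.1)), "non-negative")
})

test_that("group mean distance averages the within-subset pairs", {
  d <- relative_distances(three_point_coords())
  expect_equal(group_mean_distance(c("a", "b", "c"), d), (2 + sqrt(2)) / 3,
               tolerance = 1e-12)
  expect_equal(group_mean_distance(c("a", "b"), d), 1)
  same <- matrix(0, 2, 2, dimnames = list(c("p", "q"), c("x", "y")))
  expect_equal(group_mean_distance(c("p", "q"), relative_distances(same)), 0)
  expect_error(group_mean_distance(c("a", "nope"), d), "nope")
  # whole-map subset reproduces the overall mean statistic
  s <- distance_stats(d)
  expect_equal(group_mean_distance(c("a", "b", "c"), d), s$mean)
})

test_that("closeness verdicts are invariant to uniform coordinate rescaling", {
  co <- withr::with_seed(9L, matrix(stats::runif(16), 8, 2,
                                    dimnames = list(paste0("t", 1:8), NULL)))
  d1 <- relative_distances(co)
  s1 <- distance_stats(d1)
  for (scale in c(0.1, 3, 250)) {
    d2 <- relative_distances(co * scale)
    s2 <- distance_stats(d2)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(is_close(d1[i, j], s1)$close, is_close(d2[i, j], s2)$close)
    }
  }
})

test_that("a full semantic map is internally consistent", {
  pool <- fixture_theme_pool("IF-PE")
  prims <- extract_primitives(pool, fixture_model(), k = 20)
  map <- build_semantic_map(prims, perplexity = 5, seed = 42L)
  expect_equal(rownames(map$coords), prims$token)
  expect_equal(map$distances, t(map$distances))
  cl <- map_closeness(map)
  direct <- cl$distance < map$stats$mean & cl$distance < map$stats$lower_quartile
  expect_equal(cl$close, direct)
  expect_equal(nrow(cl), choose(20, 2))
})

test_that("atlas rendering writes a figure with the statistics box", {
  pool <- fixture_theme_pool("IF-PE")
  prims <- extract_primitives(pool, fixture_model(), k = 10)
  map <- build_semantic_map(prims, perplexity = 3, seed = 42L)
  path <- withr::local_tempfile(fileext = ".png")
  p <- render_atlas(map, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
  labs <- vapply(p$layers, function(l) class(l$geom)[1], character(1))
  expect_true("GeomLabel" %in% labs)
  expect_error(render_atlas(map, withr::local_tempfile(fileext = ".bmp")),
               "format")
})

test_that("map exports round-trip through TSV and JSON", {
  pool <- fixture_theme_pool("IF-PE")
  prims <- extract_primitives(pool, fixture_model(), k = 8)
  map <- build_semantic_map(prims, perplexity = 3, seed = 1L)
  dist_path <- withr::local_tempfile(fileext = ".tsv")
  stats_path <- withr::local_tempfile(fileext = ".json")
  write_map(map, dist_path, stats_path)
  back <- as.matrix(utils::read.table(dist_path, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(map$distances), tolerance = 1e-12)
  stats <- jsonlite::read_json(stats_path)
  expect_equal(stats$mean, map$stats$mean, tolerance = 1e-12)
})
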