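#' Project primitive vectors to the plane
#'
#' Reduces the high-dimensional primitive vectors to 2D with t-SNE and
#' min-max normalizes each axis to the unit square, so distances on the map
#' are "relative distances" on a common scale regardless of the projection's
#' raw extent.
#'
#' @param primitives A `primitive_table` from [extract_primitives()], or a
#'   numeric matrix with token rownames.
#' @param perplexity t-SNE perplexity (default 5; must be below the number
#'   of primitives).
#' @param seed Integer seed (default 42).
#' @return Matrix of normalized coordinates, one row per primitive, columns
#'   `x`, `y`.
#' @export
reduce_2d <- function(primitives, perplexity = 5, seed = 42L) {
  X <- primitive_vectors(primitives)
  Y <- tsne_embed(X, perplexity = perplexity, seed = seed)
  Y <- apply(Y, 2, function(col) {
    r <- range(col)
    if (r[2] - r[1] < .Machine$double.eps) return(rep(0.5, length(col)))
    (col - r[1]) / (r[2] - r[1])
  })
  dimnames(Y) <- list(rownames(X), c("x", "y"))
  Y
}

primitive_vectors <- function(primitives) {
  if (is.matrix(primitives)) return(primitives)
  v <- attr(primitives, "vectors")
  if (is.null(v)) stop("primitives carry no embedding vectors", call. = FALSE)
  v
}

#' Pairwise relative distances between map points
#'
#' @param coords Normalized 2D coordinates from [reduce_2d()].
#' @return Symmetric Euclidean distance matrix with zero diagonal.
#' @export
relative_distances <- function(coords) {
  if (is.null(dim(coords)) || nrow(coords) < 2) {
    stop("need at least 2 points", call. = FALSE)
  }
  as.matrix(stats::dist(coords))
}

#' Distance statistics of a semantic map
#'
#' Five-number-style summary over the strict upper triangle of the distance
#' matrix: minimum, lower quartile, median, mean, maximum (the upper
#' quartile is included for completeness). Quartiles use linear
#' interpolation (quantile type 7).
#'
#' @param distances Symmetric distance matrix from [relative_distances()].
#' @return A `distance_stats` list.
#' @export
distance_stats <- function(distances) {
  if (is.null(dim(distances)) || nrow(distances) < 2) {
    stop("need at least 2 points", call. = FALSE)
  }
  vals <- distances[upper.tri(distances)]
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(minimum = min(vals), lower_quartile = q[1], median = q[2],
                 mean = mean(vals), upper_quartile = q[3], maximum = max(vals),
                 n_pairs = length(vals)),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("<distance_stats> min %.4f | Q1 %.4f | median %.4f | mean %.4f | max %.4f (%d pairs)\n",
              x$minimum, x$lower_quartile, x$median, x$mean, x$maximum, x$n_pairs))
  invisible(x)
}

#' The closeness rule
#'
#' Two primitives are semantically close when their relative distance is
#' strictly below both the mean and the lower quartile of all pairwise
#' distances on the same map. Both inequalities are strict: a distance
#' exactly equal to the lower quartile is not close.
#'
#' @param distance Non-negative relative distance between the pair.
#' @param stats A `distance_stats` for the map.
#' @param pair Optional character pair of token names, recorded in the
#'   verdict.
#' @return A `closeness_verdict`: `pair`, `distance`, `close`.
#' @export
is_close <- function(distance, stats, pair = c(NA_character_, NA_character_)) {
  if (length(distance) != 1 || is.na(distance) || distance < 0) {
    stop("distance must be a single non-negative number", call. = FALSE)
  }
  stopifnot(inherits(stats, "distance_stats"))
  structure(list(pair = pair, distance = distance,
                 close = distance < stats$mean && distance < stats$lower_quartile),
            class = "closeness_verdict")
}

#' @export
print.closeness_verdict <- function(x, ...) {
  lab <- if (all(is.na(x$pair))) "" else paste0(x$pair[1], " - ", x$pair[2], ": ")
  cat(sprintf("<closeness_verdict> %sdistance %.4f -> %s\n", lab, x$distance,
              if (x$close) "close" else "not close"))
  invisible(x)
}

#' Mean relative distance within a token subset
#'
#' @param tokens Two or more token names present on the map.
#' @param map A `semantic_map` (or a distance matrix with token dimnames).
#' @return Mean of all pairwise relative distances within the subset.
#' @export
group_mean_distance <- function(tokens, map) {
  distances <- if (inherits(map, "semantic_map")) map$distances else map
  missing_t <- setdiff(tokens, rownames(distances))
  if (length(missing_t) > 0) {
    stop("token(s) not on the map: ", paste(missing_t, collapse = ", "), call. = FALSE)
  }
  if (length(tokens) < 2) stop("need >= 2 tokens", call. = FALSE)
  sub <- distances[tokens, tokens]
  mean(sub[upper.tri(sub)])
}

#' Build a semantic map
#'
#' Bundles the full atlas computation: t-SNE projection of the primitive
#' vectors, unit-square normalization, pairwise relative distances, distance
#' statistics, and a Gaussian kernel-density surface over the map.
#'
#' @param primitives A `primitive_table` from [extract_primitives()].
#' @param perplexity,seed Passed to [reduce_2d()].
#' @param bandwidth Kernel bandwidth for [MASS::kde2d()]; default
#'   rule-of-thumb ([MASS::bandwidth.nrd()]).
#' @param grid_n Density grid resolution per axis.
#' @return A `semantic_map`: `primitives`, `coords`, `distances`, `stats`,
#'   `density`, `seed`.
#' @export
build_semantic_map <- function(primitives, perplexity = 5, seed = 42L,
                               bandwidth = NULL, grid_n = 100) {
  coords <- reduce_2d(primitives, perplexity = perplexity, seed = seed)
  distances <- relative_distances(coords)
  stats <- distance_stats(distances)
  bw <- bandwidth %||% {
    b <- c(MASS::bandwidth.nrd(coords[, 1]), MASS::bandwidth.nrd(coords[, 2]))
    b[b <= 0] <- 0.1
    b
  }
  density <- MASS::kde2d(coords[, 1], coords[, 2], h = bw, n = grid_n,
                         lims = c(-0.1, 1.1, -0.1, 1.1))
  structure(list(primitives = primitives, coords = coords,
                 distances = distances, stats = stats, density = density,
                 bandwidth = bw, seed = as.integer(seed)),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  cat("<semantic_map> ", nrow(x$coords), " primitives (seed ", x$seed, ")\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Closeness verdicts for every pair on a map
#'
#' @param map A `semantic_map`.
#' @return Tibble of all unordered pairs: `token1`, `token2`, `distance`,
#'   `close`, sorted by distance.
#' @export
map_closeness <- function(map) {
  d <- map$distances
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble::tibble(token1 = rownames(d)[idx[, 1]],
                        token2 = colnames(d)[idx[, 2]],
                        distance = d[idx])
  out$close <- out$distance < map$stats$mean & out$distance < map$stats$lower_quartile
  out[order(out$distance), ]
}

#' Render the semantic atlas
#'
#' Draws the map the way the analysis figures are drawn: kernel-density
#' shading (darker where primitives are denser), one label per primitive at
#' its coordinates, and the distance statistics (minimum, lower quartile,
#' median, mean, maximum, to 4 decimals) boxed in the upper-left corner.
#'
#' @param map A `semantic_map`.
#' @param path Output file; format from extension (`.png` or `.svg`).
#' @param width,height,dpi Device size in inches and resolution.
#' @return The ggplot object, invisibly; the file is written as a side
#'   effect.
#' @export
render_atlas <- function(map, path, width = 7, height = 6, dpi = 150) {
  dens <- map$density
  grid <- expand.grid(x = dens$x, y = dens$y)
  grid$z <- as.vector(dens$z)
  pts <- tibble::tibble(x = map$coords[, 1], y = map$coords[, 2],
                        token = rownames(map$coords))
  s <- map$stats
  stats_text <- paste(
    sprintf("min: %.4f", s$minimum),
    sprintf("lower quartile: %.4f", s$lower_quartile),
    sprintf("median: %.4f", s$median),
    sprintf("mean: %.4f", s$mean),
    sprintf("max: %.4f", s$maximum),
    sep = "\n")
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20", guide = "none") +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 0.8, colour = "firebrick") +
    ggplot2::geom_text(data = pts, ggplot2::aes(x = .data$x, y = .data$y, label = .data$token),
                       size = 2.4, vjust = -0.8) +
    ggplot2::annotate("label", x = -0.08, y = 1.08, label = stats_text,
                      hjust = 0, vjust = 1, size = 2.6) +
    ggplot2::coord_fixed(xlim = c(-0.1, 1.1), ylim = c(-0.1, 1.1), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg")) stop("unsupported figure format: .", ext, call. = FALSE)
  if (ext == "svg" && !isTRUE(capabilities("cairo"))) {
    stop("SVG output needs cairo support in this R build", call. = FALSE)
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(p)
}

#' Export the distance matrix as TSV and the statistics as JSON
#'
#' @param map A `semantic_map`.
#' @param dist_path,stats_path Output files (either may be `NULL` to skip).
#' @export
write_map <- function(map, dist_path = NULL, stats_path = NULL) {
  if (!is.null(dist_path)) {
    utils::write.table(map$distances, dist_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(stats_path)) {
    jsonlite::write_json(unclass(map$stats), stats_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(map)
}
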