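#!/usr/bin/env Rscript

# Step 5 — semantic primitives and the semantic atlas.
#
# For each of the four most frequent causes, the theme's posts form a field
# corpus; candidates surviving the POS filter are scored with the combined
# semantic-frequency / semantic-active-index criterion, the top 30 are
# projected to the plane with t-SNE, and each map's relative-distance
# statistics, closeness pairs, and kernel-density atlas are written out.

library(inferatlas)

seed <- 2026L
out <- "results"
if (!file.exists(file.path(out, "wpp.jsonl")) ||
    !file.exists(file.path(out, "embedding.w2v"))) {
  stop("run analysis/02 and analysis/03 first")
}
wpp <- read_posts(file.path(out, "wpp.jsonl"))
truth <- readr::read_csv(file.path(out, "ground_truth.csv"),
                         show_col_types = FALSE)
model <- read_word2vec(file.path(out, "embedding.w2v"))

themes <- names(sort(table(truth$theme), decreasing = TRUE))[1:4]
for (th in themes) {
  ids <- truth$post_id[!is.na(truth$theme) & truth$theme == th]
  field <- post_pool(wpp[wpp$id %in% ids, ])
  field$theme_code <- th
  prims <- extract_primitives(field, model, k = 30)
  map <- build_semantic_map(prims, perplexity = 5, seed = seed + 20L)
  cat(sprintf("\n== theme %s (%d field posts, %d primitives) ==\n",
              th, nrow(field), nrow(prims)))
  print(map$stats)
  cl <- map_closeness(map)
  cat("closest pairs:\n")
  print(utils::head(cl, 5))
  planted <- sum(prims$token[1:10] %in%
                   sprintf("%s_core%02d", tolower(gsub("-", "", th)), 1:10))
  cat(sprintf("planted cores in top 10: %d/10\n", planted))
  write_primitives(prims, file.path(out, sprintf("primitives_%s.csv", th)))
  readr::write_csv(cl, file.path(out, sprintf("closeness_%s.csv", th)))
  write_map(map, stats_path = file.path(out, sprintf("distance_stats_%s.json", th)))
  render_atlas(map, file.path(out, sprintf("atlas_%s.png", th)))
}
cat("\nwrote per-theme primitives, closeness tables, stats and atlases\n")
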