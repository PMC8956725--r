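#!/usr/bin/env Rscript

# Step 4 — theme coding and consistency verification.
#
# From the cleaned pool, 200 posts per year (1400 in total) are drawn for
# coding with the eight-code cause codebook. Two simulated raters (10%
# independent error) code the sample; the cause distribution is tabulated
# and the codebook's consistency is verified with Cohen's kappa on a
# 140-post check, overall and one-vs-rest per code.

library(inferatlas)

seed <- 2026L
out <- "results"
if (!file.exists(file.path(out, "wpp.jsonl"))) {
  stop("run analysis/02_build_post_pool.R first")
}
wpp <- read_posts(file.path(out, "wpp.jsonl"))
truth <- readr::read_csv(file.path(out, "ground_truth.csv"),
                         show_col_types = FALSE)

sampled <- stratified_sample(wpp, per_year = 200, seed = seed + 10L)
codes <- truth$theme[match(sampled$id, truth$post_id)]
raters <- simulate_raters(stats::setNames(codes, sampled$id),
                          error_rate = 0.1, seed = seed + 11L,
                          codes = theme_codebook()$code)

dist <- theme_distribution(codes)
print(dist, n = 8)
readr::write_csv(tibble::as_tibble(dist), file.path(out, "theme_distribution.csv"))

check <- verify_codebook(raters$rater1, raters$rater2, n_check = 140,
                         seed = seed + 12L)
cat(sprintf("overall kappa on the 140-post check: %.4f\n", check$overall$kappa))
print(check$per_code, n = 8)
readr::write_csv(check$per_code, file.path(out, "per_code_kappa.csv"))
jsonlite::write_json(unclass(check$overall), file.path(out, "coding_kappa.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote theme_distribution.csv, per_code_kappa.csv, coding_kappa.json\n")
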