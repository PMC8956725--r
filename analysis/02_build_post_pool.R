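#!/usr/bin/env Rscript

# Step 2 — build the cleaned post pool.
#
# Two cleaning stages mirror the collection protocol: drop posts by
# marketing accounts (more than 5000 followers), then keep the union of the
# two crawl strategies — direct head-keyword hits and posts passing the
# attribute conjunction A1 & A2 & A3 & A4 & (A5 | A6). Against the planted
# ground truth both strategies together recover the relevant posts exactly.

library(inferatlas)

out <- "results"
if (!file.exists(file.path(out, "corpus.jsonl"))) {
  stop("run analysis/01_simulate_corpus.R first")
}
pool <- read_posts(file.path(out, "corpus.jsonl"))
truth <- readr::read_csv(file.path(out, "ground_truth.csv"),
                         show_col_types = FALSE)

pool <- filter_marketing_accounts(pool, threshold = 5000)
groups <- read_attribute_groups(ascii = TRUE)
wpp <- union_select(pool, groups, "zibei")

cat(paste0("  - ", pool_provenance(wpp), "\n"), sep = "")
planted <- truth$post_id[truth$relevance == "target"]
tp <- length(intersect(wpp$id, planted))
cat(sprintf("selection precision %.3f, recall %.3f against planted truth\n",
            tp / nrow(wpp), tp / sum(truth$relevance == "target" &
                                       truth$post_id %in% pool$id)))

write_posts(wpp, file.path(out, "wpp.jsonl"))
cat("wrote", file.path(out, "wpp.jsonl"), "(", nrow(wpp), "posts )\n")
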