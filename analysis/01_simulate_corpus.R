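#!/usr/bin/env Rscript

# Step 1 — simulate the study corpus.
#
# The original microblog corpus is not redistributable, so the workflow runs
# on a synthetic corpus with planted structure: 4000 posts over 2011-2017,
# half found by direct head-keyword search, 30% matching the six-attribute
# conjunctive filter, 20% off-target noise (advertisement- and
# aphorism-like), with 20% of accounts given marketing-scale follower
# counts and eight planted theme clusters weighted like the observed cause
# distribution.

library(inferatlas)

seed <- 2026L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
gen <- generate_corpus(cfg)

write_posts(gen$pool, file.path(out, "corpus.jsonl"))
readr::write_csv(gen$truth$posts, file.path(out, "ground_truth.csv"))

cat("posts:", nrow(gen$pool), "\n")
print(table(gen$truth$posts$post_type))
cat("marketing-account posts:", sum(gen$truth$posts$is_marketing), "\n")
cat("themes planted over relevant posts:\n")
print(sort(table(gen$truth$posts$theme), decreasing = TRUE))
cat("wrote", file.path(out, "corpus.jsonl"), "and ground_truth.csv\n")
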