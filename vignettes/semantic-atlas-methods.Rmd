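---
title: "Methods: mining the causes of inferiority feelings from microblog posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining the causes of inferiority feelings from microblog posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inferatlas)
```

## The problem

Feelings of inferiority — perceived weakness, helplessness, a sense of
being worth less than others — are rarely brought to clinicians directly,
but are expressed abundantly and spontaneously on social media. The
pipeline in this package turns a stream of microblog posts into two
complementary pictures of the *causes* of those feelings:

* a macro picture: a coded sample of posts classified into eight cause
  themes, with an inter-rater consistency check;
* a micro picture: for each theme, a *semantic atlas* — a 2D map of the
  theme's most salient vocabulary, on which geometric closeness stands for
  semantic relatedness.

Everything between raw posts and those two pictures (keyword/ontology
selection, noise filtering, classification, embedding, primitive scoring,
projection, distance statistics) is implemented and tested here.

## Corpus selection

Two selection strategies are combined, because many posts express intense
inferiority without ever naming it:

1. **Head-keyword search** — any post containing the head keyword
   (`keyword_select()`; exact token match on segmented posts, substring
   match on raw text).
2. **Ontological attribute filter** — the concept is decomposed into six
   attribute keyword groups (`A1` think/feel, `A2` oneself/myself/I, `A3`
   inferior-to/not-equal-to, `A4` other-people/he/she/them, `A5`
   feeling-low and synonyms, `A6` sadness and synonyms). A post is selected
   iff it hits all of `A1`–`A4` and at least one of `A5`/`A6`
   (`eq1_filter()`). The shipped table (`read_attribute_groups()`) carries
   both the original Chinese tokens and an ASCII transliteration used by
   the synthetic corpus and the examples.

Matching is **exact token equality** on the segmented token list by
default. Substring matching against raw text is available behind the
`use_text` flag for unsegmented input, but token-level matching is the
default because it is reproducible and independent of the segmenter.
Pronoun members of `A4` are matched like any other token; there is no
coreference resolution. The filter is monotone: adding tokens to a post
can never deselect it.

Before selection, posts from accounts with **more than 5000 followers**
are removed (`filter_marketing_accounts()`): such accounts are
overwhelmingly marketing accounts posting advertisements. "More than" is
read strictly — an account with exactly 5000 followers is kept. The
follower count is treated as a per-post snapshot, since an account's count
may change over the collection window.

## Relevance classification

Even after selection, some posts are aphorisms, running commentary or
advertisements that survived the follower filter. A binary
target/off-target classifier cleans them:

* **Features** (`vectorize_posts()`): the arithmetic mean of the post's
  in-vocabulary skip-gram vectors (`embedding_mean`, the default), or
  token counts over a fixed vocabulary (`bag_of_words`, kept as a
  baseline). A post with no in-vocabulary token maps to the zero vector
  and is reported in a warnings list. Both schemes are invariant to token
  order within a post.
* **Model** (`train_classifier()`): a support vector machine via
  `e1071::svm`, linear kernel, cost `C = 1`. The kernel and the
  vectorization scheme are configuration choices, not inferences: the
  protocol this pipeline follows does not specify them, and a linear
  kernel over mean embeddings is the minimal choice consistent with
  training the embedding before classification. Both are exposed in the
  configuration.
* **Evaluation** (`evaluate_classifier()`): accuracy plus the full 2x2
  confusion table. Validation follows an equal-per-class design, so a
  permuted-label control collapses to accuracy 1/2 rather than the
  majority-class rate.

On the synthetic corpus, where the union selection is already exact, the
classifier is evaluated (held-out accuracy, permuted control) rather than
used to drop posts. The off-target rate of real labelled data of this kind
is around 20%, which is the generator's default noise share.

## The skip-gram background model

The semantic backbone is a skip-gram word-embedding model with negative
sampling, trained on the tokenized corpus with **window 10** and
**dimension 400** (the settings used for the background-knowledge corpus
this pipeline models; both exposed). Because no suitable R implementation
was available among the package's allowed dependencies, the trainer is
written in Rcpp (`src/sgns.cpp`) following the standard formulation:
dynamic context window uniform on `1..window`, unigram^0.75 noise
distribution, 5 negative samples, linearly decaying learning rate from
0.025 to 1e-4, `min_count` 5, 5 epochs. Defaults not fixed by the modelled
protocol (negatives, learning rate, epochs) are ordinary word2vec
defaults, flagged as non-reproduction parameters.

Training is **single-threaded with its own seeded RNG**, so a given
(corpus, parameters, seed) yields bit-identical vectors — multi-worker
training would not. Distances in embedding space are cosine distances
(`embedding_distance()`, in `[0, 2]`, symmetric, zero on the diagonal).
Models round-trip through the standard word2vec text format
(`write_word2vec()` / `read_word2vec()`).

The background model is trained on the labelled corpus *before* the final
cleaning step (the analog of training on everything that was collected):
this lets the same model supply features for the relevance classifier,
and only adds noise-class vocabulary that the candidate filters of the
extraction stage discard anyway.

## SF–SAI semantic primitives

For one theme, the *field corpus* is that theme's posts. Candidates
(`build_candidates()`) are field-corpus tokens that carry an allowed
part-of-speech tag (default nouns/verbs/adjectives, Jieba-style tags),
are not stop words (the shipped stop list is empty; supply your own), and
are in the embedding vocabulary. Each candidate is scored twice:

* **Semantic frequency (SF)** — the candidate's relative frequency among
  all candidate-token occurrences in the field corpus, in `(0, 1]`.
* **Semantic active index (SAI)** — the mean cosine similarity between the
  candidate's vector and every *other* candidate's vector, in `[-1, 1]`:
  a token that is coherent with the rest of the theme's vocabulary scores
  high.

SF and SAI are each min–max normalized to `[0, 1]` over the candidate set
and combined by **product** (the default combiner); the top `k` by
combined score (default `k = 30`, the order of magnitude a readable atlas
holds) are the theme's primitives. Ties break lexicographically, so
extraction is fully deterministic. When every candidate has the same SF
(or SAI), the normalized score is defined as 1 for all, which reduces the
ranking to the other component or, failing that, to the lexicographic
tie-break.

This SF–SAI formulation is this package's reconstruction of the combined
frequency-plus-coherence criterion: the minimal reading of "semantic
frequency" and "semantic activity based on the coherence of the text".
The exact published formulas for the two components are not available in
the text this design works from, so both scores, the normalization and
the combiner are pluggable, and the shipped version is not asserted to be
numerically identical to any external implementation. The ranking it
produces is validated structurally instead: on corpora with planted core
vocabularies it must recover the cores (see the acceptance suite), it is
invariant under duplication of the field corpus, and SAI equals a brute
force O(n^2) pairwise loop on every tested candidate set.

## The semantic atlas

Primitive vectors (400-dim) are projected to 2D with **t-SNE**. The
projection is an exact (dense) implementation — primitive sets are tens of
points, where exact t-SNE is cheap and deterministic given the seed
(default 42): conditional probabilities matched to a target perplexity
(default 5, suitable for 20–50 points) by per-point precision search,
then 500 gradient-descent iterations with momentum 0.5/0.8, adaptive
gains, and 4x early exaggeration for the first 100 iterations.

The raw 2D coordinates are **min–max normalized per axis to the unit
square**, and "relative distance" is Euclidean distance between normalized
points. Normalizing by coordinate extent (rather than by the maximum
pairwise distance) was chosen because it gives every map the same frame;
either choice leaves closeness verdicts unchanged, since all distances
and their statistics rescale together — a property the tests assert.

Each map is summarized by the distance statistics over the strict upper
triangle of its distance matrix: minimum, lower quartile, median, mean,
maximum (upper quartile also emitted for completeness, since the
closeness rule only consumes the lower one). Quartiles use **linear
interpolation (quantile type 7)** — the convention had to be fixed for
testability and type 7 is R's default.

**Closeness rule** (`is_close()`): a pair of primitives is semantically
close iff its distance is strictly below *both* the mean and the lower
quartile of all pairwise distances on the same map. Both inequalities are
strict ("bigger than" read literally), so a pair exactly at the lower
quartile is not close. `group_mean_distance()` gives the mean pairwise
distance within any primitive subset, the statistic used when a cluster
of three or more primitives is discussed together.

`render_atlas()` draws the atlas the way the study figures are drawn:
Gaussian kernel-density shading (`MASS::kde2d`, rule-of-thumb bandwidth,
overridable; darker = denser), one label per primitive, and the distance
statistics to 4 decimals boxed in the upper-left corner.

## Theme coding and consistency

The coded sample is a **yearly stratified sample** — 200 posts per year
over seven years (1400 posts) by default — drawn uniformly without
replacement per year (`stratified_sample()`; a year with too few posts is
an error naming the year). Each post gets exactly one of the eight codes;
`theme_distribution()` tabulates counts and percentages. Percentages are
rounded **half-up** to 2 decimals (270/1400 is 19.29), and the rounded
percentages sum to 100 within 0.05.

Consistency is measured with **Cohen's kappa**:
`kappa = (po - pe) / (1 - pe)` with `po` the observed agreement and `pe`
the chance agreement from the raters' marginals. The degenerate case
`pe = 1` (both raters constant and identical) is defined as `kappa = 1`.
`verify_codebook()` draws a seeded `n_check`-post subset (default 140) and
reports the overall kappa plus a per-code kappa computed **one-vs-rest**
(each code against all others collapsed) — whether per-theme consistency
should be one-vs-rest or subset-restricted is not specified by the
modelled protocol; one-vs-rest was chosen because it is defined for every
code regardless of subset size, and it is labelled as a choice.

The human parts of coding — negotiation to consensus, returning
ambiguous posts to the pool — are not computable and are replaced by
`simulate_raters()`: each simulated rater reports the true code with
probability `1 - error_rate` and otherwise a uniformly random *other*
code. One consequence worth noting: with only two codes and
`error_rate = 1` the channel flips both raters deterministically, so they
agree perfectly and kappa is 1; kappa only collapses to ~0 under total
noise when there are many codes. The tests assert the analytically
correct behaviour. At the default `error_rate = 0.1` with eight codes and
the default theme weights, a 10,000-replicate simulation of the channel
puts kappa at 0.777 +/- 0.007 (n = 5000) — comfortably inside the 0.65–0.89
range reported for careful human coding of this kind, which is what the
default is meant to emulate.

## The synthetic corpus

`generate_corpus()` emulates the *structure* of the study corpus, not its
language:

* **Post types in exact counts** (largest-remainder rounding): 50%
  keyword posts (contain the head keyword), 30% attribute posts (one
  member from each of `A1`–`A4` plus one from `A5`/`A6`, never the head
  keyword), 20% off-target posts (advertisement-like and aphorism-like,
  two disjoint noise vocabularies; off-target posts never satisfy the
  attribute conjunction). Exact counts make filter fidelity assertable:
  selection precision and recall against the planted truth must be
  exactly 1.
* **Themes**: each relevant post draws a theme from the eight codes with
  weights equal to the observed cause distribution of the coded sample
  (so rare themes are rare here too). Content tokens come 60% from the
  theme's 10 planted core tokens and 40% from a 90-token shared filler
  vocabulary. The shared filler keeps the embedding geometry
  non-degenerate — fully disjoint theme vocabularies would make every
  projection trivially clustered and leave tie handling untested. The
  10-core/90-filler design also gives primitive extraction a sharp
  criterion: the cores are frequent and mutually coherent and must
  dominate the top 10.
* **Accounts and dates**: 20% of accounts get follower counts above 5000;
  years 2011–2017 are balanced so yearly stratified sampling is always
  feasible at the default sizes.
* **Determinism**: all randomness flows from the single config seed; the
  same config yields byte-identical corpora.

Defaults (4000 posts, 300 accounts, posts of 8–16 tokens) are large
enough for a ~250-token vocabulary with stable embeddings and a 1400-post
coded sample, and small enough that a full pipeline run takes seconds.

What the generator does **not** model: real linguistic style, post-length
distributions, segmentation errors, topic drift over time, user networks,
or any overlap between theme vocabularies beyond the shared filler.
Passing tests therefore demonstrate that the *machinery* is correct —
filters select exactly what they should, scores rank planted structure
correctly, statistics match their closed forms — not that the pipeline's
judgements on real social-media text would match human ones. Corpus
dependent published quantities (real-data classifier accuracy, human
kappas, printed map distances) are used as worked-example inputs, never
as reproduction targets.

## Numerical choices, in one place

* Proportion and weight validation tolerance: 1e-9.
* Percentage rounding: half-up, 2 decimals; sum check tolerance 0.05.
* Quartiles: type 7 (linear interpolation).
* Closeness: strict `<` against both thresholds.
* Primitive ties: lexicographic; degenerate min–max range normalizes to 1.
* t-SNE: perplexity 5, seed 42, 500 iterations, exact gradients.
* Skip-gram: single worker, internal RNG, vocabulary ordered by frequency
  then token so training is reproducible bit-for-bit.
* Embedding fallback: posts with no in-vocabulary token vectorize to the
  zero vector and are flagged.

## Problem sizes used by the tests

The unit suite runs on a 400-post corpus with 48-dim embeddings; the
pipeline tests use 600 posts and 24 dims; the acceptance suite runs the
full default conditions (4000 posts, 400 dims, window 10) including ten
independent generator/training seeds for primitive recovery. These sizes
are the package's own choice of a thorough-but-quick regression suite;
all of them are ordinary function arguments, so larger studies are a
configuration change.

## Known limitations

* The SF–SAI scores are a documented reconstruction (see above), not a
  verified numerical match to any external implementation.
* Exact t-SNE is O(n^2) per iteration; fine for primitive sets (tens of
  points), unsuitable for mapping whole vocabularies.
* The relevance classifier is only as good as its features; with mean
  embeddings, posts whose tokens are all out-of-vocabulary are
  indistinguishable (zero vectors).
* Selection operates on exact tokens; morphological variants of an
  attribute keyword do not match (by design, but a real deployment would
  want a segmenter-aware synonym table).
* One post, one theme code; mixed-cause posts are forced into a single
  category, mirroring the coding design whose distribution sums to the
  sample size.
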