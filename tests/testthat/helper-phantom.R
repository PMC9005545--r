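# Shared fixtures, built once per test session and cached.  All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# 64^3 synthetic atlas (test scale; 32^3 segment boxes)
test_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- make_atlas(64, seed = 1)
  .fixtures$atlas
}

# small in-memory cohort for cheap tests
test_cohort <- function(n = 6) {
  key <- paste0("cohort", n)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_cohort(test_atlas(), n, n, seed = 11)
  .fixtures[[key]]
}

# the 200-subject benchmark cohort (100 per class), preprocessed on the fast
# path; built once and shared between the end-to-end tests
test_benchmark <- function() {
  if (is.null(.fixtures$benchmark)) {
    atlas <- test_atlas()
    cohort <- make_cohort(atlas, 100, 100, seed = 20)
    pre <- preprocess_cohort(cohort, atlas, level = "landmark")
    .fixtures$benchmark <- list(cohort = cohort, stacks = pre$stacks,
                                records = pre$records)
  }
  .fixtures$benchmark
}

# masked RMSE between two volumes
masked_rmse <- function(a, b, mask) {
  m <- if (is_vol <- inherits(mask, "mci_volume")) mask$data > 0 else mask > 0
  av <- if (inherits(a, "mci_volume")) a$data else a
  bv <- if (inherits(b, "mci_volume")) b$data else b
  sqrt(mean((av[m] - bv[m])^2))
}

# random similarity transform within the generator's default ranges
random_similarity <- function(center, seed) {
  set.seed(seed)
  similarity9(rotation = runif(3, -5, 5), scale = runif(3, 0.94, 1.06),
              translation = runif(3, -5, 5), center = center)
}

# a tiny config for fast unit tests (not the benchmark architecture)
unit_config <- function(...) {
  extractor_config(blocks = c(1, 1), growth = 4, stem_channels = 6,
                   bottleneck_mult = 2, feature_dim = 8, input_size = 16,
                   decoder_base = 8, dropout = 0, epochs = 2,
                   batch_size = 4, seed = 42, ...)
}

# brute-force AUC oracle: over all (positive, negative) pairs, the fraction
# of concordant pairs with half credit for ties
auc_bruteforce <- function(scores, labels) {
  lab <- as.character(labels)
  pos <- scores[lab == "pMCI"]
  neg <- scores[lab == "sMCI"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
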