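# Shared lazily-computed objects: the packaged datasets, their fingerprints
# and preference pairs are reused across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, expr, .cache)
  get(key, .cache)
}

fixtures <- function() cached("fixtures", paper_fixtures())

fixture_fingerprints <- function() {
  cached("fps", {
    lapply(fixtures(), function(d) fingerprint_polymers(d$records$smiles))
  })
}

fixture_preferences <- function() {
  cached("prefs", {
    combine_preferences(mapply(build_preferences, fixtures(),
                               fixture_fingerprints(), SIMPLIFY = FALSE))
  })
}

fixture_model <- function() {
  cached("model", ranksvm_train(fixture_preferences(), C = 0.007))
}

# Pairs with uniformly random labels over Gaussian difference vectors: the
# null model for cross-validation calibration.
random_label_pairs <- function(n, dim = 300, seed = 1) {
  set.seed(seed)
  structure(list(
    Z = matrix(rnorm(n * dim), n, dim),
    t = sample(c(-1, 1), n, replace = TRUE),
    first = sprintf("a%d", seq_len(n)),
    second = sprintf("b%d", seq_len(n)),
    dataset_id = rep("null", n),
    n_tied = 0L,
    scheme_id = "synthetic"
  ), class = "preference_pairs")
}

# Brute-force preference enumeration used as the pair-count oracle.
brute_force_pair_count <- function(values) {
  n <- length(values)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (values[i] != values[j]) cnt <- cnt + 1L
    }
  }
  cnt
}
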