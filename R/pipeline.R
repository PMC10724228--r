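#' @name pipeline
#' @title End-to-end pipelines: unified ranking and factor analysis
#'
#' @description
#' `run_unified_ranking()` wires ingestion to ranking: fingerprints per
#' dataset, preference pairs, cross-validated selection of the trade-off C,
#' a final fit on all preferences at the selected C, and the unified ranking
#' of every polymer from every dataset. `run_factor_analysis()` takes the
#' trained model, counts the nine functional-group descriptors for the
#' distinct polymers, fits the regression tree on their (by default
#' min-max-normalized) scores and derives the three-category rule.
NULL

dataset_fingerprints <- function(dataset, scheme, hash_seed,
                                 embedding_table = NULL) {
  fp <- attr(dataset, "fingerprints")
  if (!is.null(fp)) return(fp)
  fingerprint_polymers(dataset$records$smiles, scheme = scheme,
                       embedding_table = embedding_table,
                       hash_seed = hash_seed)
}

#' Unified degradability ranking from several datasets
#'
#' @param datasets list of [degradation_dataset()] objects (values are only
#'   compared within each dataset). Datasets carrying a precomputed
#'   `fingerprints` attribute (e.g. from [generate_synth()]) use it.
#' @param scheme fingerprint scheme, see [fingerprint_polymers()].
#' @param grid candidate C values for cross-validation.
#' @param n_folds folds for [select_C()].
#' @param seed seed for the cross-validation shuffle.
#' @param normalization `"raw"` or `"minmax"` for the reported scores.
#' @param hash_seed hash seed of the default fingerprint scheme.
#' @param embedding_table optional embedding table for the
#'   `"embedding-table"` scheme.
#' @return list with `ranking` (a [unified_ranking()]), `model`
#'   (a `rank_model`), `cv` (the [select_C()] result), `pairs` (combined
#'   `preference_pairs`) and `polymers` (data.frame of everything ranked).
#' @export
run_unified_ranking <- function(datasets, scheme = "default-hashed",
                                grid = default_c_grid(), n_folds = 5L,
                                seed = 1L, normalization = "minmax",
                                hash_seed = 17L, embedding_table = NULL) {
  if (!length(datasets)) stop("need at least one dataset", call. = FALSE)
  if (inherits(datasets, "degradation_dataset")) datasets <- list(datasets)
  fps <- lapply(datasets, dataset_fingerprints, scheme = scheme,
                hash_seed = hash_seed, embedding_table = embedding_table)
  prefs <- combine_preferences(mapply(build_preferences, datasets, fps,
                                      SIMPLIFY = FALSE))
  cv <- select_C(prefs, grid = grid, n_folds = n_folds, seed = seed)
  model <- ranksvm_train(prefs, C = cv$C_best)
  X <- do.call(rbind, fps)
  attr(X, "scheme_id") <- attr(fps[[1]], "scheme_id")
  abbr <- unlist(lapply(datasets, function(d) d$records$abbreviation))
  ds_id <- unlist(lapply(datasets, function(d) rep(d$id, nrow(d$records))))
  smiles <- unlist(lapply(datasets, function(d) d$records$smiles))
  ranking <- unified_ranking(model, X, abbreviation = abbr,
                             dataset_id = ds_id,
                             normalization = normalization)
  list(ranking = ranking, model = model, cv = cv, pairs = prefs,
       polymers = data.frame(abbreviation = abbr, dataset_id = ds_id,
                             smiles = smiles, stringsAsFactors = FALSE),
       fingerprints = X)
}

#' Factor analysis of a trained ranking model
#'
#' @param datasets list of [degradation_dataset()]s whose polymers form the
#'   analysis set (polymers present in several datasets enter once).
#' @param model a trained `rank_model`.
#' @param max_leaves,min_leaf_size tree hyperparameters, see
#'   [fit_degradability_tree()].
#' @param normalize_scores fit the tree on min-max-normalized scores
#'   (default `TRUE`); raw scores otherwise.
#' @param hash_seed,embedding_table featurization configuration (must match
#'   the model's scheme).
#' @return list with `tree`, `categories` (a `category_rule`, or `NULL` when
#'   the tree has fewer than 3 leaves), `descriptors`, `scores` and
#'   `polymers` (abbreviation + smiles of the distinct analysis set).
#' @export
run_factor_analysis <- function(datasets, model, max_leaves = 10L,
                                min_leaf_size = 1L, normalize_scores = TRUE,
                                hash_seed = 17L, embedding_table = NULL) {
  if (inherits(datasets, "degradation_dataset")) datasets <- list(datasets)
  rec <- do.call(rbind, lapply(datasets, function(d) {
    d$records[, c("abbreviation", "smiles")]
  }))
  rec <- rec[!duplicated(rec$smiles), , drop = FALSE]
  scheme <- if (identical(model$scheme_id, "embedding-table")) {
    "embedding-table"
  } else {
    "default-hashed"
  }
  X <- fingerprint_polymers(rec$smiles, scheme = scheme,
                            embedding_table = embedding_table,
                            hash_seed = hash_seed)
  d <- rank_score(model, X)
  if (normalize_scores) {
    rng <- range(d)
    d <- if (diff(rng) == 0) rep(0.5, length(d)) else (d - rng[1]) / diff(rng)
  }
  desc <- count_descriptors(rec$smiles)
  tree <- fit_degradability_tree(desc, d, max_leaves = max_leaves,
                                 min_leaf_size = min_leaf_size)
  categories <- if (n_leaves(tree) >= 3) categorize_leaves(tree) else NULL
  list(tree = tree, categories = categories, descriptors = desc, scores = d,
       polymers = rec)
}
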