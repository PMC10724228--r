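#' @name rank_core
#' @title Pairwise learning-to-rank over degradability datasets
#'
#' @description
#' Each dataset is converted to pairwise preferences: for polymers i, j
#' measured in the same dataset, the pair carries label t = +1 if i is more
#' degradable, -1 otherwise; tied values produce no pair, and pairs are never
#' formed across datasets. A linear ranking SVM learns a weight vector w by
#' minimizing 0.5*||w||^2 + C * sum_i max(0, 1 - t_i w.(x_i1 - x_i2)) with no
#' intercept (difference vectors make one unidentifiable). The learned score
#' d = w.x is comparable across datasets and defines the unified ranking.
NULL

#' Default trade-off grid for cross-validated model selection
#'
#' Thirteen values spanning 1e-4 to 10.
#'
#' @return numeric vector of candidate C values.
#' @export
default_c_grid <- function() {
  c(1e-4, 3e-4, 1e-3, 3e-3, 7e-3, 1e-2, 3e-2, 7e-2, 1e-1, 3e-1, 1, 3, 10)
}

#' Build preference pairs from one dataset
#'
#' One pair per unordered polymer pair with distinct degradability values,
#' oriented as (row-earlier, row-later) with t = +1 iff the earlier row has
#' the larger value. Tied pairs are excluded and counted.
#'
#' @param dataset a [degradation_dataset()].
#' @param fingerprints numeric matrix, one row per record of `dataset`, in
#'   record order (e.g. from [fingerprint_polymers()]).
#' @return object of class `preference_pairs`: list with `Z` (matrix of
#'   difference vectors x1 - x2), `t` (labels), `first`/`second` (polymer
#'   ids), `dataset_id`, `n_tied`, `scheme_id`.
#' @export
build_preferences <- function(dataset, fingerprints) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  fingerprints <- as.matrix(fingerprints)
  n <- nrow(dataset$records)
  if (nrow(fingerprints) != n) {
    stop("fingerprints must have one row per dataset record", call. = FALSE)
  }
  if (any(!is.finite(fingerprints))) {
    stop("fingerprints contain non-finite values", call. = FALSE)
  }
  v <- dataset$records$value
  if (n < 2) {
    warning("dataset '", dataset$id, "' has fewer than 2 records: no pairs")
    idx <- cbind(integer(0), integer(0))
  } else {
    idx <- t(utils::combn(n, 2))
  }
  tied <- v[idx[, 1]] == v[idx[, 2]]
  idx_ok <- idx[!tied, , drop = FALSE]
  Z <- fingerprints[idx_ok[, 1], , drop = FALSE] -
       fingerprints[idx_ok[, 2], , drop = FALSE]
  t_lab <- ifelse(v[idx_ok[, 1]] > v[idx_ok[, 2]], 1, -1)
  structure(list(
    Z = Z,
    t = t_lab,
    first = dataset$records$id[idx_ok[, 1]],
    second = dataset$records$id[idx_ok[, 2]],
    dataset_id = rep(dataset$id, nrow(idx_ok)),
    n_tied = sum(tied),
    scheme_id = attr(fingerprints, "scheme_id")
  ), class = "preference_pairs")
}

#' Concatenate preference pairs from several datasets
#'
#' @param ... `preference_pairs` objects (or a single list of them).
#' @return a combined `preference_pairs` object.
#' @export
combine_preferences <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && !inherits(ps[[1]], "preference_pairs")) ps <- ps[[1]]
  stopifnot(all(vapply(ps, inherits, logical(1), "preference_pairs")))
  schemes <- unique(unlist(lapply(ps, `[[`, "scheme_id")))
  if (length(schemes) > 1) {
    stop("cannot combine preferences built under different fingerprint schemes",
         call. = FALSE)
  }
  structure(list(
    Z = do.call(rbind, lapply(ps, `[[`, "Z")),
    t = unlist(lapply(ps, `[[`, "t")),
    first = unlist(lapply(ps, `[[`, "first")),
    second = unlist(lapply(ps, `[[`, "second")),
    dataset_id = unlist(lapply(ps, `[[`, "dataset_id")),
    n_tied = sum(vapply(ps, `[[`, numeric(1), "n_tied")),
    scheme_id = if (length(schemes)) schemes else NULL
  ), class = "preference_pairs")
}

#' @export
print.preference_pairs <- function(x, ...) {
  cat(sprintf("preference_pairs: %d pairs from %s (%d tied pairs excluded)\n",
              length(x$t), paste(unique(x$dataset_id), collapse = ", "),
              x$n_tied))
  invisible(x)
}

#' Train the ranking SVM
#'
#' Solves the no-intercept soft-margin problem on preference difference
#' vectors by deterministic dual coordinate descent.
#'
#' @param pairs a `preference_pairs` object (see [build_preferences()]).
#' @param C positive trade-off between margin and slack.
#' @param tol dual projected-gradient tolerance.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @return object of class `rank_model`: list with weight vector `w`, `C`,
#'   `scheme_id` and `training_meta` (pair count, objective, convergence).
#' @export
ranksvm_train <- function(pairs, C, tol = 1e-6, max_sweeps = 100000L) {
  stopifnot(inherits(pairs, "preference_pairs"))
  if (length(pairs$t) < 1) stop("no preference pairs to train on", call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("C must be a positive real", call. = FALSE)
  if (any(!is.finite(pairs$Z))) {
    stop("non-finite fingerprint differences", call. = FALSE)
  }
  fit <- svm_dual_cd(pairs$Z, pairs$t, C, tol = tol,
                     max_sweeps = as.integer(max_sweeps))
  if (!fit$converged) {
    stop(sprintf(
      "ranking SVM did not converge in %d sweeps (max violation %.3g); %s",
      max_sweeps, fit$max_violation,
      "increase max_sweeps or loosen tol"), call. = FALSE)
  }
  structure(list(
    w = as.numeric(fit$w),
    C = C,
    scheme_id = pairs$scheme_id,
    training_meta = list(M = length(pairs$t),
                         n_tied_excluded = pairs$n_tied,
                         datasets = unique(pairs$dataset_id),
                         objective = fit$objective,
                         sweeps = fit$sweeps)
  ), class = "rank_model")
}

#' @export
print.rank_model <- function(x, ...) {
  cat(sprintf("rank_model: %d weights, C = %g, trained on %d pairs (%s)\n",
              length(x$w), x$C, x$training_meta$M,
              paste(x$training_meta$datasets, collapse = ", ")))
  invisible(x)
}

check_scheme <- function(model, x) {
  sx <- attr(x, "scheme_id")
  if (!is.null(sx) && !is.null(model$scheme_id) &&
      !identical(sx, model$scheme_id)) {
    stop("fingerprint scheme '", sx, "' does not match model scheme '",
         model$scheme_id, "'", call. = FALSE)
  }
}

#' Predicted pairwise preference
#'
#' y = w.(x1 - x2); sign(y) is the predicted preference. Antisymmetric in its
#' arguments, and equal to the difference of the two degradability scores.
#'
#' @param model a `rank_model`.
#' @param x1,x2 fingerprint vectors (or matrices of equal dimension) under
#'   the model's scheme.
#' @return signed real (or vector).
#' @export
predict_preference <- function(model, x1, x2) {
  stopifnot(inherits(model, "rank_model"))
  check_scheme(model, x1); check_scheme(model, x2)
  rank_score(model, x1) - rank_score(model, x2)
}

#' Degradability score d = w.x
#'
#' @param model a `rank_model`.
#' @param x fingerprint vector or matrix (rows = polymers).
#' @return numeric score(s).
#' @export
rank_score <- function(model, x) {
  stopifnot(inherits(model, "rank_model"))
  check_scheme(model, x)
  if (is.matrix(x)) as.numeric(x %*% model$w) else sum(x * model$w)
}

pair_fold_accuracy <- function(Ztr, ttr, Zte, tte, C) {
  # held-out sign accuracy is insensitive to the last digits of w: fold fits
  # use a looser dual tolerance than the final model fit
  fit <- svm_dual_cd(Ztr, ttr, C, tol = 1e-3, max_sweeps = 20000L)
  pred <- as.numeric(Zte %*% fit$w)
  mean(sign(pred) == tte)  # sign 0 counts as wrong
}

#' Select the trade-off C by k-fold cross-validation on preferences
#'
#' Pairs are shuffled with `seed` and split into `n_folds`; for each C the
#' model is refit on the training folds and scored by the fraction of
#' held-out pairs whose predicted sign matches the label. Ties in mean
#' accuracy resolve to the smaller C. Optionally folds can group by polymer
#' (a pair is held out only when both members are held out), which avoids
#' information sharing through common polymers at the cost of fewer, unevenly
#' sized evaluation pairs.
#'
#' @param pairs a `preference_pairs` object.
#' @param grid positive candidate values of C.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param group_by_polymer logical; default `FALSE` (fold on pairs).
#' @return list with `C_best`, `accuracy_by_C` (data.frame of C and mean
#'   held-out accuracy), `n_folds`, `seed`.
#' @export
select_C <- function(pairs, grid = default_c_grid(), n_folds = 5L, seed = 1L,
                     group_by_polymer = FALSE) {
  stopifnot(inherits(pairs, "preference_pairs"))
  if (length(grid) == 0) stop("empty C grid", call. = FALSE)
  if (any(!is.finite(grid) | grid <= 0)) {
    stop("C grid must contain positive reals", call. = FALSE)
  }
  M <- length(pairs$t)
  if (M < n_folds) stop("need at least n_folds pairs", call. = FALSE)
  if (group_by_polymer) {
    poly <- unique(c(pairs$first, pairs$second))
    pfold <- with_seed(seed,
                       sample(rep(seq_len(n_folds), length.out = length(poly))))
    names(pfold) <- poly
    fold_te <- lapply(seq_len(n_folds), function(k) {
      which(pfold[pairs$first] == k & pfold[pairs$second] == k)
    })
    fold_tr <- lapply(seq_len(n_folds), function(k) {
      which(pfold[pairs$first] != k & pfold[pairs$second] != k)
    })
  } else {
    fold <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = M)))
    fold_te <- lapply(seq_len(n_folds), function(k) which(fold == k))
    fold_tr <- lapply(seq_len(n_folds), function(k) which(fold != k))
  }
  acc <- vapply(grid, function(C) {
    fold_acc <- vapply(seq_len(n_folds), function(k) {
      te <- fold_te[[k]]; tr <- fold_tr[[k]]
      if (!length(te) || !length(tr)) return(NA_real_)
      pair_fold_accuracy(pairs$Z[tr, , drop = FALSE], pairs$t[tr],
                         pairs$Z[te, , drop = FALSE], pairs$t[te], C)
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-acc, grid)  # ties -> smaller C
  list(C_best = grid[ord[1]],
       accuracy_by_C = data.frame(C = grid, accuracy = acc),
       n_folds = n_folds, seed = seed,
       group_by_polymer = group_by_polymer)
}

#' Unified ranking of polymers by degradability score
#'
#' Scores every polymer with the trained model and sorts descending; ties are
#' broken by abbreviation (lexicographic). With `normalization = "minmax"`
#' the affine map sending the reference scores (by default the ranked set
#' itself) to \[0, 1\] is applied; queries outside the reference range may
#' fall outside \[0, 1\]. Affine normalization never changes the order.
#'
#' @param model a `rank_model`.
#' @param fingerprints matrix of fingerprints under the model's scheme.
#' @param abbreviation,dataset_id per-row labels (recycled if length 1).
#' @param normalization `"raw"` or `"minmax"`.
#' @param norm_reference optional fingerprint matrix whose scores define the
#'   min-max map (e.g. the training set when ranking queries).
#' @return object of class `unified_ranking`: data.frame with columns `rank`,
#'   `abbreviation`, `d_raw`, `d_norm`, `dataset_id`; attributes record the
#'   normalization and its min/max.
#' @export
unified_ranking <- function(model, fingerprints, abbreviation,
                            dataset_id = "query",
                            normalization = c("raw", "minmax"),
                            norm_reference = NULL) {
  normalization <- match.arg(normalization)
  fingerprints <- as.matrix(fingerprints)
  d <- rank_score(model, fingerprints)
  n <- length(d)
  abbreviation <- rep_len(as.character(abbreviation), n)
  dataset_id <- rep_len(as.character(dataset_id), n)
  ref <- if (is.null(norm_reference)) d else rank_score(model, as.matrix(norm_reference))
  rng <- range(ref)
  d_norm <- if (normalization == "minmax") {
    if (diff(rng) == 0) rep(0.5, n) else (d - rng[1]) / diff(rng)
  } else {
    d
  }
  ord <- order(-d, abbreviation)
  out <- data.frame(rank = seq_len(n),
                    abbreviation = abbreviation[ord],
                    d_raw = d[ord],
                    d_norm = d_norm[ord],
                    dataset_id = dataset_id[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("unified_ranking", "data.frame"),
            normalization = normalization,
            norm_min = rng[1], norm_max = rng[2])
}

#' Save / load a ranking model as JSON
#'
#' @param model a `rank_model`.
#' @param path file path.
#' @return `path` (write) or a `rank_model` (read).
#' @export
write_rank_model <- function(model, path) {
  stopifnot(inherits(model, "rank_model"))
  doc <- list(format = "polyrank/rank_model", version = 1L,
              scheme_id = model$scheme_id, C = model$C, w = model$w,
              training_meta = model$training_meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rank_model
#' @param path file path.
#' @export
read_rank_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "polyrank/rank_model")) {
    stop("not a polyrank model file: ", path, call. = FALSE)
  }
  structure(list(w = as.numeric(doc$w), C = doc$C,
                 scheme_id = doc$scheme_id,
                 training_meta = as.list(doc$training_meta)),
            class = "rank_model")
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
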