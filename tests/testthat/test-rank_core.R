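test_that("preference construction matches brute-force enumeration", {
  fx <- fixtures()
  fps <- fixture_fingerprints()
  expected <- vapply(fx, function(d) brute_force_pair_count(d$records$value),
                     integer(1))
  got <- mapply(function(d, f) length(build_preferences(d, f)$t), fx, fps)
  expect_equal(unname(got), unname(expected))
  # the literature table has one tied pair (two polymers at 100 %/day)
  lit_pairs <- build_preferences(fx$literature, fps$literature)
  expect_equal(lit_pairs$n_tied, 1L)
})

test_that("pair orientation follows the measured values", {
  lit <- fixtures()$literature
  fps <- fixture_fingerprints()$literature
  pairs <- build_preferences(lit, fps)
  i <- match("literature:PET", pairs$first)
  # PET (0.0003, row 1) vs PLA (0.00033, row 2): earlier row less degradable
  expect_equal(pairs$second[i], "literature:PLA")
  expect_equal(pairs$t[i], -1)
})

test_that("degenerate datasets yield no pairs", {
  one <- degradation_dataset(data.frame(smiles = "*CC*", value = 1), "one")
  fp <- fingerprint_polymers(one$records$smiles)
  expect_warning(p <- build_preferences(one, fp), "fewer than 2")
  expect_equal(length(p$t), 0L)
})

test_that("training solves the hinge problem: separable and shrinkage limits", {
  syn <- generate_synth(synth_config(n_polymers = 12, n_datasets = 1,
                                     noise_sd = 0, seed = 3))
  ds <- syn$datasets[[1]]
  pairs <- build_preferences(ds, attr(ds, "fingerprints"))
  m_big <- ranksvm_train(pairs, C = 100)
  acc <- mean(sign(pairs$Z %*% m_big$w) == pairs$t)
  expect_equal(acc, 1.0)
  # C -> 0+ shrinks w to zero
  m_small <- ranksvm_train(pairs, C = 1e-8)
  expect_lt(sqrt(sum(m_small$w^2)), 1e-4)
})

test_that("training matches a generic no-intercept soft-margin classifier", {
  skip_if_not_installed("e1071")
  syn <- generate_synth(synth_config(n_polymers = 10, n_datasets = 1,
                                     noise_sd = 0.1, seed = 42))
  ds <- syn$datasets[[1]]
  X <- attr(ds, "fingerprints")
  pairs <- build_preferences(ds, X)
  for (C in c(0.01, 0.1, 1)) {
    m <- ranksvm_train(pairs, C)
    # oracle: soft-margin linear SVM on the symmetrized difference vectors;
    # symmetry forces the intercept to zero, and each original pair appears
    # twice, so the equivalent cost is C/2
    Zs <- rbind(pairs$Z, -pairs$Z)
    ys <- factor(c(pairs$t, -pairs$t))
    sv <- e1071::svm(Zs, ys, kernel = "linear", cost = C / 2, scale = FALSE)
    w_or <- as.numeric(t(sv$coefs) %*% sv$SV)
    if (mean(sign(pairs$Z %*% w_or) == pairs$t) < 0.5) w_or <- -w_or
    expect_lt(abs(sv$rho), 1e-3)
    expect_identical(order(-rank_score(m, X)),
                     order(-as.numeric(X %*% w_or)))
  }
})

test_that("prediction is antisymmetric and equals the score difference", {
  model <- fixture_model()
  set.seed(7)
  x1 <- rnorm(300); x2 <- rnorm(300)
  expect_equal(predict_preference(model, x1, x2),
               -predict_preference(model, x2, x1))
  expect_equal(predict_preference(model, x1, x1), 0)
  expect_equal(predict_preference(model, x1, x2),
               rank_score(model, x1) - rank_score(model, x2))
})

test_that("ranking is invariant to fingerprint translation and positive scaling", {
  syn <- generate_synth(synth_config(n_polymers = 15, n_datasets = 2,
                                     noise_sd = 0.05, seed = 5))
  fps <- lapply(syn$datasets, attr, "fingerprints")
  pairs0 <- combine_preferences(mapply(build_preferences, syn$datasets, fps,
                                       SIMPLIFY = FALSE))
  shift <- matrix(rep(rnorm(300), each = nrow(fps[[1]])), ncol = 300)
  fps_shift <- lapply(fps, function(f) {
    out <- f + matrix(rep(shift[1, ], each = nrow(f)), ncol = 300)
    attr(out, "scheme_id") <- attr(f, "scheme_id")
    out
  })
  pairs1 <- combine_preferences(mapply(build_preferences, syn$datasets,
                                       fps_shift, SIMPLIFY = FALSE))
  # difference vectors are unchanged by translation, hence so is training
  expect_equal(pairs0$Z, pairs1$Z)
  m <- ranksvm_train(pairs0, C = 0.1)
  X <- do.call(rbind, fps)
  d <- rank_score(m, X)
  expect_equal(rank_score(m, 3 * X), 3 * d)
  expect_equal(order(-rank_score(m, 3 * X)), order(-d))
})

test_that("cross-validation selects C deterministically with documented ties", {
  pairs <- random_label_pairs(60, seed = 2)
  one <- select_C(pairs, grid = 0.05, seed = 1)
  expect_equal(one$C_best, 0.05)
  expect_error(select_C(pairs, grid = numeric(0)), "empty")
  cv1 <- select_C(pairs, grid = c(0.01, 0.1), seed = 9)
  cv2 <- select_C(pairs, grid = c(0.01, 0.1), seed = 9)
  expect_identical(cv1$accuracy_by_C, cv2$accuracy_by_C)
  # grouped splitter runs and returns the full curve too
  cvg <- select_C(pairs, grid = c(0.01, 0.1), seed = 9,
                  group_by_polymer = TRUE)
  expect_equal(nrow(cvg$accuracy_by_C), 2L)
})

test_that("fully consistent noiseless preferences cross-validate accurately", {
  syn <- generate_synth(synth_config(n_polymers = 25, n_datasets = 1,
                                     noise_sd = 0, seed = 11))
  ds <- syn$datasets[[1]]
  pairs <- build_preferences(ds, attr(ds, "fingerprints"))
  cv <- select_C(pairs, grid = c(0.1, 1, 10), seed = 1)
  expect_gte(max(cv$accuracy_by_C$accuracy), 0.95)
})

test_that("unified ranking sorts by score with recorded normalization", {
  model <- fixture_model()
  fps <- fixture_fingerprints()
  X <- do.call(rbind, fps)
  abbr <- unlist(lapply(fixtures(), function(d) d$records$abbreviation))
  dsid <- unlist(lapply(fixtures(), function(d) rep(d$id, nrow(d$records))))
  r <- unified_ranking(model, X, abbr, dsid, normalization = "minmax")
  expect_equal(nrow(r), 39L)
  expect_true(!is.unsorted(rev(r$d_raw)))
  expect_equal(range(r$d_norm), c(0, 1))
  # affine normalization preserves the order
  expect_equal(order(-r$d_norm), order(-r$d_raw))
})

test_that("models round-trip through JSON", {
  model <- fixture_model()
  f <- tempfile(fileext = ".json")
  write_rank_model(model, f)
  back <- read_rank_model(f)
  expect_equal(back$w, model$w)
  expect_equal(back$C, model$C)
  expect_equal(back$scheme_id, model$scheme_id)
  x <- fixture_fingerprints()$exp1
  expect_equal(rank_score(back, x), rank_score(model, x))
})

test_that("scheme mismatches are refused", {
  model <- fixture_model()
  x <- matrix(rnorm(300), 1)
  attr(x, "scheme_id") <- "something-else"
  expect_error(rank_score(model, x), "scheme")
})
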