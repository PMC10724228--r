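# brute-force oracle: best single split of a node over all (feature,
# integer threshold) pairs, first-best under the fixed feature order
oracle_best_split <- function(X, y) {
  sse <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    for (thr in vals[-length(vals)]) {
      left <- X[, f] <= thr
      gain <- sse(y) - sse(y[left]) - sse(y[!left])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = colnames(X)[f], threshold = thr, gain = gain)
      }
    }
  }
  best
}

synthetic_descriptor_table <- function(n, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(sample(0:4, n * 9, replace = TRUE), n, 9))
  names(X) <- descriptor_names()
  X
}

test_that("constant scores give a single-leaf tree with that mean", {
  X <- synthetic_descriptor_table(12, seed = 1)
  tr <- fit_degradability_tree(X, rep(0.7, 12))
  expect_equal(n_leaves(tr), 1L)
  expect_equal(tr$nodes[[1]]$d_bar, 0.7)
})

test_that("an ester-determined score is recovered split by split", {
  X <- synthetic_descriptor_table(40, seed = 2)
  y <- as.numeric(X$ester)
  tr <- fit_degradability_tree(X, y, max_leaves = 10)
  orc <- oracle_best_split(as.matrix(X), y)
  expect_equal(tr$nodes[[1]]$feature, orc$feature)
  expect_equal(tr$nodes[[1]]$threshold, orc$threshold)
  expect_equal(tr$nodes[[1]]$feature, "ester")
  # with 5 distinct ester counts the tree reaches pure leaves
  expect_lte(n_leaves(tr), 10L)
  expect_equal(unname(predict(tr, X)), y)
  expect_equal(sort(split_features(tr)), "ester")
})

test_that("leaf means conserve the global mean and R2 is monotone in leaves", {
  X <- synthetic_descriptor_table(30, seed = 3)
  set.seed(3)
  y <- X$ester - 0.5 * X$benzene_ring + rnorm(30, sd = 0.2)
  r2 <- vapply(c(2, 4, 6, 8, 10), function(k) {
    tr <- fit_degradability_tree(X, y, max_leaves = k)
    leaves <- Filter(function(nd) nd$is_leaf, tr$nodes)
    wmean <- sum(vapply(leaves, function(l) length(l$members) * l$d_bar,
                        numeric(1))) / tr$n
    expect_equal(wmean, mean(y))
    tr$r_squared
  }, numeric(1))
  expect_true(!is.unsorted(r2))
})

test_that("refitting with permuted rows yields the identical tree", {
  X <- synthetic_descriptor_table(25, seed = 4)
  set.seed(4)
  y <- X$alkyl_carbon + rnorm(25, sd = 0.1)
  tr1 <- fit_degradability_tree(X, y, max_leaves = 6)
  set.seed(99)
  perm <- sample(25)
  tr2 <- fit_degradability_tree(X[perm, ], y[perm], max_leaves = 6)
  strip <- function(tr) lapply(tr$nodes, function(nd) {
    nd$members <- sort(nd$members)
    nd
  })
  expect_equal(format(tr1), format(tr2))
  expect_equal(predict(tr1, X), predict(tr2, X))
})

test_that("largest-gaps categorization returns the documented boundaries", {
  X <- data.frame(ester = 1:3, alkyl_carbon = 0L, hydroxyl = 0L, ether = 0L,
                  benzene_ring = 0L, amide = 0L, carbonate = 0L,
                  heteroatom = 0L, urethane = 0L)
  tr <- fit_degradability_tree(X, c(0.1, 0.5, 0.9), max_leaves = 3)
  rule <- categorize_leaves(tr)
  expect_equal(attr(rule, "boundaries"), c(0.3, 0.7))
  expect_equal(sort(rule$category),
               c("degradable", "middle", "undegradable"))
})

test_that("largest-gaps grouping matches the minimum within-group variance cut", {
  # ten leaf means drawn from three well-separated clusters
  means <- c(0.05, 0.08, 0.12, 0.45, 0.50, 0.52, 0.55, 0.88, 0.92, 0.97)
  X <- data.frame(ester = 1:10, alkyl_carbon = 0L, hydroxyl = 0L, ether = 0L,
                  benzene_ring = 0L, amide = 0L, carbonate = 0L,
                  heteroatom = 0L, urethane = 0L)
  tr <- fit_degradability_tree(X, means, max_leaves = 10)
  expect_equal(n_leaves(tr), 10L)
  rule <- categorize_leaves(tr)
  got <- rule$category[order(rule$d_bar)]
  expect_equal(got, rep(c("undegradable", "middle", "degradable"),
                        c(3, 4, 3)))
  # oracle: enumerate all 2-cut partitions of the sorted means and verify the
  # largest-gaps choice minimizes within-group sum of squares
  s <- sort(means)
  wss <- function(groups) sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  best <- Inf
  for (i in 1:8) for (j in (i + 1):9) {
    best <- min(best, wss(list(s[1:i], s[(i + 1):j], s[(j + 1):10])))
  }
  chosen <- wss(split(s, cut(s, c(-Inf, attr(rule, "boundaries"), Inf))))
  expect_equal(chosen, best)
})

test_that("decision paths are reported node by node", {
  X <- synthetic_descriptor_table(40, seed = 2)
  y <- as.numeric(X$ester)
  tr <- fit_degradability_tree(X, y, max_leaves = 10)
  ex <- explain_polymer(tr, X[which(X$ester == 3)[1], ])
  expect_true(all(vapply(ex$path, `[[`, character(1), "feature") == "ester"))
  expect_equal(ex$d_bar, 3)
  depth <- max(vapply(tr$nodes, `[[`, integer(1), "depth"))
  expect_lte(length(ex$path), depth)
  # single-leaf tree: empty path
  tr1 <- fit_degradability_tree(X[1:5, ], rep(1, 5))
  ex1 <- explain_polymer(tr1, X[1, ])
  expect_equal(length(ex1$path), 0L)
  expect_equal(ex1$d_bar, 1)
})

test_that("fewer than three leaves cannot be categorized", {
  X <- synthetic_descriptor_table(10, seed = 6)
  tr <- fit_degradability_tree(X, rep(1, 10))
  expect_error(categorize_leaves(tr), ">= 3 leaves")
})
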