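#' @name interpret
#' @title Regression-tree factor analysis of degradability scores
#'
#' @description
#' To expose which functional groups drive the learned degradability score, a
#' variance-reduction (CART-style) regression tree is fit with the nine
#' functional-group counts as inputs and the score d as output. Growth is
#' best-first: at each step the leaf whose best split removes the most
#' residual sum of squares is split, until `max_leaves` is reached or no
#' split helps. Thresholds are integers (the descriptors are counts) of the
#' form "<= t vs > t". All tie-breaks are fixed (feature order as given, then
#' smaller threshold, then older leaf), so refitting permuted rows yields the
#' identical tree.
NULL

node_sse <- function(y) sum((y - mean(y))^2)

# Best split of one node: returns NULL or list(feature, threshold, gain, ...)
best_split <- function(X, y, members, min_leaf_size) {
  yv <- y[members]
  if (length(members) < 2 * min_leaf_size || length(unique(yv)) == 1L) {
    return(NULL)
  }
  parent_sse <- node_sse(yv)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xv <- X[members, f]
    vals <- sort(unique(xv))
    if (length(vals) < 2) next
    for (thr in vals[-length(vals)]) {
      left <- members[xv <= thr]
      right <- members[xv > thr]
      if (length(left) < min_leaf_size || length(right) < min_leaf_size) next
      gain <- parent_sse - node_sse(y[left]) - node_sse(y[right])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = f, threshold = thr, gain = gain,
                     left = left, right = right)
      }
      # strict ">" above keeps the earliest (feature, threshold) on ties
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

#' Fit the regression tree on descriptor counts
#'
#' @param descriptors data.frame or matrix of non-negative integer counts
#'   (typically from [count_descriptors()]); column order fixes the split
#'   tie-break order.
#' @param scores numeric degradability scores, aligned with the rows.
#' @param max_leaves growth stops at this many leaves (default 10).
#' @param min_leaf_size minimum polymers per leaf (default 1).
#' @return object of class `degradability_tree`: list of nodes (internal
#'   nodes carry `feature`/`threshold`/children; leaves carry `members` and
#'   mean score `d_bar`), plus feature names and fit statistics.
#' @export
fit_degradability_tree <- function(descriptors, scores, max_leaves = 10L,
                                   min_leaf_size = 1L) {
  X <- as.matrix(descriptors)
  y <- as.numeric(scores)
  if (nrow(X) != length(y)) stop("descriptors and scores misaligned", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 polymers", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite inputs", call. = FALSE)
  }
  features <- colnames(X)
  if (is.null(features)) features <- paste0("x", seq_len(ncol(X)))

  nodes <- list(list(id = 1L, depth = 0L, members = seq_len(nrow(X)),
                     d_bar = mean(y), sse = node_sse(y), is_leaf = TRUE,
                     feature = NA_character_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_))
  n_leaves <- 1L
  repeat {
    if (n_leaves >= max_leaves) break
    # best candidate split per current leaf; pick the largest gain,
    # ties resolved toward the older (smaller-id) leaf
    cand <- NULL
    for (nd in nodes) {
      if (!nd$is_leaf) next
      sp <- best_split(X, y, nd$members, min_leaf_size)
      if (is.null(sp)) next
      if (is.null(cand) || sp$gain > cand$gain + 1e-12) {
        cand <- c(sp, list(node = nd$id))
      }
    }
    if (is.null(cand)) break
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    parent <- nodes[[cand$node]]
    nodes[[cand$node]]$is_leaf <- FALSE
    nodes[[cand$node]]$feature <- features[cand$feature]
    nodes[[cand$node]]$threshold <- cand$threshold
    nodes[[cand$node]]$left <- lid
    nodes[[cand$node]]$right <- rid
    nodes[[lid]] <- list(id = lid, depth = parent$depth + 1L,
                         members = cand$left, d_bar = mean(y[cand$left]),
                         sse = node_sse(y[cand$left]), is_leaf = TRUE,
                         feature = NA_character_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    nodes[[rid]] <- list(id = rid, depth = parent$depth + 1L,
                         members = cand$right, d_bar = mean(y[cand$right]),
                         sse = node_sse(y[cand$right]), is_leaf = TRUE,
                         feature = NA_character_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    n_leaves <- n_leaves + 1L
  }
  if (n_leaves == 1L && length(unique(y)) > 1L) {
    warning("no informative split found: returning a single-leaf tree")
  }
  leaf_sse <- sum(vapply(nodes, function(nd) if (nd$is_leaf) nd$sse else 0,
                         numeric(1)))
  tot <- node_sse(y)
  structure(list(nodes = nodes, features = features, n = nrow(X),
                 scores = y,
                 r_squared = if (tot > 0) 1 - leaf_sse / tot else 1,
                 max_leaves = max_leaves, min_leaf_size = min_leaf_size),
            class = "degradability_tree")
}

tree_leaves <- function(tree) {
  Filter(function(nd) nd$is_leaf, tree$nodes)
}

#' Number of leaves of a fitted tree
#' @param tree a `degradability_tree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) length(tree_leaves(tree))

#' Features used for splitting
#' @param tree a `degradability_tree`.
#' @return character vector of distinct split features.
#' @export
split_features <- function(tree) {
  unique(stats::na.omit(vapply(tree$nodes, `[[`, character(1), "feature")))
}

route <- function(tree, x) {
  id <- 1L
  path <- list()
  repeat {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) return(list(leaf = nd, path = path))
    go_left <- x[[nd$feature]] <= nd$threshold
    path[[length(path) + 1L]] <- list(feature = nd$feature,
                                      threshold = nd$threshold,
                                      branch = if (go_left) "<=" else ">")
    id <- if (go_left) nd$left else nd$right
  }
}

#' Predict leaf mean scores
#' @param object a `degradability_tree`.
#' @param newdata data.frame/matrix of descriptor counts with the training
#'   feature columns.
#' @param ... unused.
#' @return numeric vector of leaf means d-bar.
#' @export
predict.degradability_tree <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  vapply(seq_len(nrow(nd)), function(i) route(object, nd[i, ])$leaf$d_bar,
         numeric(1))
}

#' Decision path of one polymer through the tree
#'
#' @param tree a `degradability_tree`.
#' @param descriptors one-row data.frame (or named vector) of counts.
#' @param categories optional [categorize_leaves()] result for a category
#'   label on the terminal leaf.
#' @return list with `path` (ordered feature/threshold/branch steps), `d_bar`
#'   and `category` (NA without `categories`).
#' @export
explain_polymer <- function(tree, descriptors, categories = NULL) {
  stopifnot(inherits(tree, "degradability_tree"))
  x <- as.data.frame(as.list(descriptors))
  r <- route(tree, x[1, ])
  cat_label <- NA_character_
  if (!is.null(categories)) {
    cat_label <- categories$category[match(r$leaf$id, categories$leaf_id)]
  }
  list(path = r$path, leaf_id = r$leaf$id, d_bar = r$leaf$d_bar,
       category = cat_label)
}

#' Group tree leaves into three degradability categories
#'
#' Leaves are sorted by mean score d-bar; the two largest gaps between
#' consecutive means cut the sequence into "undegradable", "middle" and
#' "degradable" groups. Boundaries are reported as gap midpoints. Among the
#' canonical single-linkage style 2-cut partitions, cutting the two widest
#' gaps minimizes within-group spread.
#'
#' @param tree a `degradability_tree` with at least 3 leaves.
#' @param method only `"largest-gaps"` is implemented.
#' @return object of class `category_rule`: data.frame (`leaf_id`, `d_bar`,
#'   `category`) with attribute `boundaries` (two increasing cut points).
#' @export
categorize_leaves <- function(tree, method = "largest-gaps") {
  method <- match.arg(method, "largest-gaps")
  leaves <- tree_leaves(tree)
  if (length(leaves) < 3) {
    stop("need >= 3 leaves for three categories; refit with more leaves or ",
         "fall back to one/two categories manually", call. = FALSE)
  }
  d_bar <- vapply(leaves, `[[`, numeric(1), "d_bar")
  ids <- vapply(leaves, `[[`, integer(1), "id")
  ord <- order(d_bar, ids)
  d_sorted <- d_bar[ord]
  gaps <- diff(d_sorted)
  cut_idx <- sort(order(-gaps, seq_along(gaps))[1:2])  # ties -> lower gap
  boundaries <- (d_sorted[cut_idx] + d_sorted[cut_idx + 1]) / 2
  grp <- cut(d_bar, breaks = c(-Inf, boundaries, Inf),
             labels = c("undegradable", "middle", "degradable"))
  out <- data.frame(leaf_id = ids, d_bar = d_bar,
                    category = as.character(grp), stringsAsFactors = FALSE)
  structure(out, class = c("category_rule", "data.frame"),
            boundaries = boundaries, method = method)
}

#' @export
format.degradability_tree <- function(x, ...) {
  lines <- character(0)
  walk <- function(id, indent, label) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$is_leaf) {
      lines <<- c(lines, sprintf("%s%sleaf #%d: n = %d, d_bar = %.4f",
                                 pad, label, nd$id, length(nd$members),
                                 nd$d_bar))
    } else {
      lines <<- c(lines, sprintf("%s%s%s <= %g ?", pad, label, nd$feature,
                                 nd$threshold))
      walk(nd$left, indent + 1L, "yes: ")
      walk(nd$right, indent + 1L, "no:  ")
    }
  }
  walk(1L, 0L, "")
  paste(lines, collapse = "\n")
}

#' @export
print.degradability_tree <- function(x, ...) {
  cat(sprintf("degradability_tree: %d leaves, n = %d, R^2 = %.3f\n",
              n_leaves(x), x$n, x$r_squared))
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize a tree as a nested JSON document
#'
#' @param tree a `degradability_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  to_list <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$is_leaf) {
      list(leaf = TRUE, id = nd$id, n = length(nd$members), d_bar = nd$d_bar)
    } else {
      list(leaf = FALSE, id = nd$id, feature = nd$feature,
           threshold = nd$threshold,
           left = to_list(nd$left), right = to_list(nd$right))
    }
  }
  doc <- list(format = "polyrank/tree", version = 1L,
              features = tree$features, r_squared = tree$r_squared,
              root = to_list(1L))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
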