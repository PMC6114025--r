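# Minimal CART + bagging ensemble for binary classification, grown on Gini
# impurity with per-node random feature subsets (mtry) and out-of-bag error.
# Implemented in-package because no tree package is available offline; data
# sizes here (n tens, p tens) keep plain R recursion cheap.

gini <- function(p) 2 * p * (1 - p)

best_split <- function(X, y, idx, mtry) {
  n <- length(idx)
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL
  parent_imp <- gini(mean(y[idx]))
  for (j in feats) {
    xs <- X[idx, j]
    if (anyNA(xs)) next
    ord <- order(xs)
    xo <- xs[ord]; yo <- y[idx][ord]
    distinct <- which(diff(xo) > 0)
    if (!length(distinct)) next
    cum1 <- cumsum(yo)
    tot1 <- cum1[n]
    nl <- distinct
    pl <- cum1[distinct] / nl
    pr <- (tot1 - cum1[distinct]) / (n - nl)
    dec <- parent_imp - (nl * gini(pl) + (n - nl) * gini(pr)) / n
    k <- which.max(dec)
    if (dec[k] > 1e-12 && (is.null(best) || dec[k] > best$dec)) {
      best <- list(var = j, split = (xo[distinct[k]] + xo[distinct[k] + 1]) / 2,
                   dec = dec[k])
    }
  }
  best
}

grow_tree <- function(X, y, mtry, min_node = 2L) {
  nodes <- new.env()
  nodes$tab <- list()
  recurse <- function(idx) {
    id <- length(nodes$tab) + 1L
    nodes$tab[[id]] <- list()  # reserve slot
    p1 <- mean(y[idx])
    sp <- NULL
    if (length(idx) >= min_node && p1 > 0 && p1 < 1) {
      sp <- best_split(X, y, idx, mtry)
    }
    if (is.null(sp)) {
      nodes$tab[[id]] <- list(var = NA_integer_, split = NA_real_,
                              left = NA_integer_, right = NA_integer_,
                              prob = p1)
      return(id)
    }
    go_left <- X[idx, sp$var] <= sp$split
    left_id <- recurse(idx[go_left])
    right_id <- recurse(idx[!go_left])
    nodes$tab[[id]] <- list(var = sp$var, split = sp$split,
                            left = left_id, right = right_id, prob = p1)
    id
  }
  recurse(seq_along(y))
  nodes$tab
}

predict_tree <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      nd <- tree[[id]]
      if (is.na(nd$var)) return(nd$prob)
      v <- X[i, nd$var]
      if (is.na(v)) return(nd$prob)
      id <- if (v <= nd$split) nd$left else nd$right
    }
  }, numeric(1))
}

#' Bagged classification tree ensemble with out-of-bag error
#'
#' Grows `n_trees` CART trees (Gini impurity, `mtry` random candidate
#' features per node, grown to purity or `min_node`) on bootstrap resamples
#' and estimates generalization error from out-of-bag majority votes.
#'
#' @param X numeric predictor matrix.
#' @param y logical or 0/1 case indicator.
#' @param n_trees ensemble size; out-of-bag votes stabilize above ~50 trees.
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param min_node minimum node size eligible for splitting.
#' @param seed integer RNG seed.
#' @return List with `trees`, `oob_error` (percent), `oob_prob` (per-sample
#'   out-of-bag case vote fraction), `mtry`, `n_trees`, `seed`.
#' @export
bagged_forest <- function(X, y, n_trees = 500L, mtry = NULL,
                          min_node = 2L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("single-class data", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  n <- nrow(X)
  votes_case <- votes_tot <- numeric(n)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    tree <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry, min_node)
    trees[[b]] <- tree
    if (length(oob)) {
      pr <- predict_tree(tree, X[oob, , drop = FALSE])
      votes_case[oob] <- votes_case[oob] + as.numeric(pr >= 0.5)
      votes_tot[oob] <- votes_tot[oob] + 1
    }
  }
  covered <- votes_tot > 0
  oob_prob <- ifelse(covered, votes_case / pmax(votes_tot, 1), NA_real_)
  oob_call <- oob_prob >= 0.5
  oob_error <- 100 * mean(oob_call[covered] != (y[covered] == 1))
  list(trees = trees, oob_error = oob_error, oob_prob = oob_prob,
       mtry = mtry, n_trees = n_trees, seed = seed)
}

predict_forest <- function(forest, X, type = c("prob", "class")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  votes <- matrix(0, nrow(X), length(forest$trees))
  for (b in seq_along(forest$trees)) {
    votes[, b] <- as.numeric(predict_tree(forest$trees[[b]], X) >= 0.5)
  }
  prob <- rowMeans(votes)
  if (type == "prob") prob else as.numeric(prob >= 0.5)
}
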