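# Real-valued AdaBoost (SAMME.R) importance-based feature ranking.
#
# Each round fits a depth-limited classification tree to the current sample
# weights (weighted Gini splits), converts its leaf class-probability
# estimates into the SAMME.R weight update, and credits the weighted impurity
# decrease of every split to its feature. Scores are the per-round impurity
# decreases averaged across rounds and normalized to sum to one.

.PROB_CLIP <- 1e-9

# Grow a weighted Gini classification tree (node list) on rows `innode`.
# Returns list of nodes; leaf nodes carry the weighted positive-class
# probability. `imp` (an environment) accumulates impurity decrease by feature.
.gini_tree <- function(X, ps, w, y, innode, depth, min_leaf, imp) {
  node_prob <- function(mask) {
    W <- sum(w[mask])
    if (W <= 0) 0.5 else sum(w[mask & y == 1L]) / W
  }
  build <- function(mask, d) {
    if (d >= depth || sum(mask) < 2 * min_leaf)
      return(list(leaf = TRUE, prob = node_prob(mask)))
    sp <- cpp_gini_scan(ps$sorted, ps$ord, mask, w, y, min_leaf)
    if (sp$feature == 0L)
      return(list(leaf = TRUE, prob = node_prob(mask)))
    imp$dec[sp$feature] <- imp$dec[sp$feature] + sp$decrease
    left <- mask & (X[, sp$feature] <= sp$threshold)
    right <- mask & !(X[, sp$feature] <= sp$threshold)
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = build(left, d + 1L), right = build(right, d + 1L))
  }
  build(innode, 0L)
}

.tree_prob <- function(tree, X) {
  p <- numeric(nrow(X))
  assign_node <- function(node, mask) {
    if (node$leaf) {
      p[mask] <<- node$prob
    } else {
      go_left <- X[, node$feature] <= node$threshold
      assign_node(node$left, mask & go_left)
      assign_node(node$right, mask & !go_left)
    }
  }
  assign_node(tree, rep(TRUE, nrow(X)))
  p
}

#' Fit SAMME.R feature-importance ranking
#'
#' Boosts depth-limited classification trees with the real-valued (SAMME.R)
#' update: per round, leaf class-probability estimates (clipped away from 0/1)
#' reweight every sample by `exp(-0.5 * (log p_y - log p_other))`, and the
#' weighted Gini impurity decrease of each split is credited to its feature.
#' The final score per feature is the impurity decrease averaged over rounds,
#' normalized to sum to 1. Deterministic given the inputs (the seed is recorded
#' in the metadata; the fit itself uses no randomness).
#'
#' @param X numeric feature matrix (rows = samples); `NA` entries are
#'   mean-imputed (columns that are all-`NA` become 0), with a message.
#' @param y binary labels (0/1, logical, or `"positive"`/`"negative"`).
#' @param rounds boosting rounds (default 50).
#' @param depth base-tree depth (default 1: stumps).
#' @param seed recorded for provenance.
#' @param min_leaf minimum samples per leaf.
#' @return An `importance_ranking`: list with `scores` (length = ncol(X),
#'   sums to 1 when any score is positive), `ranking` (feature indices by
#'   descending score, ties broken by ascending index), `feature_names`, and
#'   `meta`.
#' @export
fit_importance <- function(X, y, rounds = 50L, depth = 1L, seed = 1L,
                           min_leaf = 1L) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  if (nrow(X) < 4) stop("need at least 4 samples")
  X <- impute_missing(X)
  n <- nrow(X); d <- ncol(X)
  ps <- cpp_presort(X)   # per-feature sort, done once for all rounds
  w <- rep(1 / n, n)
  dec_sum <- numeric(d)
  all_rows <- rep(TRUE, n)
  for (m in seq_len(rounds)) {
    imp <- new.env()
    imp$dec <- numeric(d)
    tree <- .gini_tree(X, ps, w, y, all_rows, depth, min_leaf, imp)
    dec_sum <- dec_sum + imp$dec
    p1 <- pmin(pmax(.tree_prob(tree, X), .PROB_CLIP), 1 - .PROB_CLIP)
    logit_half <- 0.5 * (log(p1) - log(1 - p1))
    ytilde <- 2 * y - 1
    w <- w * exp(-ytilde * logit_half)
    w <- w / sum(w)
  }
  scores <- dec_sum / rounds
  if (sum(scores) > 0) scores <- scores / sum(scores)
  ranking <- order(-scores, seq_along(scores))
  structure(list(scores = scores, ranking = ranking,
                 feature_names = colnames(X),
                 meta = list(rounds = rounds, depth = depth, seed = seed)),
            class = "importance_ranking")
}

.as_binary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    ok <- y %in% c("positive", "negative")
    if (!all(ok)) stop("labels must be positive/negative or 0/1")
    return(as.integer(y == "positive"))
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  y
}

#' Mean-impute missing feature values
#'
#' Columns containing `NA` are replaced by their observed mean (0 when a
#' column is entirely `NA`); a message reports how many columns were imputed.
#'
#' @param X numeric matrix.
#' @return matrix with no missing values.
#' @export
impute_missing <- function(X) {
  nac <- which(colSums(is.na(X)) > 0)
  if (length(nac)) {
    for (j in nac) {
      mu <- mean(X[, j], na.rm = TRUE)
      if (!is.finite(mu)) mu <- 0
      X[is.na(X[, j]), j] <- mu
    }
    message(length(nac), " feature column(s) mean-imputed")
  }
  X
}

#' @export
print.importance_ranking <- function(x, ...) {
  nz <- sum(x$scores > 0)
  cat(sprintf("<importance_ranking> %d features, %d with nonzero score (rounds=%d, depth=%d)\n",
              length(x$scores), nz, x$meta$rounds, x$meta$depth))
  invisible(x)
}

#' Select features from an importance ranking
#'
#' `rule = "nonzero"` (default) keeps every feature with positive score;
#' `rule = "top_k"` keeps the `k` best ranks (ties broken by ascending
#' feature index).
#'
#' @param ranking an [fit_importance()] result.
#' @param rule `"nonzero"` or `"top_k"`.
#' @param k number of features for `top_k`.
#' @return A `selection_mask`: list with logical `keep`, integer `selected`
#'   (indices in ranking order), and `rule`.
#' @export
select_features <- function(ranking, rule = c("nonzero", "top_k"), k = NULL) {
  stopifnot(inherits(ranking, "importance_ranking"))
  rule <- match.arg(rule)
  d <- length(ranking$scores)
  if (rule == "top_k") {
    if (is.null(k) || k <= 0 || k > d) stop("k must be in 1..", d)
    selected <- ranking$ranking[seq_len(k)]
  } else {
    selected <- ranking$ranking[ranking$scores[ranking$ranking] > 0]
    if (length(selected) == 0)
      warning("all importance scores are zero; empty selection")
  }
  keep <- rep(FALSE, d)
  keep[selected] <- TRUE
  structure(list(keep = keep, selected = selected, rule = rule,
                 feature_names = ranking$feature_names),
            class = "selection_mask")
}

#' Write an importance table as TSV
#'
#' Columns: feature, score, rank.
#' @param ranking an [fit_importance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_importance_tsv <- function(ranking, path) {
  nm <- ranking$feature_names %||% paste0("f", seq_along(ranking$scores))
  df <- data.frame(feature = nm, score = ranking$scores,
                   rank = match(seq_along(ranking$scores), ranking$ranking))
  df <- df[order(df$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
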