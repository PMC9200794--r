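# Gradient-boosted decision trees with logistic loss.
#
# Labels are stored as y in {0,1} and boosted as ytilde = 2y - 1. The model
# score H(x) is half the log-odds: the initial score is
# h0 = 0.5 * log(sum(y) / sum(1 - y)), each round fits a least-squares
# regression tree to the pseudo-residuals r_i = ytilde_i / (1 + exp(ytilde_i *
# h_i)), sets each leaf value by 1-D Newton-Raphson on the leaf's logistic
# loss, and updates h <- h + lr * leaf_value. Probabilities use the matching
# link p = sigmoid(2 * H).

.SCORE_CLIP <- 50
.LEAF_CLIP <- 4

#' Initial boosting score from class balance
#'
#' `h0 = 0.5 * log(sum(y) / sum(1 - y))` — half the log-odds of the positive
#' class.
#' @param y binary labels (0/1).
#' @return a real.
#' @export
gbdt_init_score <- function(y) {
  y <- .as_binary(y)
  npos <- sum(y); nneg <- sum(1 - y)
  if (npos == 0 || nneg == 0)
    stop("degenerate labels: both classes required for the log-odds init")
  0.5 * log(npos / nneg)
}

#' Logistic-loss pseudo-residuals
#'
#' `r_i = ytilde_i / (1 + exp(ytilde_i * h_i))`, the negative gradient of
#' `log(1 + exp(-ytilde * h))` with respect to h. Scores are clipped to
#' +/- 50 before exponentiation.
#' @param ytilde labels in -1/+1.
#' @param h current scores (same length).
#' @return numeric vector of residuals in (-1, 1).
#' @export
gbdt_pseudo_residuals <- function(ytilde, h) {
  stopifnot(length(ytilde) == length(h), all(ytilde %in% c(-1, 1)))
  hc <- pmin(pmax(h, -.SCORE_CLIP), .SCORE_CLIP)
  ytilde / (1 + exp(ytilde * hc))
}

# Grow a least-squares regression tree on the pseudo-residuals. Nodes are a
# flat data frame (feature/threshold/left/right/value); leaf ids index rows.
gbdt_fit_tree <- function(X, r, max_depth, min_leaf, ps = NULL) {
  if (is.null(ps)) ps <- cpp_presort(X)
  nodes <- list()
  grow <- function(mask, d) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         value = NA_real_, leaf = TRUE)
    if (d < max_depth && sum(mask) >= 2 * min_leaf) {
      sp <- cpp_sse_scan(ps$sorted, ps$ord, mask, r, min_leaf)
      if (sp$feature > 0L && sp$gain > 0) {
        go_left <- X[, sp$feature] <= sp$threshold
        lid <- grow(mask & go_left, d + 1L)
        rid <- grow(mask & !go_left, d + 1L)
        nodes[[id]] <<- list(feature = sp$feature, threshold = sp$threshold,
                             left = lid, right = rid, value = NA_real_,
                             leaf = FALSE)
      }
    }
    id
  }
  grow(rep(TRUE, nrow(X)), 0L)
  do.call(rbind, lapply(nodes, as.data.frame))
}

# Leaf id (row in the node table) reached by each row of X.
gbdt_leaf_of <- function(tree, X) {
  leaf <- integer(nrow(X))
  descend <- function(id, mask) {
    nd <- tree[id, ]
    if (nd$leaf) {
      leaf[mask] <<- id
    } else {
      go_left <- X[, nd$feature] <= nd$threshold
      descend(nd$left, mask & go_left)
      descend(nd$right, mask & !go_left)
    }
  }
  descend(1L, rep(TRUE, nrow(X)))
  leaf
}

#' Newton leaf value for the logistic loss
#'
#' Minimizes `sum(log(1 + exp(-ytilde * (h + v))))` over the scalar v by
#' safeguarded Newton-Raphson from v = 0 (first step equals
#' `sum(r) / sum(|r| (1 - |r|))`), iterating until `|dv| < 1e-8` or 25
#' iterations, with v clamped to +/- 4 (a leaf whose residuals are all
#' saturated has its minimizer at infinity; the clamp, with a warning, keeps
#' scores finite).
#' @param ytilde labels in -1/+1 of the samples in the leaf.
#' @param h their current scores.
#' @return optimal leaf value v.
#' @export
gbdt_leaf_value <- function(ytilde, h) {
  v <- 0
  for (it in seq_len(25)) {
    r <- gbdt_pseudo_residuals(ytilde, h + v)
    g <- -sum(r)                     # d/dv of the leaf loss
    hess <- sum(abs(r) * (1 - abs(r)))
    if (hess < 1e-12) {
      warning("saturated leaf; value clipped to +/-", .LEAF_CLIP)
      v <- sign(if (g != 0) -g else sum(ytilde)) * .LEAF_CLIP
      break
    }
    dv <- -g / hess
    v <- v + dv
    if (v > .LEAF_CLIP) { v <- .LEAF_CLIP; break }
    if (v < -.LEAF_CLIP) { v <- -.LEAF_CLIP; break }
    if (abs(dv) < 1e-8) break
  }
  v
}

#' Train a gradient-boosted decision tree classifier
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or `"positive"`/`"negative"`); both classes
#'   required.
#' @param rounds number of boosting rounds M (default 100).
#' @param learning_rate shrinkage in (0, 1\] (default 0.1).
#' @param max_depth regression-tree depth (default 3).
#' @param min_leaf minimum samples per leaf (default 5).
#' @param seed recorded for provenance (the fit itself is deterministic).
#' @return A `gbdt_model`: list with `h0`, `lr`, `trees` (node tables with
#'   leaf values), `loss_curve` (mean training logistic loss after each
#'   round), `d`, `feature_names`.
#' @export
gbdt_train <- function(X, y, rounds = 100L, learning_rate = 0.1,
                       max_depth = 3L, min_leaf = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  stopifnot(nrow(X) == length(y), learning_rate > 0, learning_rate <= 1)
  h0 <- gbdt_init_score(y)
  ytilde <- 2 * y - 1
  h <- rep(h0, length(y))
  ps <- cpp_presort(X)
  trees <- vector("list", rounds)
  loss_curve <- numeric(rounds)
  for (m in seq_len(rounds)) {
    r <- gbdt_pseudo_residuals(ytilde, h)
    tree <- gbdt_fit_tree(X, r, max_depth, min_leaf, ps)
    leaf <- gbdt_leaf_of(tree, X)
    for (j in which(tree$leaf)) {
      idx <- which(leaf == j)
      if (length(idx))
        tree$value[j] <- gbdt_leaf_value(ytilde[idx], h[idx])
      else tree$value[j] <- 0
    }
    h <- h + learning_rate * tree$value[leaf]
    trees[[m]] <- tree
    loss_curve[m] <- mean(log1p(exp(-pmin(pmax(ytilde * h, -.SCORE_CLIP),
                                          .SCORE_CLIP))))
  }
  structure(list(h0 = h0, lr = learning_rate, trees = trees,
                 loss_curve = loss_curve, d = ncol(X),
                 feature_names = colnames(X),
                 params = list(rounds = rounds, max_depth = max_depth,
                               min_leaf = min_leaf, seed = seed)),
            class = "gbdt_model")
}

#' Predict from a GBDT model
#'
#' The additive score is `H(x) = h0 + lr * sum_m v_m(x)`; probabilities use
#' `p = 1 / (1 + exp(-2 H(x)))` and classes threshold p at 0.5.
#'
#' @param object a `gbdt_model`.
#' @param newdata numeric matrix with the training column count.
#' @param type `"prob"` (default), `"score"` (H) or `"class"` (0/1).
#' @param ... unused.
#' @return numeric vector (or integer vector for `"class"`).
#' @export
predict.gbdt_model <- function(object, newdata,
                               type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$d)
  H <- rep(object$h0, nrow(newdata))
  for (tree in object$trees)
    H <- H + object$lr * tree$value[gbdt_leaf_of(tree, newdata)]
  if (type == "score") return(H)
  p <- 1 / (1 + exp(-2 * pmin(pmax(H, -.SCORE_CLIP), .SCORE_CLIP)))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("<gbdt_model> %d trees, lr=%g, depth<=%d, d=%d features\n",
              length(x$trees), x$lr, x$params$max_depth, x$d))
  cat(sprintf("  h0=%.4f, final training loss=%.4f\n", x$h0,
              if (length(x$loss_curve)) x$loss_curve[length(x$loss_curve)]
              else NA))
  invisible(x)
}

#' Serialize a GBDT model to JSON
#'
#' @param model a `gbdt_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gbdt_json <- function(model, path) {
  # internal nodes only carry feature/threshold; leaves only carry value.
  # Use 0 sentinels for the unused slots so the JSON has no NA/null entries.
  enc <- function(t) {
    list(feature = ifelse(t$leaf, 0L, t$feature),
         threshold = ifelse(t$leaf, 0, t$threshold),
         left = ifelse(t$leaf, 0L, t$left),
         right = ifelse(t$leaf, 0L, t$right),
         value = ifelse(t$leaf, t$value, 0),
         leaf = t$leaf)
  }
  payload <- list(h0 = model$h0, lr = model$lr, d = model$d,
                  params = model$params,
                  feature_names = model$feature_names,
                  trees = lapply(model$trees, enc))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GBDT model from JSON
#'
#' @param path a file written by [write_gbdt_json()].
#' @return a `gbdt_model`.
#' @export
read_gbdt_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(t) {
    n <- length(t$leaf)
    data.frame(
      feature = ifelse(unlist(t$leaf), NA_integer_, unlist(t$feature)),
      threshold = ifelse(unlist(t$leaf), NA_real_,
                         as.numeric(unlist(t$threshold))),
      left = ifelse(unlist(t$leaf), NA_integer_, unlist(t$left)),
      right = ifelse(unlist(t$leaf), NA_integer_, unlist(t$right)),
      value = ifelse(unlist(t$leaf), as.numeric(unlist(t$value)), NA_real_),
      leaf = unlist(t$leaf))
  }
  structure(list(h0 = p$h0, lr = p$lr,
                 trees = lapply(p$trees, dec), loss_curve = numeric(0),
                 d = p$d,
                 feature_names = if (is.null(p$feature_names)) NULL
                                 else unlist(p$feature_names),
                 params = p$params),
            class = "gbdt_model")
}
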