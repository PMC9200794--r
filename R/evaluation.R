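# Seven-metric evaluation (ACC, AUC, AUPR, F1, MCC, SEN, SPC), stratified
# k-fold cross-validation, and the positives-vs-negative-batches averaging
# scheme. Degenerate-denominator metrics are reported as 0 and flagged rather
# than NaN so batch averages stay defined.

#' Confusion counts
#'
#' @param y_true,y_pred binary vectors (0/1) of equal length.
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- .as_binary(y_true); y_pred <- .as_binary(y_pred)
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

.safe_div <- function(num, den, flags, name) {
  if (den == 0) {
    flags[[name]] <- TRUE
    list(value = 0, flags = flags)
  } else list(value = num / den, flags = flags)
}

#' Threshold metrics from confusion counts
#'
#' ACC = (TP+TN)/total; precision = TP/(TP+FP); SEN (recall/TPR) =
#' TP/(TP+FN); F1 = TP/(TP + 0.5 (FN+FP)); MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); SPC (TNR) = TN/(TN+FP);
#' FPR = 1 - SPC. A zero denominator yields 0 with a flag.
#'
#' @param cc a [confusion_counts()] result.
#' @return list of metrics plus `counts` and `flags` (names of degenerate
#'   metrics).
#' @export
threshold_metrics <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stop("no evaluated records")
  flags <- list()
  out <- list(ACC = (cc$TP + cc$TN) / total)
  r <- .safe_div(cc$TP, cc$TP + cc$FP, flags, "precision")
  out$precision <- r$value; flags <- r$flags
  r <- .safe_div(cc$TP, cc$TP + cc$FN, flags, "SEN")
  out$SEN <- r$value; flags <- r$flags
  r <- .safe_div(cc$TP, cc$TP + 0.5 * (cc$FN + cc$FP), flags, "F1")
  out$F1 <- r$value; flags <- r$flags
  mcc_den <- sqrt(cc$TP + cc$FP) * sqrt(cc$TP + cc$FN) *
             sqrt(cc$TN + cc$FP) * sqrt(cc$TN + cc$FN)
  if (mcc_den == 0) {
    out$MCC <- 0; flags$MCC <- TRUE
  } else out$MCC <- (cc$TP * cc$TN - cc$FP * cc$FN) / mcc_den
  r <- .safe_div(cc$TN, cc$TN + cc$FP, flags, "SPC")
  out$SPC <- r$value; flags <- r$flags
  out$FPR <- 1 - out$SPC
  out$counts <- cc
  out$flags <- names(flags)
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the TPR-vs-FPR curve swept over all score
#' thresholds, with tied scores grouped (equivalent to the Mann-Whitney
#' rank statistic).
#'
#' @param y_true binary labels (both classes present).
#' @param scores real-valued scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y <- .as_binary(y_true)
  if (length(unique(y)) < 2) stop("AUC undefined: single-class labels")
  stopifnot(length(y) == length(scores))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  # group ties: cumulative counts at the end of each tie group
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  tpr <- c(0, tp / sum(y == 1))
  fpr <- c(0, fp / sum(y == 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' `sum_n (Recall_n - Recall_{n-1}) * Precision_n` over descending-score
#' thresholds (step interpolation), with tied scores grouped.
#'
#' @param y_true binary labels (both classes present).
#' @param scores real-valued scores.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(y_true, scores) {
  y <- .as_binary(y_true)
  if (length(unique(y)) < 2) stop("AUPR undefined: single-class labels")
  stopifnot(length(y) == length(scores))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  n_pred <- seq_along(y)[last_of_group]
  recall <- tp / sum(y == 1)
  precision <- tp / n_pred
  sum(diff(c(0, recall)) * precision)
}

#' Full metrics report for scored predictions
#'
#' Applies the 0.5 probability threshold for the confusion-based metrics and
#' computes AUC/AUPR from the raw scores.
#'
#' @param y_true binary labels.
#' @param scores predicted probabilities (or any monotone scores for
#'   AUC/AUPR; the 0.5 threshold assumes probabilities).
#' @param threshold decision threshold (default 0.5).
#' @return A `metrics_report`: list of ACC, AUC, AUPR, F1, MCC, SEN, SPC,
#'   precision, FPR, counts, flags.
#' @export
evaluate_scores <- function(y_true, scores, threshold = 0.5) {
  y <- .as_binary(y_true)
  tm <- threshold_metrics(confusion_counts(y, as.integer(scores >= threshold)))
  rep <- list(ACC = tm$ACC, AUC = roc_auc(y, scores), AUPR = aupr(y, scores),
              F1 = tm$F1, MCC = tm$MCC, SEN = tm$SEN, SPC = tm$SPC,
              precision = tm$precision, FPR = tm$FPR, counts = tm$counts,
              flags = tm$flags)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> ACC=%.3f AUC=%.3f AUPR=%.3f F1=%.3f MCC=%.3f SEN=%.3f SPC=%.3f\n",
    x$ACC, x$AUC, x$AUPR, x$F1, x$MCC, x$SEN, x$SPC))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffles.
#' @return integer fold id (1..k) per sample; every fold contains both
#'   classes when each class has at least k members.
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- .as_binary(y)
  if (min(table(y)) < k)
    stop("stratification error: k exceeds the size of a class")
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Arithmetic mean of metrics reports
#'
#' Averages the seven headline metrics (plus precision and FPR) across
#' reports; confusion counts are summed.
#'
#' @param reports list of `metrics_report`.
#' @return a `metrics_report` with an extra `n_averaged` field.
#' @export
average_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  keys <- c("ACC", "AUC", "AUPR", "F1", "MCC", "SEN", "SPC", "precision",
            "FPR")
  out <- lapply(keys, function(k) mean(vapply(reports, `[[`, numeric(1), k)))
  names(out) <- keys
  out$counts <- Reduce(function(a, b) Map(`+`, a, b),
                       lapply(reports, `[[`, "counts"))
  out$flags <- unique(unlist(lapply(reports, `[[`, "flags")))
  out$n_averaged <- length(reports)
  structure(out, class = "metrics_report")
}

#' Cross-validated GBDT evaluation
#'
#' Stratified k-fold: per fold, a GBDT is trained on the training split and
#' scored on the held-out split; all metrics (including AUC/AUPR) are computed
#' per fold and arithmetically averaged. When `select` is given, SAMME.R
#' feature selection is refit inside each training fold and its mask applied
#' to that fold's test split — selection never sees held-out labels (fitting
#' the selector on the full dataset before CV leaks label information through
#' the feature choice and inflates null performance). Set `pooled = TRUE` to
#' instead pool held-out predictions across folds and compute one report.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param k folds (e.g. 4 or 10).
#' @param seed fold-assignment seed.
#' @param gbdt named list of arguments passed to [gbdt_train()].
#' @param select optional named list for per-fold selection: `rounds`,
#'   `depth`, `rule`, `k` (as in [fit_importance()] / [select_features()]).
#' @param pooled pool predictions instead of averaging per-fold metrics?
#' @return a `metrics_report` (fold-averaged), with attribute `"folds"`
#'   holding the per-fold reports.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L, gbdt = list(),
                           select = NULL, pooled = FALSE) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  fold <- make_folds(y, k, seed)
  per_fold <- vector("list", k)
  pooled_scores <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    if (!is.null(select)) {
      rk <- fit_importance(Xtr, ytr, rounds = select$rounds %||% 50L,
                           depth = select$depth %||% 1L, seed = seed)
      mask <- select_features(rk, rule = select$rule %||% "nonzero",
                              k = select$k)
      if (length(mask$selected) > 0) {
        Xtr <- Xtr[, mask$selected, drop = FALSE]
        Xte <- Xte[, mask$selected, drop = FALSE]
      }
    }
    model <- do.call(gbdt_train, c(list(X = Xtr, y = ytr), gbdt))
    sc <- predict(model, Xte, type = "prob")
    pooled_scores[test] <- sc
    per_fold[[f]] <- evaluate_scores(y[test], sc)
  }
  out <- if (pooled) evaluate_scores(y, pooled_scores)
         else average_reports(per_fold)
  attr(out, "folds") <- per_fold
  out
}

#' Batch-averaged evaluation against negative batches
#'
#' For each negative batch, builds the balanced two-class dataset (all
#' positives plus that batch), runs the full pipeline (featurize, impute,
#' SAMME.R selection, cross-validated GBDT) and averages the resulting
#' reports across batches.
#'
#' @param pos a [fasta_dataset()] of positives.
#' @param neg_batches list of [fasta_dataset()] negatives (ids disjoint from
#'   positives).
#' @param config a [pipeline_config()].
#' @return a `metrics_report` averaged over batches, with attribute
#'   `"batches"` holding the per-batch reports.
#' @export
batch_evaluate <- function(pos, neg_batches, config = pipeline_config()) {
  stopifnot(inherits(pos, "fasta_dataset"), length(neg_batches) >= 1)
  reports <- vector("list", length(neg_batches))
  for (bi in seq_along(neg_batches)) {
    neg <- neg_batches[[bi]]
    if (length(overlap_ids(pos, neg)))
      stop("data leak: ids shared between positives and batch ", bi)
    ds <- fasta_dataset(id = c(pos$id, neg$id),
                        residues = c(pos$residues, neg$residues),
                        label = c(rep("positive", nrow(pos)),
                                  rep("negative", nrow(neg))),
                        source = "batch_evaluate")
    reports[[bi]] <- .evaluate_two_class(ds, config)
  }
  out <- average_reports(reports)
  attr(out, "batches") <- reports
  out
}

# Featurize + cross-validate one balanced two-class dataset (selection, when
# enabled, happens inside each training fold; see cross_validate).
.evaluate_two_class <- function(ds, config) {
  X <- .featurize(ds, config)
  y <- .as_binary(ds$label)
  X <- impute_missing(X)
  sel <- if (isTRUE(config$select$enabled)) config$select else NULL
  cross_validate(X, y, k = config$cv$k, seed = config$seed,
                 gbdt = config$gbdt, select = sel)
}

.featurize <- function(ds, config) {
  fam <- config$features$family
  if (fam == "pyfeat") {
    pyfeat_features(ds, K = config$features$K, n = config$features$n)
  } else if (fam == "rff") {
    rff_features(ds)
  } else {
    cbind(pyfeat_features(ds, K = config$features$K, n = config$features$n),
          rff_features(ds))
  }
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @param extra named list merged into the JSON (e.g. config echo).
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, extra = list()) {
  payload <- c(unclass(report), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
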