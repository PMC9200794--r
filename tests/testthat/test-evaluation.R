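test_that("confusion counts", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cc, list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(c(1, 0), c(1, 1))
  expect_equal(cc2$TP, 1L); expect_equal(cc2$FP, 1L)
  cc3 <- confusion_counts(integer(0), integer(0))
  expect_equal(unlist(cc3), c(TP = 0L, TN = 0L, FP = 0L, FN = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "mismatch")
})

test_that("threshold metrics reproduce the hand-computed example", {
  cc <- list(TP = 50L, TN = 40L, FP = 10L, FN = 0L)
  tm <- threshold_metrics(cc)
  expect_equal(tm$ACC, 0.9)
  expect_equal(tm$SEN, 1.0)
  expect_equal(tm$SPC, 0.8)
  expect_equal(tm$F1, 50 / 55)
  expect_equal(tm$MCC, (50 * 40 - 10 * 0) / sqrt(60 * 50 * 50 * 40))
  expect_equal(tm$FPR, 1 - tm$SPC)
  expect_length(tm$flags, 0)
})

test_that("degenerate denominators report 0 with a flag", {
  tm <- threshold_metrics(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L))
  expect_equal(tm$ACC, 1)
  expect_equal(tm$F1, 0)
  expect_true(all(c("F1", "precision", "SEN") %in% tm$flags))

  # all four margins positive: MCC is well-defined and equals -1 for a
  # perfectly wrong predictor
  tm2 <- threshold_metrics(list(TP = 0L, TN = 0L, FP = 5L, FN = 5L))
  expect_equal(tm2$MCC, -1)
  expect_false("MCC" %in% tm2$flags)
  # a genuinely zero margin (TP + FP = 0) flags MCC
  tm3 <- threshold_metrics(list(TP = 0L, TN = 5L, FP = 0L, FN = 5L))
  expect_equal(tm3$MCC, 0)
  expect_true("MCC" %in% tm3$flags)
})

test_that("roc_auc: perfect, reversed, symmetric, and the rank oracle", {
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)), 1)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)), 0)
  set.seed(17)
  s <- rnorm(6)
  expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "single-class")

  # 1,000 random instances (with ties) against the Mann-Whitney oracle
  set.seed(18)
  for (i in 1:1000) {
    n <- sample(6:30, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 1))  # rounding forces ties
    expect_equal(roc_auc(y, s), auc_rank_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(19)
  y <- sample(0:1, 100, replace = TRUE, prob = c(0.6, 0.4))
  s <- rnorm(100)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 3 * s - 7), a)
  expect_equal(roc_auc(y, rank(s)), a)
})

test_that("aupr: perfect, constant, and the threshold-sweep oracle", {
  y <- c(1, 1, 0, 0)
  expect_equal(aupr(y, c(0.9, 0.8, 0.2, 0.1)), 1)
  # constant scores: single PR point at recall 1, precision = prevalence
  expect_equal(aupr(y, rep(0.5, 4)), 0.5)
  set.seed(20)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 1))
    expect_equal(aupr(y, s), aupr_sweep_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("metric report invariants", {
  set.seed(22)
  y <- c(1, 0, sample(0:1, 60, replace = TRUE))
  s <- runif(62)
  rep <- evaluate_scores(y, s)
  for (k in c("ACC", "AUC", "AUPR", "F1", "SEN", "SPC", "precision"))
    expect_true(rep[[k]] >= 0 && rep[[k]] <= 1)
  expect_true(rep$MCC >= -1 && rep$MCC <= 1)
  expect_equal(rep$FPR, 1 - rep$SPC)
  prev <- mean(y)
  expect_equal(rep$ACC, rep$SEN * prev + rep$SPC * (1 - prev))
})

test_that("stratified folds partition and keep both classes", {
  y <- rep(c(1, 0), c(30, 40))
  fold <- make_folds(y, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 70)
  for (f in 1:10) expect_equal(length(unique(y[fold == f])), 2)
  # fold sizes as equal as possible
  expect_true(max(table(fold)) - min(table(fold)) <= 2)
  expect_error(make_folds(rep(c(1, 0), c(3, 40)), 10), "stratification")
})

test_that("cross_validate averages per-fold reports; permuted labels ~ 0.5", {
  set.seed(33)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4)
  y_null <- sample(rep(0:1, n / 2))
  cv <- cross_validate(X, y_null, k = 4, seed = 1,
                       gbdt = list(rounds = 20, max_depth = 2))
  expect_s3_class(cv, "metrics_report")
  expect_gt(cv$AUC, 0.4); expect_lt(cv$AUC, 0.6)
  folds <- attr(cv, "folds")
  expect_length(folds, 4)
  expect_equal(cv$AUC, mean(vapply(folds, `[[`, numeric(1), "AUC")))

  # separable signal: near-perfect fold-averaged AUC
  y_sig <- as.integer(X[, 1] > 0)
  cv2 <- cross_validate(X, y_sig, k = 4, seed = 1,
                        gbdt = list(rounds = 20, max_depth = 2))
  expect_gt(cv2$AUC, 0.95)
})

test_that("average_reports is the arithmetic mean and sums counts", {
  r1 <- evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  r2 <- evaluate_scores(c(1, 0, 1, 0), c(0.6, 0.7, 0.9, 0.1))
  avg <- average_reports(list(r1, r2))
  expect_equal(avg$AUC, (r1$AUC + r2$AUC) / 2)
  expect_equal(avg$counts$TP, r1$counts$TP + r2$counts$TP)
  expect_equal(avg$n_averaged, 2)
})

test_that("batch_evaluate refuses id leaks and averages across batches", {
  set.seed(41)
  pos <- fasta_dataset(id = sprintf("p_%02d", 1:12),
                       residues = replicate(12, random_dna(60)),
                       label = "positive")
  set.seed(42)
  mk_batch <- function(tag) {
    fasta_dataset(id = sprintf("%s_%02d", tag, 1:12),
                  residues = replicate(12, random_dna(60)),
                  label = "negative")
  }
  leak <- mk_batch("x"); leak$id[1] <- pos$id[1]
  expect_error(batch_evaluate(pos, list(leak)), "leak")

  cfg <- pipeline_config(select = list(rounds = 5),
                         gbdt = list(rounds = 5), cv = list(k = 3))
  b1 <- mk_batch("b1")
  rep1 <- batch_evaluate(pos, list(b1), cfg)
  # identical batches: the average equals the single-batch report
  rep2 <- batch_evaluate(pos, list(b1, b1_copy = {
    b2 <- b1; b2$id <- sub("^b1", "b2", b2$id); b2
  }), cfg)
  expect_equal(rep2$AUC, rep1$AUC)
  expect_equal(attr(rep2, "batches")[[1]]$AUC,
               attr(rep2, "batches")[[2]]$AUC)
})
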