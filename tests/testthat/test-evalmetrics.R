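test_that("confusion counting is threshold-inclusive with malignant positive", {
  probs <- c(0.2, 0.5, 0.7, 0.4)
  labels <- c(0L, 1L, 1L, 1L)
  cm <- confusion(probs, labels, threshold = 0.5)
  expect_identical(cm, c(TP = 2L, FP = 0L, TN = 1L, FN = 1L))
  expect_error(confusion(probs, labels[-1]), class = "fh_invalid_input")
})

test_that("confusion-derived metrics satisfy their defining identities", {
  set.seed(1)
  for (i in 1:10) {
    cts <- sample(0:40, 4, replace = TRUE)
    m <- metrics_from_confusion(cts[1], cts[2], cts[3], cts[4])
    sens <- if (cts[1] + cts[4] > 0) cts[1] / (cts[1] + cts[4]) else NA_real_
    spec <- if (cts[3] + cts[2] > 0) cts[3] / (cts[3] + cts[2]) else NA_real_
    expect_equal(m$sensitivity, sens)
    expect_equal(m$specificity, spec)
    expect_equal(m$balanced_accuracy, (sens + spec) / 2)
    expect_equal(m$f1, 2 * cts[1] / (2 * cts[1] + cts[2] + cts[4]))
  }
  expect_true(is.na(metrics_from_confusion(0, 5, 5, 0)$sensitivity))
  expect_error(metrics_from_confusion(-1, 0, 0, 0), class = "fh_invalid_input")
})

test_that("balanced accuracy recovers published three-dataset summaries", {
  ## printed sensitivity/specificity pairs of one benchmark's lead method and
  ## its reported balanced accuracies (percent)
  pairs <- list(c(sens = 0.833, spec = 0.920, ba = 87.6),
                c(sens = 0.800, spec = 0.905, ba = 85.2),
                c(sens = 0.450, spec = 0.778, ba = 61.4))
  for (p in pairs) {
    ba <- (p[["sens"]] + p[["spec"]]) / 2 * 100
    expect_lt(abs(ba - p[["ba"]]), 0.051)
  }
})

test_that("recomputed balanced accuracy tracks printed method rows to 0.001", {
  sens <- c(0.833, 0.690, 0.714, 0.714, 0.690, 0.595)
  spec <- c(0.920, 0.931, 0.851, 0.897, 0.885, 0.862)
  printed <- c(0.876, 0.811, 0.782, 0.805, 0.788, 0.729)
  expect_true(all(abs((sens + spec) / 2 - printed) <= 0.001 + 1e-12))
})

test_that("the ROC area equals the concordance statistic", {
  ## hand case: one discordant pair among four -> 0.75
  r <- roc_pr_curves(c(0.9, 0.8, 0.4, 0.35), c(1L, 0L, 1L, 0L))
  expect_equal(r$auc_roc, 0.75)
  ## perfect and inverted separations
  expect_equal(roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L))$auc_roc, 1)
  expect_equal(roc_pr_curves(c(0.1, 0.2, 0.8, 0.9), c(1L, 1L, 0L, 0L))$auc_roc, 0)
  ## Mann-Whitney equivalence on continuous scores
  set.seed(2)
  probs <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  u <- unname(stats::wilcox.test(probs[labels == 1],
                                 probs[labels == 0])$statistic)
  expect_equal(roc_pr_curves(probs, labels)$auc_roc,
               u / (sum(labels == 1) * sum(labels == 0)), tolerance = 1e-12)
  expect_error(roc_pr_curves(probs, rep(1L, 60)), class = "fh_undefined_curve")
})

test_that("the ROC area agrees with an independent implementation", {
  set.seed(3)
  probs <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  ours <- roc_pr_curves(probs, labels)$auc_roc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("decision curves obey the treat-all and treat-none closed forms", {
  set.seed(4)
  probs <- runif(50)
  labels <- rbinom(50, 1, 0.3)
  th <- seq(0.05, 0.95, by = 0.05)
  dc <- decision_curve(probs, labels, th)
  prev <- mean(labels)
  expect_identical(dc$treat_none, rep(0, length(th)))
  expect_equal(dc$treat_all, prev - (1 - prev) * th / (1 - th),
               tolerance = 1e-12)
  ## a perfect classifier's net benefit is the prevalence at every threshold
  dcp <- decision_curve(as.numeric(labels), labels, th)
  expect_equal(dcp$net_benefit, rep(prev, length(th)), tolerance = 1e-12)
  expect_error(decision_curve(probs, labels, c(0, 0.5)),
               class = "fh_invalid_input")
})

test_that("evaluation reports are complete, deterministic and serialisable", {
  set.seed(5)
  probs <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  r1 <- evaluate_predictions(probs, labels)
  r2 <- evaluate_predictions(probs, labels)
  expect_identical(r1, r2)
  expect_s3_class(r1, "fh_eval_report")
  expect_identical(sum(r1$counts), 40L)
  expect_equal(r1$balanced_accuracy, (r1$sensitivity + r1$specificity) / 2)
  path <- file.path(tempfile("ev"), "report.json")
  dir.create(dirname(path))
  write_eval_report(r1, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$balanced_accuracy, r1$balanced_accuracy, tolerance = 1e-12)
  expect_equal(back$auc_roc, r1$auc_roc, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", "_roc.csv", path)))
  expect_true(file.exists(sub("\\.json$", "_dca.csv", path)))
  unlink(dirname(path), recursive = TRUE)
})

test_that("a perfect oracle scores one on every summary metric", {
  labels <- rep(0:1, each = 10)
  r <- evaluate_predictions(c(rep(0.1, 10), rep(0.9, 10)), labels)
  expect_equal(r$balanced_accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$auc_roc, 1)
  expect_equal(r$auc_pr, 1)
})
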