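# Confusion-matrix metrics against brute-force oracles, ROC/AUC against the
# pairwise rank statistic and against an independent library.

test_that("confusion matrices tally pairs exactly", {
  t12 <- c("normal", "normal", "metastasis", "arthritis", "arthritis",
           "thyroid_carcinoma", "normal", "metastasis", "arthritis",
           "thyroid_carcinoma", "thyroid_carcinoma", "normal")
  p12 <- c("normal", "metastasis", "metastasis", "arthritis", "normal",
           "thyroid_carcinoma", "normal", "metastasis", "arthritis",
           "arthritis", "thyroid_carcinoma", "normal")
  cm <- confusion(t12, p12)
  # hand tally
  expect_identical(cm["normal", "normal"], 3L)
  expect_identical(cm["normal", "metastasis"], 1L)
  expect_identical(cm["metastasis", "metastasis"], 2L)
  expect_identical(cm["arthritis", "arthritis"], 2L)
  expect_identical(cm["arthritis", "normal"], 1L)
  expect_identical(cm["thyroid_carcinoma", "thyroid_carcinoma"], 2L)
  expect_identical(cm["thyroid_carcinoma", "arthritis"], 1L)
  expect_identical(sum(cm), 12L)

  # perfect predictions: diagonal, row sums = class counts
  cmp <- confusion(t12, t12)
  expect_identical(sum(cmp) - sum(diag(cmp)), 0L)
  expect_identical(unname(diag(cmp)), as.integer(table(
    factor(t12, levels = class_labels()))))

  # empty input: zero matrix
  expect_identical(sum(confusion(character(0), character(0))), 0L)
  expect_error(confusion(t12, p12[-1]), "length")
  # integer codes accepted
  expect_identical(confusion(c(0, 1), c(0, 1))["normal", "normal"], 1L)
})

test_that("one-vs-rest reduction satisfies the partition identity", {
  cm <- confusion(rep(class_labels(), times = c(5, 3, 4, 2)),
                  c(rep("normal", 4), "arthritis",
                    "metastasis", "normal", "metastasis",
                    rep("arthritis", 3), "thyroid_carcinoma",
                    "thyroid_carcinoma", "metastasis"))
  for (cl in class_labels()) {
    v <- one_vs_rest(cm, cl)
    expect_identical(sum(v), sum(cm))
    expect_identical(v[["TP"]], cm[cl, cl])
  }
  d <- confusion(t <- rep(class_labels(), 2), t)
  for (cl in class_labels()) {
    v <- one_vs_rest(d, cl)
    expect_identical(v[["FP"]], 0L)
    expect_identical(v[["FN"]], 0L)
  }
})

test_that("the five rates match hand evaluation and conventions", {
  m <- basic_metrics(8, 2, 1, 9)
  expect_equal(unname(m), c(0.85, 8 / 9, 0.8, 0.9,
                            2 * (8 / 9) * 0.8 / (8 / 9 + 0.8)))
  expect_equal(m[["f1"]], 0.8421, tolerance = 1e-4)

  expect_equal(unname(basic_metrics(7, 0, 0, 5)), rep(1, 5))

  deg <- basic_metrics(0, 3, 0, 9)
  expect_true(is.na(deg[["precision"]]))
  expect_identical(deg[["f1"]], 0)
  expect_error(basic_metrics(0, 0, 0, 0), "all counts zero")
})

test_that("macro aggregation equals a brute-force oracle on random matrices", {
  # independent oracle: re-derive every quantity from first principles
  oracle <- function(cm) {
    n <- sum(cm)
    out <- matrix(NA_real_, 4, 5)
    for (i in 1:4) {
      tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
      tn <- n - tp - fn - fp
      acc <- (tp + tn) / n
      pr <- if (tp + fp > 0) tp / (tp + fp) else NA
      rc <- if (tp + fn > 0) tp / (tp + fn) else NA
      sp <- if (tn + fp > 0) tn / (tn + fp) else NA
      f1 <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
        2 * pr * rc / (pr + rc) else 0
      out[i, ] <- c(acc, pr, rc, sp, f1)
    }
    out
  }
  set.seed(17)
  for (i in 1:1000) {
    cm <- matrix(rpois(16, lambda = sample(c(0.5, 3, 20), 1)), 4, 4,
                 dimnames = list(true = class_labels(),
                                 predicted = class_labels()))
    if (sum(cm) == 0) next
    rep_ <- macro_report(cm)
    orc <- oracle(cm)
    expect_equal(unname(rep_$per_class), orc, tolerance = 1e-12)
    expect_equal(unname(rep_$macro), colMeans(orc, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(rep_$micro_accuracy, sum(diag(cm)) / sum(cm))
  }

  # diagonal: every macro metric 1; one class never predicted drags F-1
  d <- diag(c(5L, 5L, 5L, 5L))
  dimnames(d) <- list(true = class_labels(), predicted = class_labels())
  expect_equal(unname(macro_report(d)$macro), rep(1, 5))
  d2 <- d
  d2["arthritis", ] <- c(5L, 0L, 0L, 0L) # arthritis always called normal
  r2 <- macro_report(d2)
  expect_equal(r2$per_class["arthritis", "f1"], 0)
  expect_equal(r2$macro[["f1"]], mean(c(r2$per_class[-3, "f1"], 0)))
})

test_that("trapezoid AUC equals the tie-corrected pairwise rank statistic", {
  rank_auc <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    (sum(outer(sp, sn, ">")) + 0.5 * sum(outer(sp, sn, "=="))) /
      (length(sp) * length(sn))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))$auc, 0.5)

  set.seed(23)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, rank_auc(scores, pos), tolerance = 1e-12)
    # curve endpoints
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
  }
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "at least one")
})

test_that("AUC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:20) {
    scores <- runif(50)
    pos <- runif(50) < 0.4
    if (!any(pos) || all(pos)) next
    ours <- roc_auc(scores, pos)$auc
    theirs <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = pos, predictor = scores, direction = "<"))))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("multiclass one-vs-rest AUC handles one-hot, uniform and absent classes", {
  truth <- rep(class_labels(), times = 5)
  onehot <- matrix(0, 20, 4)
  onehot[cbind(1:20, match(truth, class_labels()))] <- 1
  a <- multiclass_auc(onehot, truth)
  expect_equal(unname(a$per_class), rep(1, 4))
  expect_equal(a$macro, 1)

  unif <- matrix(0.25, 20, 4)
  expect_equal(unname(multiclass_auc(unif, truth)$per_class), rep(0.5, 4))

  # class-0 scores shifted upward: AUC matches brute-force pair counting
  set.seed(3)
  probs <- matrix(runif(160), 40, 4)
  probs <- probs / rowSums(probs)
  truth40 <- sample(class_labels(), 40, replace = TRUE,
                    prob = c(0.4, 0.2, 0.2, 0.2))
  shift <- ifelse(truth40 == "normal", 0.3, 0)
  scores <- probs[, 1] + shift
  pos <- truth40 == "normal"
  brute <- (sum(outer(scores[pos], scores[!pos], ">")) +
              0.5 * sum(outer(scores[pos], scores[!pos], "=="))) /
    (sum(pos) * sum(!pos))
  expect_equal(roc_auc(scores, pos)$auc, brute)

  # absent class excluded from the macro with a warning
  t3 <- truth40[truth40 != "arthritis"]
  p3 <- probs[truth40 != "arthritis", ]
  expect_warning(m3 <- multiclass_auc(p3, t3), "absent")
  expect_true(is.na(m3$per_class[["arthritis"]]))
  expect_false(is.na(m3$macro))
})

test_that("metrics are invariant to sample order", {
  set.seed(41)
  truth <- sample(class_labels(), 60, replace = TRUE)
  pred <- sample(class_labels(), 60, replace = TRUE)
  probs <- matrix(runif(240), 60, 4); probs <- probs / rowSums(probs)
  perm <- sample(60)
  expect_identical(confusion(truth, pred), confusion(truth[perm], pred[perm]))
  expect_equal(multiclass_auc(probs, truth)$per_class,
               multiclass_auc(probs[perm, ], truth[perm])$per_class)
})
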