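# Agreement metrics, ROC/PR curves, top-K recovery.

test_that("perfect and degenerate partitions hit the definitional values", {
  truth <- rep(c("a", "b", "c"), each = 4)
  pred_perm <- rep(c(2, 3, 1), each = 4)   # same partition, renamed
  m <- clustering_metrics(pred_perm, truth)
  expect_equal(unlist(m), c(ari = 1, nmi = 1, homogeneity = 1,
                            completeness = 1))
  single <- clustering_metrics(rep(1, 12), truth)
  expect_equal(single$homogeneity, 0)
  expect_equal(single$completeness, 1)
  expect_error(clustering_metrics(1:3, 1:4), "length")
})

test_that("a fixed 3x2 contingency table matches longhand entropy sums", {
  # contingency: pred {1,2,3} x truth {x,y} with counts 3,1 / 1,2 / 0,3
  pred <- c(rep(1, 4), rep(2, 3), rep(3, 3))
  truth <- c("x", "x", "x", "y", "x", "y", "y", "y", "y", "y")
  m <- clustering_metrics(pred, truth)
  o <- oracle_info_scores(pred, truth)
  expect_equal(m$nmi, o$nmi, tolerance = 1e-12)
  expect_equal(m$homogeneity, o$homogeneity, tolerance = 1e-12)
  expect_equal(m$completeness, o$completeness, tolerance = 1e-12)
  expect_equal(m$ari, oracle_ari(pred, truth), tolerance = 1e-12)
})

test_that("metrics match oracles on randomized instances", {
  set.seed(100)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    pred <- sample(1:4, n, replace = TRUE)
    truth <- sample(letters[1:3], n, replace = TRUE)
    m <- clustering_metrics(pred, truth)
    o <- oracle_info_scores(pred, truth)
    expect_equal(m$ari, oracle_ari(pred, truth), tolerance = 1e-10)
    expect_equal(m$nmi, o$nmi, tolerance = 1e-10)
    expect_equal(m$homogeneity, o$homogeneity, tolerance = 1e-10)
    expect_equal(m$completeness, o$completeness, tolerance = 1e-10)
  }
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(101)
  for (i in 1:10) {
    pred <- sample(1:5, 80, replace = TRUE)
    truth <- sample(1:3, 80, replace = TRUE)
    expect_equal(clustering_metrics(pred, truth)$ari,
                 mclust::adjustedRandIndex(pred, truth), tolerance = 1e-10)
  }
})

test_that("ROC and PR areas match pairwise/step oracles", {
  set.seed(102)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    truth <- runif(n) < 0.3
    if (!any(truth) || all(truth)) next
    score <- rnorm(n) + 2 * truth
    if (i %% 3 == 0) score <- round(score)   # force ties
    expect_equal(roc_auc(score, truth), oracle_roc_auc(score, truth),
                 tolerance = 1e-10)
    expect_equal(pr_auc(score, truth), oracle_pr_auc(score, truth),
                 tolerance = 1e-10)
  }
  # separable scores give area 1
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_equal(pr_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
})

test_that("top-K recovery has the stated endpoints and random behaviour", {
  truth <- rep(c(TRUE, FALSE), c(5, 95))
  perfect <- topk_recovery(seq(100, 1), truth, K = 10)
  expect_equal(perfect$auc, 1)
  none <- topk_recovery(seq(1, 100), truth, K = 10)
  expect_equal(none$auc, 0)
  expect_error(topk_recovery(rnorm(100), rep(FALSE, 100), 10), "no positives")
  expect_error(topk_recovery(rnorm(100), truth, 200), "exceeds")
  # random rankings: prefixes that do catch a positive average near one
  # half; prefixes that catch none score exactly zero by convention
  set.seed(103)
  n <- 1000
  tr <- rep(c(TRUE, FALSE), c(10, n - 10))
  aucs <- vapply(1:100, function(i) topk_recovery(rnorm(n), tr, K = 100)$auc, 0)
  # (the conditional mean sits slightly above 1/2 because prefixes holding
  # more positives also tend to hold them earlier)
  expect_equal(mean(aucs[aucs > 0]), 0.5, tolerance = 0.1)
  expect_gt(sum(aucs == 0), 0)
})

test_that("top-K recovery is invariant to monotone score transforms", {
  set.seed(104)
  score <- rnorm(200)
  truth <- runif(200) < 0.05
  truth[1] <- TRUE
  a <- topk_recovery(score, truth, K = 20)$auc
  expect_equal(topk_recovery(exp(score), truth, K = 20)$auc, a)
  expect_equal(topk_recovery(rank(score), truth, K = 20)$auc, a)
})

test_that("precision/recall/F1 come straight from the confusion counts", {
  m <- cytodeep:::prf_counts(9, 1, 2)
  expect_equal(unname(m["precision"]), 0.9)
  expect_equal(unname(m["recall"]), 9 / 11)
  expect_equal(unname(m["f1"]),
               2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  # no predicted positives: precision reported as 0 by convention
  expect_equal(unname(cytodeep:::prf_counts(0, 0, 5)["precision"]), 0)
})
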