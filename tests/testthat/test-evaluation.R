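test_that("confusion counts cross-tabulate calls against truth and conserve totals", {
  truth <- c(rep(FALSE, 6), rep(TRUE, 4))
  calls <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  cc <- confusionCounts(calls, truth)
  expect_identical(cc, list(TP = 3L, FP = 2L, TN = 4L, FN = 1L))
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, length(truth))

  expect_identical(confusionCounts(truth, truth)[c("FP", "FN")],
                   list(FP = 0L, FN = 0L))
  allCalled <- confusionCounts(rep(TRUE, 10), truth)
  expect_identical(allCalled[c("TP", "FP")], list(TP = 4L, FP = 6L))
  none <- confusionCounts(rep(FALSE, 10), truth)
  expect_identical(none[c("TP", "FP", "FN")], list(TP = 0L, FP = 0L, FN = 4L))
  expect_error(confusionCounts(calls[-1], truth), "length")
})

test_that("basic metrics follow their defining ratios with missing for 0/0", {
  bm <- basicMetrics(list(TP = 50, FP = 10, TN = 10, FN = 30))
  expect_equal(bm$f1, 100 / 140)
  expect_equal(bm$tpr, 50 / 80)
  expect_equal(bm$fpr, 10 / 20)
  expect_equal(bm$fdr, 10 / 60)
  # F1 agrees with the harmonic mean of precision and recall
  prec <- 50 / 60; rec <- 50 / 80
  expect_equal(bm$f1, 2 * prec * rec / (prec + rec))

  perfect <- basicMetrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(perfect), c(tpr = 1, fpr = 0, fdr = 0, f1 = 1))

  empty <- basicMetrics(list(TP = 0, FP = 0, TN = 8, FN = 2))
  expect_true(is.na(empty$fdr))
  expect_equal(empty$tpr, 0)
})

test_that("metric monotonicity: correct calls help, wrong calls hurt", {
  truth <- rep(c(TRUE, FALSE), c(5, 10))
  base <- rep(FALSE, 15); base[1:2] <- TRUE
  b0 <- basicMetrics(confusionCounts(base, truth))
  plusTP <- base; plusTP[3] <- TRUE
  b1 <- basicMetrics(confusionCounts(plusTP, truth))
  expect_gte(b1$tpr, b0$tpr); expect_gte(b1$f1, b0$f1)
  plusFP <- base; plusFP[6] <- TRUE
  b2 <- basicMetrics(confusionCounts(plusFP, truth))
  expect_gte(b2$fpr, b0$fpr)
})

test_that("Mean-Rank and MRSR match direct evaluation and bound at 1", {
  truth <- data.frame(gene_id = paste0("g", 1:10),
                      isDE = c(rep(TRUE, 3), rep(FALSE, 7)))
  # true positives at ranks 1, 3, 5 of the predicted list
  ranked <- c("g1", "g4", "g2", "g5", "g3", "g6")
  mr <- meanRankMRSR(ranked, truth)
  expect_equal(mr$meanRank, 3)
  expect_equal(mr$mrsr, 1.5)

  perfect <- meanRankMRSR(c("g2", "g3", "g1", "g7"), truth)
  expect_identical(perfect$mrsr, 1)

  expect_true(is.na(meanRankMRSR(c("g4", "g5"), truth)$mrsr))

  # prose variant: rank sum divided by the predicted-list length
  alt <- meanRankMRSR(ranked, truth, denominator = "predicted")
  expect_equal(alt$meanRank, 9 / 6)
})

test_that("MRSR is at least 1 whenever a true positive is recovered", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    truth <- data.frame(gene_id = paste0("g", 1:n),
                        isDE = sample(c(TRUE, FALSE), n, replace = TRUE))
    if (!any(truth$isDE)) next
    ranked <- sample(truth$gene_id, sample(seq_len(n), 1))
    mr <- meanRankMRSR(ranked, truth)
    if (!is.na(mr$mrsr)) expect_gte(mr$mrsr, 1)
  }
})

test_that("rank-form AUC equals brute force over all DE x non-DE pairs", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(6:50, 1)
    truth <- c(rep(TRUE, 2), sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    truth[3] <- FALSE
    scores <- sample(0:5, n, replace = TRUE) + rnorm(n, sd = 0.01)
    brute <- mean(outer(scores[truth], scores[!truth],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(rocAuc(scores, truth), brute, tolerance = 1e-12)
  }
})

test_that("AUC honors the tie and separation conventions and rejects one-class truth", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(rocAuc(c(4, 3, 2, 1), truth), 1)
  expect_equal(rocAuc(c(1, 1, 1, 1), truth), 0.5)
  expect_error(rocAuc(1:4, rep(TRUE, 4)), "non-DE")
  curve <- rocCurve(c(4, 3, 2, 1), truth)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve[nrow(curve), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  expect_true(all(diff(curve$tpr) >= 0) && all(diff(curve$fpr) >= 0))
})

test_that("fold-change reference genes use a strict threshold on scaled means", {
  m <- rbind(quad = c(16, 16, 4, 4),     # 4-fold
             dbl  = c(8, 8, 4, 4),       # exactly 2-fold: boundary
             flat = c(6, 6, 6, 6))
  groups <- factor(c("A", "A", "B", "B"))
  ref <- referenceGenesFoldChange(m, groups, threshold = 1,
                                  pseudocount = 0, sizeFactors = rep(1, 4))
  expect_identical(ref$isReference, c(TRUE, FALSE, FALSE))
  expect_equal(ref$log2FC, c(2, 1, 0))
})
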