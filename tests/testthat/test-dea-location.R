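# Welch t, moderated t and regularized t share the log-CPM input; their
# oracles are stats::t.test and direct arithmetic on that matrix.

test_that("Welch t matches stats::t.test gene by gene, including unequal group sizes", {
  fx <- randomCounts(40, n1 = 4, n2 = 3, seed = 11)
  res <- statTTest(fx$m, fx$groups)
  lm2 <- normalizeLogCounts(fx$m)
  for (i in seq_len(nrow(lm2))) {
    tt <- t.test(lm2[i, fx$groups == "A"], lm2[i, fx$groups == "B"])
    expect_equal(res@score[i], abs(unname(tt$statistic)), tolerance = 1e-10)
    expect_equal(res@pValue[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1; degenerate variance follows the convention", {
  # equal column sums so the CPM transform preserves the crafted structure
  m <- rbind(g1 = c(3, 7, 3, 7),        # identical values in both groups
             g2 = c(5, 5, 8, 8),        # zero variance, unequal means
             g3 = c(12, 8, 9, 5))       # balance: every column sums to 20
  groups <- factor(c("A", "A", "B", "B"))
  res <- statTTest(m, groups)
  expect_equal(res@score[1], 0)
  expect_equal(res@pValue[1], 1)
  expect_equal(res@pValue[2], 0)
  called <- callDE(res, alpha = 1e-6)
  expect_true(called@called[2])
  expect_false(called@called[1])
})

test_that("p-values and scores are invariant under swapping the group labels", {
  fx <- randomCounts(30, 3, 3, seed = 5)
  swapped <- factor(ifelse(fx$groups == "A", "B", "A"), levels = c("A", "B"))
  for (stat in list(statTTest, statWilcoxon, statNBWald, statModeratedT)) {
    a <- stat(fx$m, fx$groups)
    b <- stat(fx$m, swapped)
    expect_equal(a@score, b@score, tolerance = 1e-12)
    expect_equal(a@pValue, b@pValue, tolerance = 1e-12)
  }
})

test_that("moderated variance shrinkage follows the posterior formula exactly", {
  # craft one gene with residual variance 5 (groups of 2, dj = 2)
  d <- sqrt(10)
  lm2 <- rbind(g1 = c(0, d, 5, 5 + d),
               g2 = c(1, 1 + d, 9, 9 + d))
  groups <- factor(c("A", "A", "B", "B"))
  model <- fitModeratedVariance(lm2, groups, priorDf = 4, priorVar = 2)
  expect_equal(unname(model@sjSq), c(5, 5))
  # (d0 s0^2 + dj sj^2) / (d0 + dj) = (8 + 10) / 6
  expect_equal(unname(model@sTildeSq), c(3, 3))
  expect_true(all(model@sTildeSq >= pmin(model@s0Sq, model@sjSq) - 1e-12 &
                  model@sTildeSq <= pmax(model@s0Sq, model@sjSq) + 1e-12))
})

test_that("with zero prior degrees of freedom the moderated t is the pooled-variance t", {
  fx <- randomCounts(25, 3, 3, seed = 21)
  res <- statModeratedT(fx$m, fx$groups, priorDf = 0)
  lm2 <- normalizeLogCounts(fx$m)
  for (i in seq_len(nrow(lm2))) {
    tt <- t.test(lm2[i, fx$groups == "A"], lm2[i, fx$groups == "B"],
                 var.equal = TRUE)
    expect_equal(res@score[i], abs(unname(tt$statistic)), tolerance = 1e-10)
    expect_equal(res@pValue[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("homogeneous residual variances are a fixed point of the shrinkage", {
  # all genes share the same pattern, hence the same sj^2
  base <- c(0, sqrt(10), 5, 5 + sqrt(10))
  lm2 <- t(vapply(1:12, function(i) base + i, numeric(4)))
  rownames(lm2) <- paste0("g", 1:12)
  groups <- factor(c("A", "A", "B", "B"))
  model <- fitModeratedVariance(lm2, groups)
  expect_equal(unname(model@sTildeSq), rep(5, 12), tolerance = 1e-6)
})

test_that("a gene with variance far below the prior is shrunk toward it, damping |t|", {
  set.seed(3)
  lm2 <- matrix(rnorm(50 * 6, sd = 2), nrow = 50)
  lm2[1, ] <- c(0, 0.01, 0, 1, 1.01, 1)   # tiny variance, clear shift
  rownames(lm2) <- paste0("g", 1:50)
  groups <- factor(rep(c("A", "B"), each = 3))
  model <- fitModeratedVariance(lm2, groups)
  expect_gt(model@sTildeSq[1], model@sjSq[1])
  ordinaryT <- abs(diff(tapply(lm2[1, ], groups, mean))) /
    sqrt(model@sjSq[1] * (1 / 3 + 1 / 3))
  moderatedT <- abs(diff(tapply(lm2[1, ], groups, mean))) /
    sqrt(model@sTildeSq[1] * (1 / 3 + 1 / 3))
  expect_lt(moderatedT, ordinaryT)
})

test_that("moderated t agrees with limma when limma's hyperparameters are imposed", {
  skip_if_not_installed("limma")
  fx <- randomCounts(60, 4, 4, seed = 31)
  lm2 <- normalizeLogCounts(fx$m)
  design <- cbind(Intercept = 1, A = as.integer(fx$groups == "A"))
  eb <- limma::eBayes(limma::lmFit(lm2, design))
  res <- statModeratedT(fx$m, fx$groups, priorDf = eb$df.prior,
                        priorVar = eb$s2.prior)
  expect_equal(res@score, abs(eb$t[, "A"]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # limma caps its total df at the pooled residual df; p-values therefore
  # agree only approximately while the statistics agree exactly
  expect_equal(res@pValue, eb$p.value[, "A"], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("regularized t with s0 = 0 matches the pooled spread formula by hand", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  groups <- factor(rep(c("A", "B"), each = 3))
  res <- statRegularizedT(m, groups, s0 = 0, normalize = FALSE)
  # s(i) = sqrt((1/4)(1/3+1/3)(2+2)); t = -3 / s(i)
  expect_equal(res@score[1], 3 / sqrt((1 / 4) * (2 / 3) * 4),
               tolerance = 1e-12)
})

test_that("regularized t collapses to zero as s0 grows and matches pooled t at s0 = 0", {
  fx <- randomCounts(20, 3, 3, seed = 41)
  res0 <- statRegularizedT(fx$m, fx$groups, s0 = 0)
  lm2 <- normalizeLogCounts(fx$m)
  for (i in seq_len(nrow(lm2))) {
    tt <- t.test(lm2[i, fx$groups == "A"], lm2[i, fx$groups == "B"],
                 var.equal = TRUE)
    expect_equal(res0@score[i], abs(unname(tt$statistic)), tolerance = 1e-10)
  }
  resBig <- statRegularizedT(fx$m, fx$groups, s0 = 1e9)
  expect_true(all(resBig@score < 1e-6))
})

test_that("regularized-t permutation p-values are valid and rank with the scores", {
  fx <- randomCounts(80, 4, 4, seed = 51)
  res <- statRegularizedT(fx$m, fx$groups)
  expect_true(all(res@pValue > 0 & res@pValue <= 1))
  # p decreases as |t| increases (pooled null is shared across genes)
  ord <- order(res@score)
  expect_true(all(diff(res@pValue[ord]) <= 1e-12))
  # the "median" rule pins s0 at the median pooled spread, computed by hand
  lm2 <- normalizeLogCounts(fx$m)
  spread <- apply(lm2, 1, function(y) {
    a <- y[fx$groups == "A"]; b <- y[fx$groups == "B"]
    sqrt((1 / (length(y) - 2)) * (1 / length(a) + 1 / length(b)) *
           (sum((a - mean(a))^2) + sum((b - mean(b))^2)))
  })
  resMed <- statRegularizedT(fx$m, fx$groups, s0Method = "median")
  expect_equal(resMed@decisionRule$s0, median(spread), tolerance = 1e-12)
})
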