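# Wilcoxon rank-sum and the NB Wald statistic operate on (scaled) counts.

test_that("exact Wilcoxon p-values match enumeration on the smallest designs", {
  # {1,2} vs {3,4}: most extreme of C(4,2)=6 arrangements, two-sided p = 2/6
  m <- rbind(g1 = c(1, 2, 3, 4))
  groups <- factor(c("A", "A", "B", "B"))
  res <- statWilcoxon(m, groups)
  expect_equal(res@pValue[1], 2 / 6, tolerance = 1e-12)

  # K = 3, perfect separation: p = 2 / C(6,3) = 2/20 > 0.05
  m3 <- rbind(g1 = c(1, 2, 3, 10, 11, 12))
  g3 <- factor(rep(c("A", "B"), each = 3))
  res3 <- statWilcoxon(m3, g3)
  expect_equal(res3@pValue[1], 2 / 20, tolerance = 1e-12)
  expect_false(callDE(res3, alpha = 0.05)@called[1])
})

test_that("with K <= 3 replicates the exact Wilcoxon test never rejects at the 5% level", {
  # continuous draws guarantee no ties, so the exact enumeration null
  # applies and the attainable p-value floor is 2 / choose(2K, K) > 0.05
  for (K in 2:3) {
    se <- simulateTweedieData(SimulationConfig(
      nNull = 100, nUp = 30, nDown = 30, kReplicates = K, seed = 60 + K,
      roundToInteger = FALSE))
    res <- callDE(statWilcoxon(se), alpha = 0.05)
    expect_identical(sum(res@called), 0L)
    expect_gte(min(res@pValue), 2 / choose(2 * K, K))
  }
})

test_that("completely tied genes get p = 1", {
  m <- rbind(g1 = rep(7, 6))
  groups <- factor(rep(c("A", "B"), each = 3))
  expect_equal(statWilcoxon(m, groups)@pValue[1], 1)
})

test_that("Wilcoxon agrees with stats::wilcox.test with and without ties", {
  fx <- randomCounts(60, 5, 5, lambda = 4, seed = 71)  # low lambda: many ties
  res <- statWilcoxon(fx$m, fx$groups)
  for (i in seq_len(nrow(fx$m))) {
    wt <- suppressWarnings(
      wilcox.test(fx$m[i, fx$groups == "A"], fx$m[i, fx$groups == "B"]))
    expect_equal(res@pValue[i], wt$p.value, tolerance = 1e-10)
  }
})

test_that("NB Wald gives z = 0, p = 1 for identical group means after scaling", {
  m <- matrix(rep(c(6, 11, 3), 4), nrow = 3)
  rownames(m) <- paste0("g", 1:3)
  groups <- factor(rep(c("A", "B"), each = 2))
  res <- statNBWald(m, groups)
  expect_equal(res@score, rep(0, 3), ignore_attr = TRUE)
  expect_equal(res@pValue, rep(1, 3), ignore_attr = TRUE)
})

test_that("NB Wald matches the delta-method arithmetic on a hand-set toy gene", {
  m <- rbind(g1 = c(10, 14, 30, 26))
  groups <- factor(c("A", "A", "B", "B"))
  res <- statNBWald(m, groups, sizeFactors = rep(1, 4), dispersionShrink = 0,
                    pseudocount = 0.5)
  # group means 12 and 28, variances 8 and 8; both moment dispersions are
  # negative so the floored dispersion is 0 and Var = mu
  lfc <- log2(12.5 / 28.5)
  se2 <- (12 / 2) / (12.5^2 * log(2)^2) + (28 / 2) / (28.5^2 * log(2)^2)
  expect_equal(res@score[1], abs(lfc / sqrt(se2)), tolerance = 1e-12)
  expect_equal(res@pValue[1], 2 * pnorm(-abs(lfc / sqrt(se2))),
               tolerance = 1e-12)
})

test_that("NB Wald propagates the size-factor error on unfilterable matrices", {
  m <- rbind(g1 = c(0, 3, 1, 2), g2 = c(4, 0, 2, 2))
  groups <- factor(c("A", "A", "B", "B"))
  expect_error(statNBWald(m, groups), "filter")
})
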