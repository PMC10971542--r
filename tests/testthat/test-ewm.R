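# Independent hand evaluation of the min-max / entropy / weight chain.
handEWM <- function(x, dirs) {
  norm <- x
  for (j in seq_len(ncol(x))) {
    r <- range(x[, j])
    norm[, j] <- if (dirs[j] == "benefit") (x[, j] - r[1]) / diff(r)
                 else (r[2] - x[, j]) / diff(r)
  }
  e <- apply(norm, 2, function(v) {
    p <- v / sum(v)
    -sum(ifelse(p > 0, p * log(p), 0)) / log(nrow(x))
  })
  w <- (1 - e) / sum(1 - e)
  raw <- as.vector(norm %*% w)
  list(w = w, comp = (raw - min(raw)) / diff(range(raw)) * 100)
}

test_that("EWM weights and composites match a step-by-step hand computation", {
  panel <- rbind(A = c(tpr = 0.9, fpr = 0.03),
                 B = c(tpr = 0.6, fpr = 0.02),
                 C = c(tpr = 0.4, fpr = 0.10))
  res <- ewmComposite(panel)
  hand <- handEWM(panel, c("benefit", "cost"))
  expect_equal(unname(ewmWeights(res)), unname(hand$w), tolerance = 1e-12)
  expect_equal(unname(ewmScores(res)), hand$comp, tolerance = 1e-10)
  expect_equal(sum(ewmWeights(res)), 1, tolerance = 1e-12)
  expect_true(all(ewmScores(res) >= 0 & ewmScores(res) <= 100))
  expect_equal(unname(range(ewmScores(res))), c(0, 100))
})

test_that("a constant metric column gets zero weight; all-constant panels fail", {
  panel <- rbind(A = c(m1 = 0.5, m2 = 0.9),
                 B = c(m1 = 0.5, m2 = 0.2),
                 C = c(m1 = 0.5, m2 = 0.4))
  expect_message(res <- ewmComposite(
    panel, c(m1 = "benefit", m2 = "benefit")), "constant")
  expect_equal(unname(ewmWeights(res)), c(0, 1))

  flat <- rbind(A = c(m1 = 1, m2 = 2), B = c(m1 = 1, m2 = 2))
  expect_error(ewmComposite(flat, c(m1 = "benefit", m2 = "benefit")),
               "unscorable")
})

test_that("row permutation permutes composites identically", {
  set.seed(31)
  panel <- matrix(runif(12), 4, 3,
                  dimnames = list(paste0("m", 1:4), c("tpr", "f1", "fpr")))
  res <- ewmComposite(panel)
  perm <- c(3, 1, 4, 2)
  resPerm <- ewmComposite(panel[perm, ])
  expect_equal(ewmScores(resPerm), ewmScores(res)[perm])
})

test_that("a dominating method scores 100 and a dominated one 0", {
  panel <- rbind(best = c(tpr = 0.95, f1 = 0.9, fpr = 0.01),
                 mid = c(tpr = 0.7, f1 = 0.6, fpr = 0.05),
                 worst = c(tpr = 0.3, f1 = 0.2, fpr = 0.20))
  sc <- ewmScores(ewmComposite(panel))
  expect_equal(unname(sc["best"]), 100)
  expect_equal(unname(sc["worst"]), 0)
})

test_that("rescaling one metric column leaves the result unchanged", {
  set.seed(37)
  panel <- matrix(runif(12, 0.2, 0.9), 4, 3,
                  dimnames = list(paste0("m", 1:4), c("tpr", "f1", "fpr")))
  res <- ewmComposite(panel)
  panel2 <- panel
  panel2[, "f1"] <- panel2[, "f1"] * 7.3
  expect_equal(ewmScores(ewmComposite(panel2)), ewmScores(res),
               tolerance = 1e-10)
})

test_that("missing cells are imputed with the column's worst value", {
  panel <- rbind(A = c(tpr = 0.9, fpr = 0.03),
                 B = c(tpr = NA, fpr = 0.02),
                 C = c(tpr = 0.4, fpr = 0.10))
  expect_message(res <- ewmComposite(panel), "imputing")
  ref <- panel; ref["B", "tpr"] <- 0.4
  expect_equal(ewmScores(res), ewmScores(suppressMessages(ewmComposite(ref))))
})
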