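#' Available differential-expression statistics
#'
#' Names accepted by [runDEAMethod()] and [BenchmarkConfig()]:
#' `"ttest"` (Welch t on log-CPM), `"wilcoxon"` (rank-sum on raw counts),
#' `"nbwald"` (negative-binomial Wald with median-of-ratios size factors),
#' `"moderated_t"` (empirical-Bayes moderated t on log-CPM),
#' `"regularized_t"` (SAM-style regularized t with permutation p-values),
#' and `"def"` (entropy-based DEF score; no p-value, called by top-P).
#'
#' @return character vector of method names.
#' @export
deaMethods <- function() {
  c("ttest", "wilcoxon", "nbwald", "moderated_t", "regularized_t", "def")
}

#' Run one DEA statistic by name and apply its decision rule
#'
#' Dispatches to the `stat*` function for `method` and then applies the
#' appropriate decision rule with [callDE()]: `p < alpha` for p-value methods,
#' top-P by score for the DEF statistic.
#'
#' @param method one of [deaMethods()].
#' @param x count matrix or `SummarizedExperiment`.
#' @param groups two-level factor over samples (taken from `colData(x)$group`
#'   when `x` is a `SummarizedExperiment`).
#' @param alpha significance level for p-value methods.
#' @param topP top-P rule size for the DEF statistic.
#' @param ... passed to the underlying `stat*` function.
#' @return a called [DEAResult-class].
#' @export
runDEAMethod <- function(method, x, groups = NULL, alpha = 0.05, topP = 1000,
                         ...) {
  method <- match.arg(method, deaMethods())
  res <- switch(method,
    ttest = statTTest(x, groups, ...),
    wilcoxon = statWilcoxon(x, groups, ...),
    nbwald = statNBWald(x, groups, ...),
    moderated_t = statModeratedT(x, groups, ...),
    regularized_t = statRegularizedT(x, groups, ...),
    def = statDEFEntropy(x, ...))
  if (method == "def") callDE(res, topP = topP) else callDE(res, alpha = alpha)
}

.groupIdx <- function(groups) {
  list(g1 = which(groups == levels(groups)[1L]),
       g2 = which(groups == levels(groups)[2L]))
}

.rowVar <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Welch two-sample t-test on log-CPM values
#'
#' Per gene, \eqn{t = (\bar x_1 - \bar x_2) / \sqrt{s_1^2/N_1 + s_2^2/N_2}}
#' computed on [normalizeLogCounts()] values, with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. The evidence score is
#' \eqn{|t|}. When both group variances vanish the statistic is degenerate:
#' equal means give p = 1, unequal means p = 0 (infinite evidence).
#'
#' @inheritParams runDEAMethod
#' @param pseudocount pseudocount for the log-CPM transform.
#' @return an uncalled [DEAResult-class] with scores and p-values.
#' @export
statTTest <- function(x, groups = NULL, pseudocount = 1) {
  groups <- .resolveGroups(x, groups)
  lm2 <- normalizeLogCounts(x, pseudocount)
  gi <- .groupIdx(groups)
  a <- lm2[, gi$g1, drop = FALSE]; b <- lm2[, gi$g2, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- .rowVar(a); v2 <- .rowVar(b)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                  ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- ifelse(is.finite(tstat) & se2 > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(se2 > 0, NA_real_,  # unreachable; keeps shape
                     ifelse(m1 == m2, 1, 0)))
  p[!is.finite(tstat)] <- 0
  .DEAResult("ttest", rownames(lm2), abs(tstat), p)
}

#' Wilcoxon rank-sum test on raw counts
#'
#' Per gene, the two-sided Mann-Whitney test of the two sample groups. With
#' at most 10 samples in total and no tied counts the exact enumeration null
#' is used; otherwise the normal approximation with midranks, tie correction,
#' and continuity correction (matching `stats::wilcox.test`). The evidence
#' score is `1 - p`. With K <= 3 replicates per group the smallest attainable
#' exact two-sided p-value is `2 / choose(2K, K) > 0.05`, so the test can
#' never reject at the 5% level — the small-replicate failure mode this
#' package quantifies.
#'
#' @inheritParams runDEAMethod
#' @return an uncalled [DEAResult-class].
#' @export
statWilcoxon <- function(x, groups = NULL) {
  groups <- .resolveGroups(x, groups)
  m <- .validateCounts(.asCountMatrix(x))
  gi <- .groupIdx(groups)
  n1 <- length(gi$g1); n2 <- length(gi$g2); N <- n1 + n2
  ord <- c(gi$g1, gi$g2)
  p <- apply(m[, ord, drop = FALSE], 1L, function(y) {
    r <- rank(y)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(y)
    if (N <= 10L && all(ties == 1L)) {
      pr <- if (U > n1 * n2 / 2)
        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(U, n1, n2)
      min(2 * pr, 1)
    } else {
      z <- U - n1 * n2 / 2
      sigma2 <- (n1 * n2 / 12) *
        ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      if (sigma2 <= 0) return(1)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      min(2 * stats::pnorm(-abs(z)), 1)
    }
  })
  .DEAResult("wilcoxon", rownames(m), 1 - p, p)
}

#' Negative-binomial Wald test with size factors
#'
#' Counts are scaled by [estimateSizeFactors()] factors. Per gene, the NB
#' dispersion is estimated by the method of moments on the scaled counts
#' within each group, \eqn{\Phi_k = (v_k - m_k) / m_k^2}, pooled across the
#' two groups with degree-of-freedom weights and floored at 0, then shrunk
#' (weight `dispersionShrink` toward a log-log linear mean-dispersion trend
#' fitted across genes, a simplified information-borrowing step). The tested
#' effect is the log2 fold change of the scaled group means (with
#' `pseudocount`); its standard error follows from the NB variance function
#' \eqn{Var = \mu + \Phi \mu^2} by the delta method:
#' \deqn{SE^2 = \sum_k \frac{(m_k + \Phi m_k^2)/n_k}{(m_k + c)^2 \ln^2 2}.}
#' The Wald statistic z = log2FC / SE is referred to the standard normal;
#' score = |z|.
#'
#' @inheritParams runDEAMethod
#' @param sizeFactors optional per-sample factors overriding the
#'   median-of-ratios estimate.
#' @param dispersionShrink weight in \[0,1\] on the fitted trend (0 = raw
#'   moment estimates; ignored when fewer than 10 genes inform the trend).
#' @param pseudocount offset protecting the fold change at zero means.
#' @return an uncalled [DEAResult-class].
#' @export
statNBWald <- function(x, groups = NULL, sizeFactors = NULL,
                       dispersionShrink = 0.5, pseudocount = 0.5) {
  groups <- .resolveGroups(x, groups)
  m <- .validateCounts(.asCountMatrix(x))
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(m)
  if (length(sizeFactors) != ncol(m) || any(sizeFactors <= 0))
    stop("'sizeFactors' must be one positive factor per sample")
  sc <- sweep(m, 2L, sizeFactors, "/")
  gi <- .groupIdx(groups)
  a <- sc[, gi$g1, drop = FALSE]; b <- sc[, gi$g2, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- .rowVar(a); v2 <- .rowVar(b)
  d1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
  d2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, 0)
  disp <- pmax(0, ((n1 - 1) * d1 + (n2 - 1) * d2) / (n1 + n2 - 2))
  baseMean <- rowMeans(sc)
  use <- disp > 0 & baseMean > 0
  if (dispersionShrink > 0 && sum(use) >= 10L) {
    fit <- stats::lm.fit(cbind(1, log(baseMean[use])), log(disp[use]))
    trend <- exp(fit$coefficients[1L] +
                 fit$coefficients[2L] * log(pmax(baseMean, min(baseMean[use]))))
    disp <- (1 - dispersionShrink) * disp + dispersionShrink * trend
  }
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  se2 <- ((m1 + disp * m1^2) / n1) / ((m1 + pseudocount)^2 * log(2)^2) +
         ((m2 + disp * m2^2) / n2) / ((m2 + pseudocount)^2 * log(2)^2)
  z <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- ifelse(is.finite(z), 2 * stats::pnorm(-abs(z)), 0)
  p[se2 == 0 & lfc == 0] <- 1
  .DEAResult("nbwald", rownames(m), abs(z), p)
}

# Newton inversion of the trigamma function (for the moment estimator of the
# prior degrees of freedom).
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Fit the empirical-Bayes moderated variance model
#'
#' For each gene a two-group linear model on the supplied log-scale matrix
#' yields the residual variance \eqn{s_j^2} with \eqn{d_j = n - 2} degrees of
#' freedom. The hyperparameters \eqn{d_0} (prior degrees of freedom) and
#' \eqn{s_0^2} (prior variance) are estimated by the method of moments on
#' \eqn{\log s_j^2}, using the mean and excess variance of
#' \eqn{e_j = \log s_j^2 - \psi(d_j/2) + \log(d_j/2)} and inverting the
#' trigamma function. When the moment estimate diverges (residual variances
#' essentially homogeneous) \eqn{d_0} is capped at 10 times the gene count.
#' Shrunken variances are
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_j s_j^2)/(d_0 + d_j)}, which always lie
#' between \eqn{s_0^2} and \eqn{s_j^2}.
#'
#' @param logMatrix gene-by-sample matrix of log-scale values.
#' @param groups two-level factor over columns.
#' @param priorDf,priorVar optional fixed hyperparameters bypassing
#'   estimation (with `priorDf = 0` the shrunken variances equal the raw
#'   residual variances and the moderated t degenerates to the ordinary
#'   pooled-variance t).
#' @return a [ModeratedVarianceModel-class].
#' @export
fitModeratedVariance <- function(logMatrix, groups, priorDf = NULL,
                                 priorVar = NULL) {
  groups <- .resolveGroups(logMatrix, groups)
  lm2 <- as.matrix(logMatrix)
  gi <- .groupIdx(groups)
  a <- lm2[, gi$g1, drop = FALSE]; b <- lm2[, gi$g2, drop = FALSE]
  n <- ncol(lm2)
  dj <- n - 2
  sjSq <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / dj
  if (is.null(priorDf)) {
    if (nrow(lm2) < 10L)
      stop("need at least 10 genes to estimate the variance prior; ",
           "supply priorDf/priorVar for smaller problems")
    ok <- sjSq > 0
    e <- log(sjSq[ok]) - digamma(dj / 2) + log(dj / 2)
    eBar <- mean(e)
    ve <- stats::var(e)
    rhs <- ve - trigamma(dj / 2)
    if (!is.finite(rhs) || rhs <= 0) {
      # residual variances (log-scale) no more dispersed than chi-square
      # noise allows: treat them as homogeneous around their geometric mean
      d0 <- 10 * nrow(lm2)
      s0Sq <- exp(mean(log(sjSq[ok])))
    } else {
      d0 <- min(2 * .trigammaInverse(rhs), 10 * nrow(lm2))
      s0Sq <- exp(eBar + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- priorDf
    s0Sq <- if (is.null(priorVar)) {
      if (d0 > 0) stop("'priorVar' required when priorDf > 0")
      0
    } else priorVar
  }
  sTildeSq <- if (d0 == 0) sjSq else (d0 * s0Sq + dj * sjSq) / (d0 + dj)
  new("ModeratedVarianceModel", d0 = d0, s0Sq = s0Sq,
      dj = rep(dj, nrow(lm2)), sjSq = sjSq, sTildeSq = sTildeSq)
}

#' Empirical-Bayes moderated t-statistic
#'
#' The two-group linear-model coefficient (difference of group means of
#' log-CPM values) divided by its standard error with the residual variance
#' replaced by the shrunken variance from [fitModeratedVariance()]:
#' \eqn{\tilde t = \hat\beta / (u \tilde s)} with
#' \eqn{u = \sqrt{1/N_1 + 1/N_2}}. Two-sided p-values use a t reference with
#' \eqn{d_0 + d_j} degrees of freedom; score = \eqn{|\tilde t|}. With
#' `priorDf = 0` the statistic equals the ordinary pooled-variance t.
#'
#' @inheritParams statTTest
#' @param priorDf,priorVar optional fixed hyperparameters, see
#'   [fitModeratedVariance()].
#' @return an uncalled [DEAResult-class].
#' @export
statModeratedT <- function(x, groups = NULL, pseudocount = 1,
                           priorDf = NULL, priorVar = NULL) {
  groups <- .resolveGroups(x, groups)
  lm2 <- normalizeLogCounts(x, pseudocount)
  model <- fitModeratedVariance(lm2, groups, priorDf, priorVar)
  gi <- .groupIdx(groups)
  n1 <- length(gi$g1); n2 <- length(gi$g2)
  beta <- rowMeans(lm2[, gi$g1, drop = FALSE]) -
          rowMeans(lm2[, gi$g2, drop = FALSE])
  u <- sqrt(1 / n1 + 1 / n2)
  s <- sqrt(model@sTildeSq)
  tstat <- ifelse(s > 0, beta / (u * s), ifelse(beta == 0, 0, Inf * sign(beta)))
  df <- model@d0 + model@dj
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df), 0)
  p[s == 0 & beta == 0] <- 1
  .DEAResult("moderated_t", rownames(lm2), abs(tstat), p)
}

# All (or up to nMax sampled) assignments of n1 of n samples to group 1,
# returned as an n x nPerm 0/1 membership matrix whose first column is the
# observed assignment.
.permMatrix <- function(n, n1, idx1, nMax) {
  total <- choose(n, n1)
  if (total <= nMax) {
    sel <- utils::combn(n, n1)
  } else {
    sel <- replicate(nMax - 1L, sort(sample.int(n, n1)))
    sel <- cbind(sort(idx1), sel)
  }
  memb <- matrix(0, n, ncol(sel))
  memb[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = n1))] <- 1
  # put the observed assignment first
  obs <- which(colSums(memb[idx1, , drop = FALSE]) == n1)[1L]
  memb[, c(obs, setdiff(seq_len(ncol(memb)), obs)), drop = FALSE]
}

#' SAM-style regularized t-statistic
#'
#' Per gene, \eqn{t = (\bar x_A - \bar x_B) / (s_0 + s(i))} on log-CPM
#' values, where \eqn{s(i)} is the pooled spread
#' \deqn{s(i) = \sqrt{\tfrac{1}{m+n-2}\left(\tfrac1m + \tfrac1n\right)
#'   \left[\sum_A (x - \bar x_A)^2 + \sum_B (x - \bar x_B)^2\right]}}
#' and the regularizing constant \eqn{s_0} damps the spuriously large
#' statistics of genes with tiny variance. By default \eqn{s_0} is chosen
#' data-adaptively: candidates are the 0th, 5th, ..., 100th percentiles of
#' \eqn{\{s(i)\}}, and the candidate minimizing the coefficient of variation
#' of the statistic's median absolute deviation across 100 spread-ordered
#' gene windows is selected (`s0Method = "median"` instead uses the median
#' spread; `s0` fixes it directly).
#'
#' P-values come from a pooled gene-wise label-permutation null: statistics
#' are recomputed (with the same \eqn{s_0}) under all distinct group-label
#' assignments when there are at most `nPermutations` of them, otherwise
#' under `nPermutations` sampled assignments, and each gene's two-sided
#' p-value is the fraction of the pooled permuted \eqn{|t^*|} at least as
#' large as its observed \eqn{|t|}. Score = \eqn{|t|}.
#'
#' @inheritParams statTTest
#' @param s0 optional fixed regularization constant (0 recovers the plain
#'   pooled-variance statistic).
#' @param s0Method `"cv"` (window-CV search) or `"median"`.
#' @param nPermutations cap on label permutations for the null.
#' @param normalize log-CPM-transform the counts first (disable to run the
#'   statistic on the values as given).
#' @return an uncalled [DEAResult-class].
#' @export
statRegularizedT <- function(x, groups = NULL, pseudocount = 1, s0 = NULL,
                             s0Method = c("cv", "median"),
                             nPermutations = 500, normalize = TRUE) {
  s0Method <- match.arg(s0Method)
  groups <- .resolveGroups(x, groups)
  lm2 <- if (normalize) normalizeLogCounts(x, pseudocount)
         else .asCountMatrix(x)
  gi <- .groupIdx(groups)
  n1 <- length(gi$g1); n2 <- length(gi$g2); n <- n1 + n2
  cc <- (1 / (n - 2)) * (1 / n1 + 1 / n2)

  statFor <- function(memb1) {                 # memb1: n x P matrix of 0/1
    memb2 <- 1 - memb1
    ma <- (lm2 %*% memb1) / n1
    mb <- (lm2 %*% memb2) / n2
    sq <- lm2^2
    ss <- cc * ((sq %*% memb1) - n1 * ma^2 + (sq %*% memb2) - n2 * mb^2)
    ss[ss < 0] <- 0                 # numerical noise below zero
    list(r = ma - mb, s = sqrt(ss))
  }
  obs1 <- matrix(0, n, 1); obs1[gi$g1, 1] <- 1
  obs <- statFor(obs1)
  r <- obs$r[, 1L]; s <- obs$s[, 1L]

  if (is.null(s0)) {
    if (s0Method == "median") {
      s0 <- stats::median(s)
    } else {
      cand <- unique(stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE))
      nw <- min(100L, max(2L, floor(length(s) / 5)))
      win <- cut(rank(s, ties.method = "first"), nw, labels = FALSE)
      cv <- vapply(cand, function(a) {
        d <- r / (a + s)
        mads <- tapply(d, win, stats::mad)
        mads <- mads[is.finite(mads) & mads > 0]
        if (length(mads) < 2L) return(Inf)
        stats::sd(mads) / mean(mads)
      }, numeric(1))
      s0 <- cand[which.min(cv)]
    }
  }
  tstat <- ifelse(s0 + s > 0, r / (s0 + s), ifelse(r == 0, 0, Inf * sign(r)))

  memb <- .permMatrix(n, n1, gi$g1, nPermutations)
  perm <- statFor(memb)
  tperm <- abs(perm$r / (s0 + perm$s))
  tperm[!is.finite(tperm)] <- Inf
  pooled <- sort(as.vector(tperm))
  np <- length(pooled)
  # p = fraction of pooled permuted |t*| >= observed |t|
  p <- (np - findInterval(abs(tstat) - 1e-12, pooled)) / np
  p[!is.finite(tstat)] <- 1 / np
  res <- .DEAResult("regularized_t", rownames(lm2), abs(tstat), pmin(p, 1))
  res@decisionRule <- list(type = "none", s0 = s0)
  res
}

#' Entropy-based DEF statistic
#'
#' The label-free differential-entropy-like function. Counts are first
#' normalized per sample (each value divided by its sample's total count) to
#' remove sequencing depth; for each gene the normalized values are turned
#' into proportions \eqn{p_j} over the n samples, and
#' \deqn{Ent(Y) = 1 - \frac{-\sum_j p_j \log p_j}{\log n} \in [0, 1].}
#' A gene expressed uniformly across samples scores exactly 0; a gene
#' expressed in a single sample scores 1. The statistic uses no group labels
#' and yields no p-value; calls are made by the top-P rule. The logarithm
#' base cancels between numerator and denominator. Genes with zero total
#' normalized count have undefined proportions; they get an NA score, are
#' never called, and are reported as skipped.
#'
#' @inheritParams runDEAMethod
#' @return an uncalled [DEAResult-class] with scores only.
#' @export
statDEFEntropy <- function(x, groups = NULL) {
  m <- .validateCounts(.asCountMatrix(x))
  libSizes <- colSums(m)
  if (any(libSizes == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[libSizes == 0], collapse = ", "))
  yt <- sweep(m, 2L, libSizes, "/")
  tot <- rowSums(yt)
  p <- yt / tot
  plogp <- p * log(p)
  plogp[p == 0] <- 0              # 0 * log 0 := 0
  ent <- 1 - (-rowSums(plogp)) / log(ncol(m))
  ent <- pmin(pmax(ent, 0), 1)    # clamp roundoff at the range bounds
  ent[tot == 0] <- NA_real_
  .DEAResult("def", rownames(m), ent)
}

#' Apply a decision rule to a DEA result
#'
#' Exactly one of `alpha` and `topP` must be given. The `alpha` rule calls
#' genes with `p < alpha` (strict). The `topP` rule calls the P genes with
#' the largest scores among genes with a defined score, breaking score ties
#' by input gene order (deterministic); P is clipped to the number of scored
#' genes with a warning when it exceeds it.
#'
#' @param result a [DEAResult-class].
#' @param alpha significance level for the p-value rule.
#' @param topP number of top-scoring genes to call.
#' @return the result with `called` flags and the decision rule recorded.
#' @export
callDE <- function(result, alpha = NULL, topP = NULL) {
  stopifnot(is(result, "DEAResult"))
  if (is.null(alpha) == is.null(topP))
    stop("supply exactly one of 'alpha' and 'topP'")
  if (!is.null(alpha)) {
    if (all(is.na(result@pValue)))
      stop("method '", result@method, "' yields no p-values; use topP")
    called <- !is.na(result@pValue) & result@pValue < alpha
    result@decisionRule <- c(list(type = "alpha", alpha = alpha),
                             result@decisionRule[
                               setdiff(names(result@decisionRule), "type")])
  } else {
    scored <- which(!is.na(result@score))
    if (topP > length(result@geneIds)) {
      warning("topP = ", topP, " exceeds the number of genes; clipping")
      topP <- length(result@geneIds)
    }
    k <- min(topP, length(scored))
    ord <- scored[order(-result@score[scored], seq_along(scored))]
    called <- logical(length(result@geneIds))
    called[ord[seq_len(k)]] <- TRUE
    result@decisionRule <- c(list(type = "topP", P = topP),
                             result@decisionRule[
                               setdiff(names(result@decisionRule), "type")])
  }
  result@called <- called
  validObject(result)
  result
}
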