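#' Entropy-weight-method composite scores
#'
#' Combines a method-by-metric panel into one comprehensive score per method.
#' Benefit metrics (larger is better: TPR, F1, AUC) are min-max normalized
#' ascending, cost metrics (FPR, MRSR) descending, so every normalized value
#' lies in \[0,1\] with 1 best. Column proportions
#' \eqn{p_{ij} = x'_{ij} / \sum_i x'_{ij}} give each metric's entropy
#' \eqn{e_j = -\frac{1}{\ln m} \sum_i p_{ij} \ln p_{ij}} (with
#' \eqn{0 \ln 0 := 0}); weights \eqn{w_j = (1-e_j)/\sum_j (1-e_j)} put more
#' weight on metrics that discriminate more between methods. Composites
#' \eqn{\sum_j w_j x'_{ij}} are min-max rescaled to a 0-100 scale, so the
#' best and worst methods score 100 and 0.
#'
#' A metric column constant across methods carries no information: it gets
#' weight 0 (with a message). If every column is constant the panel is
#' unscorable and an error is raised. Missing cells are imputed with the
#' column's worst observed value (with a message).
#'
#' @param panel numeric matrix or data.frame, methods as rows (rownames =
#'   method names), metrics as columns.
#' @param directions named character vector over the panel's columns with
#'   values `"benefit"` or `"cost"`; defaults classify `fpr`, `mrsr`,
#'   `fdr` and `mean_rank` as cost and everything else as benefit.
#' @return an [EWMResult-class].
#' @examples
#' panel <- rbind(A = c(tpr = 0.9, fpr = 0.04),
#'                B = c(tpr = 0.7, fpr = 0.02),
#'                C = c(tpr = 0.5, fpr = 0.10))
#' ewmComposite(panel)
#' @export
ewmComposite <- function(panel, directions = NULL) {
  x <- as.matrix(panel)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 methods and 2 metrics")
  if (is.null(rownames(x))) rownames(x) <- paste0("method_", seq_len(nrow(x)))
  if (is.null(colnames(x))) stop("panel columns must be named metrics")
  if (is.null(directions)) {
    directions <- ifelse(colnames(x) %in% c("fpr", "mrsr", "fdr", "mean_rank"),
                         "cost", "benefit")
    names(directions) <- colnames(x)
  }
  if (!all(colnames(x) %in% names(directions)))
    stop("'directions' must cover every panel column")
  directions <- directions[colnames(x)]
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'")

  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) {
        if (all(miss))
          stop("metric '", colnames(x)[j], "' is entirely missing")
        worst <- if (directions[j] == "benefit") min(x[, j], na.rm = TRUE)
                 else max(x[, j], na.rm = TRUE)
        message("imputing ", sum(miss), " missing value(s) in '",
                colnames(x)[j], "' with the column's worst value")
        x[miss, j] <- worst
      }
    }
  }

  rng <- apply(x, 2L, function(v) diff(range(v)))
  if (all(rng == 0))
    stop("every metric is constant across methods; panel is unscorable")
  norm <- x
  for (j in seq_len(ncol(x))) {
    if (rng[j] == 0) {
      message("metric '", colnames(x)[j],
              "' is constant across methods; weight 0")
      norm[, j] <- 0
    } else if (directions[j] == "benefit") {
      norm[, j] <- (x[, j] - min(x[, j])) / rng[j]
    } else {
      norm[, j] <- (max(x[, j]) - x[, j]) / rng[j]
    }
  }

  m <- nrow(norm)
  entropy <- vapply(seq_len(ncol(norm)), function(j) {
    tot <- sum(norm[, j])
    if (tot == 0) return(1)            # no information
    p <- norm[, j] / tot
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(m)
  }, numeric(1))
  d <- 1 - entropy
  if (sum(d) <= 0)
    stop("no metric carries information; panel is unscorable")
  w <- d / sum(d)
  names(w) <- colnames(norm)

  raw <- as.vector(norm %*% w)
  rngR <- diff(range(raw))
  composite <- if (rngR == 0) rep(0, m) else (raw - min(raw)) / rngR * 100
  names(composite) <- rownames(norm)
  new("EWMResult", directions = directions, weights = w,
      composite = composite, normalized = norm)
}

#' Accessors for EWM results
#'
#' @param object an [EWMResult-class].
#' @return `ewmWeights()` the named metric weights; `ewmScores()` the named
#'   0-100 per-method composite scores.
#' @export
ewmWeights <- function(object) object@weights

#' @rdname ewmWeights
#' @export
ewmScores <- function(object) object@composite
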