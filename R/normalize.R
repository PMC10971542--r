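#' Log-CPM normalization
#'
#' Scales each sample to counts-per-million and applies
#' `log2(cpm + pseudocount)`. Zero counts map to `log2(pseudocount)` (0 for
#' the default pseudocount of 1), preserving the sparsity pattern; columns
#' proportional to one another become identical, so the transform removes
#' library-size differences before the normal-theory statistics.
#'
#' @param x count matrix or `SummarizedExperiment` (assay `"counts"`).
#' @param pseudocount positive offset added before the log.
#' @return numeric matrix of log2 CPM values, same dimnames as the input.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(90, 180))
#' normalizeLogCounts(m)   # proportional columns normalize identically
#' @export
normalizeLogCounts <- function(x, pseudocount = 1) {
  m <- .validateCounts(.asCountMatrix(x))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be positive")
  libSizes <- colSums(m)
  if (any(libSizes == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[libSizes == 0], collapse = ", "))
  log2(sweep(m, 2L, libSizes, "/") * 1e6 + pseudocount)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene expressed in every
#' sample, form the ratio of its count to the gene's geometric mean across
#' samples; a sample's factor is the median of those ratios. A matrix with
#' identical columns yields factors of exactly 1; doubling one column doubles
#' only that sample's factor.
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- rbind(g1 = c(4, 9))
#' estimateSizeFactors(m)   # geometric mean 6 -> c(4/6, 9/6)
#' @export
estimateSizeFactors <- function(x) {
  m <- .validateCounts(.asCountMatrix(x))
  allPos <- rowSums(m > 0) == ncol(m)
  if (!any(allPos))
    stop("no gene has nonzero counts in every sample; ",
         "filter the matrix to expressed genes first")
  lg <- log(m[allPos, , drop = FALSE])
  logGeoMean <- rowMeans(lg)
  sf <- apply(exp(lg - logGeoMean), 2L, stats::median)
  names(sf) <- colnames(m)
  sf
}
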