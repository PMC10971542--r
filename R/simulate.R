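#' Simulate a two-group count matrix with known DE genes
#'
#' Generates a gene-by-sample count matrix from the compound Poisson-Gamma
#' model. Genes come in three classes: null genes drawn from the same Tweedie
#' distribution in both groups, and up-/down-regulated genes whose control
#' group uses shifted (mu, phi). Rows are genes (`gene_0001`, ...), columns
#' are samples (`exp_1..exp_K`, then `ctl_1..ctl_K`); the returned
#' `SummarizedExperiment` carries the group factor in `colData(se)$group`
#' (levels `"experimental"`, `"control"`) and the per-gene truth in
#' `rowData(se)$geneClass` / `rowData(se)$isDE`.
#'
#' The generator is fully determined by `config` (including `config@seed`):
#' the same configuration reproduces the identical matrix. Draws are rounded
#' to the nearest nonnegative integer by default so the matrix is a valid
#' count table for count-based statistics; set `roundToInteger = FALSE` in
#' the config to keep the raw continuous draws.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer overriding `config@seed`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`.
#' @examples
#' se <- simulateTweedieData(SimulationConfig(nNull = 90, nUp = 5, nDown = 5,
#'                                            kReplicates = 3, seed = 7))
#' table(truthLabels(se)$geneClass)
#' @export
simulateTweedieData <- function(config = SimulationConfig(), seed = NULL) {
  validObject(config)
  if (!is.null(seed)) config@seed <- as.integer(seed)
  set.seed(config@seed)
  K <- config@kReplicates
  counts <- c(null = config@nNull, up = config@nUp, down = config@nDown)
  blocks <- lapply(c("null", "up", "down"), function(cls) {
    nr <- counts[[cls]]
    if (nr == 0L) return(NULL)
    spec <- config@classSpecs[[cls]]
    cbind(
      matrix(rtweedie(nr * K, spec@experimental), nrow = nr),
      matrix(rtweedie(nr * K, spec@control), nrow = nr))
  })
  mat <- do.call(rbind, blocks)
  if (config@roundToInteger) mat <- round(mat)
  nGenes <- nrow(mat)
  rownames(mat) <- sprintf("gene_%0*d", max(4L, nchar(nGenes)), seq_len(nGenes))
  colnames(mat) <- c(paste0("exp_", seq_len(K)), paste0("ctl_", seq_len(K)))
  group <- factor(rep(c("experimental", "control"), each = K),
                  levels = c("experimental", "control"))
  geneClass <- factor(rep(c("null", "up", "down"), counts),
                      levels = c("null", "up", "down"))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    rowData = S4Vectors::DataFrame(geneClass = geneClass,
                                   isDE = geneClass != "null"),
    colData = S4Vectors::DataFrame(group = group))
}

#' Ground-truth labels of a simulated dataset
#'
#' @param se a `SummarizedExperiment` from [simulateTweedieData()].
#' @return data.frame with `gene_id`, `geneClass` and logical `isDE`.
#' @export
truthLabels <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  if (!all(c("geneClass", "isDE") %in% colnames(rd)))
    stop("'se' carries no truth labels (geneClass/isDE) in rowData")
  data.frame(gene_id = rownames(se), geneClass = rd$geneClass,
             isDE = rd$isDE, stringsAsFactors = FALSE)
}

#' Per-gene mean-variance summary
#'
#' Row-wise sample mean and unbiased sample variance, the standard diagnostic
#' that simulated counts are overdispersed (variance above the mean for most
#' genes, as in real single-cell data).
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @return data.frame with `gene_id`, `mean`, `variance`.
#' @examples
#' m <- rbind(a = c(5, 5, 5, 5), b = c(2, 4, 6, 8))
#' meanVarianceSummary(m)
#' @export
meanVarianceSummary <- function(x) {
  m <- .asCountMatrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples for a variance")
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1L)
  data.frame(gene_id = rownames(m), mean = mu, variance = v,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Resolve counts + group factor from a SummarizedExperiment or matrix pair.
.asCountMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  m <- as.matrix(x)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("gene_%0*d", max(4L, nchar(nrow(m))),
                           seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

.resolveGroups <- function(x, groups = NULL) {
  if (is.null(groups)) {
    if (!is(x, "SummarizedExperiment"))
      stop("'groups' must be supplied when 'x' is a plain matrix")
    groups <- SummarizedExperiment::colData(x)$group
    if (is.null(groups))
      stop("colData(x) has no 'group' column")
  }
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly 2 levels, got ", nlevels(groups))
  if (any(table(groups) < 2L))
    stop("each group must contain at least 2 samples")
  groups
}

.validateCounts <- function(m) {
  if (any(!is.finite(m)))
    stop("count matrix contains non-finite values")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count for gene '%s' in sample '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  invisible(m)
}
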