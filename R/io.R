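#' Write a count matrix to disk
#'
#' Two plain-text formats: `"tsv"` writes a tab-delimited table whose header
#' row holds the sample ids and whose first column (`gene_id`) holds the gene
#' ids; `"mtx"` writes MatrixMarket coordinate format plus two sidecar files,
#' `<path>.genes.txt` and `<path>.samples.txt`, with one id per line.
#' Integer matrices round-trip bit-exactly through [readCountMatrix()].
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @param path output file path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- .validateCounts(.asCountMatrix(x))
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read a count matrix from disk
#'
#' Reads the formats written by [writeCountMatrix()] and validates the
#' result: values must be nonnegative (errors name the offending gene and
#' sample), gene and sample ids must be unique, and MatrixMarket sidecar
#' lengths must match the matrix dimensions.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"mtx"`; guessed from the file extension when
#'   omitted (`.mtx` means MatrixMarket).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readCountMatrix <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  format <- match.arg(format, c("tsv", "mtx"))
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "gene_id")
      stop("expected first column 'gene_id' in ", path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    m <- as.matrix(Matrix::readMM(path))
    genesFile <- paste0(path, ".genes.txt")
    samplesFile <- paste0(path, ".samples.txt")
    if (!file.exists(genesFile) || !file.exists(samplesFile))
      stop("MatrixMarket sidecar files ", genesFile, " / ", samplesFile,
           " not found")
    genes <- readLines(genesFile)
    samples <- readLines(samplesFile)
    if (length(genes) != nrow(m))
      stop("gene sidecar has ", length(genes), " ids but matrix has ",
           nrow(m), " rows")
    if (length(samples) != ncol(m))
      stop("sample sidecar has ", length(samples), " ids but matrix has ",
           ncol(m), " columns")
    rownames(m) <- genes
    colnames(m) <- samples
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  .validateCounts(m)
  m
}

#' Write and read truth labels
#'
#' Truth labels travel as two-column tab-delimited text: `gene_id` and
#' `class` (one of `null`, `up`, `down`).
#'
#' @param truth data.frame from [truthLabels()].
#' @param path file path.
#' @return `writeTruthLabels()` returns `path` invisibly;
#'   `readTruthLabels()` a data.frame with `gene_id`, `geneClass`, `isDE`.
#' @export
writeTruthLabels <- function(truth, path) {
  utils::write.table(
    data.frame(gene_id = truth$gene_id, class = truth$geneClass),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthLabels
#' @export
readTruthLabels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% colnames(df)))
    stop("expected columns 'gene_id' and 'class' in ", path)
  if (!all(df$class %in% c("null", "up", "down")))
    stop("unknown class labels in ", path)
  data.frame(gene_id = df$gene_id,
             geneClass = factor(df$class, levels = c("null", "up", "down")),
             isDE = df$class != "null", stringsAsFactors = FALSE)
}

#' Read a two-level group label file
#'
#' Tab-delimited text with columns `sample_id` and `group`; the group column
#' must contain exactly two distinct levels.
#'
#' @param path file path.
#' @param sampleIds optional sample ids to align and validate against.
#' @return factor of group labels, named by sample id.
#' @export
readGroupLabels <- function(path, sampleIds = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("expected columns 'sample_id' and 'group' in ", path)
  g <- factor(df$group)
  if (nlevels(g) != 2L)
    stop("group file must have exactly 2 levels, got ", nlevels(g),
         " (", paste(levels(g), collapse = ", "), ")")
  names(g) <- df$sample_id
  if (!is.null(sampleIds)) {
    if (!setequal(names(g), sampleIds))
      stop("sample ids in ", path, " do not match the count matrix")
    g <- g[sampleIds]
  }
  g
}
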