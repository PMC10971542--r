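#' Confusion counts of DE calls against ground truth
#'
#' Cross-tabulates per-gene calls against the true DE status. The four cells
#' always sum to the number of genes; TP + FN equals the number of true DE
#' genes and TP + FP the number of predicted DE genes.
#'
#' @param called logical vector of calls (or a called [DEAResult-class]).
#' @param truth logical vector of true DE status, or a data.frame with an
#'   `isDE` column as returned by [truthLabels()].
#' @return named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(called, truth) {
  if (is(called, "DEAResult")) called <- called@called
  if (is.data.frame(truth)) truth <- truth$isDE
  truth <- as.logical(truth)
  called <- as.logical(called)
  if (length(called) != length(truth))
    stop("'called' and 'truth' differ in length (",
         length(called), " vs ", length(truth), ")")
  list(TP = sum(called & truth), FP = sum(called & !truth),
       TN = sum(!called & !truth), FN = sum(!called & truth))
}

#' Basic classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), FDR = FP/(FP+TP), and
#' F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is reported as
#' `NA` (missing), never silently as zero.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (from [confusionCounts()]).
#' @return named list with `tpr`, `fpr`, `fdr`, `f1`.
#' @export
basicMetrics <- function(counts) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, list(
    tpr = rat(TP, TP + FN),
    fpr = rat(FP, FP + TN),
    fdr = rat(FP, FP + TP),
    f1 = rat(2 * TP, 2 * TP + FP + FN)))
}

#' Mean-Rank and MRSR of a ranked prediction list
#'
#' Given the predicted DE genes ranked by evidence (strongest first),
#' Mean-Rank is the average within-list rank of the true positives, and the
#' Mean Rank-sum Ratio normalizes it by its ideal value:
#' \deqn{MRSR = \frac{\mathrm{MeanRank}}{(TP+1)/2} \ge 1,}
#' attaining exactly 1 when the TP true positives occupy ranks 1..TP. Both
#' are `NA` when the list contains no true positive. The normalization by TP
#' makes MRSR comparable across conditions with different numbers of
#' recovered genes; `denominator = "predicted"` instead divides the rank sum
#' by the length of the predicted list (an alternative, non-normalized
#' reading kept for sensitivity analysis — its lower bound is not 1).
#'
#' @param rankedGenes character vector of predicted gene ids, best first
#'   (see [rankedCallList()]).
#' @param truth data.frame from [truthLabels()] (or any with `gene_id`,
#'   `isDE`).
#' @param denominator `"tp"` (default) or `"predicted"`.
#' @return named list with `meanRank` and `mrsr`.
#' @export
meanRankMRSR <- function(rankedGenes, truth,
                         denominator = c("tp", "predicted")) {
  denominator <- match.arg(denominator)
  deGenes <- truth$gene_id[as.logical(truth$isDE)]
  hit <- rankedGenes %in% deGenes
  tp <- sum(hit)
  if (tp == 0L) return(list(meanRank = NA_real_, mrsr = NA_real_))
  rankSum <- sum(which(hit))
  meanRank <- rankSum / if (denominator == "tp") tp else length(rankedGenes)
  list(meanRank = meanRank, mrsr = meanRank / ((tp + 1) / 2))
}

#' Ranked list of called genes
#'
#' Orders the called genes of a result best-evidence-first: ascending
#' p-value with descending score as tie-break for p-value methods, or
#' descending score for score-only methods (the DEF statistic).
#'
#' @param result a called [DEAResult-class].
#' @return character vector of called gene ids, best first.
#' @export
rankedCallList <- function(result) {
  stopifnot(is(result, "DEAResult"))
  idx <- which(result@called)
  if (!length(idx)) return(character())
  if (all(is.na(result@pValue))) {
    idx <- idx[order(-result@score[idx], seq_along(idx))]
  } else {
    idx <- idx[order(result@pValue[idx], -result@score[idx],
                     seq_along(idx))]
  }
  result@geneIds[idx]
}

#' Ranking AUC against ground truth
#'
#' The area under the ROC curve in its rank-statistic (Mann-Whitney) form:
#' the probability that a randomly chosen true DE gene receives a higher
#' score than a randomly chosen non-DE gene, with ties counting one half.
#' Genes with an undefined (NA) score are excluded.
#'
#' @param scores per-gene evidence (larger = stronger), or a
#'   [DEAResult-class].
#' @param truth data.frame from [truthLabels()], or a logical vector.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, truth) {
  if (is(scores, "DEAResult")) scores <- scores@score
  if (is.data.frame(truth)) truth <- truth$isDE
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' differ in length")
  ok <- !is.na(scores)
  scores <- scores[ok]; truth <- truth[ok]
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0L || nN == 0L)
    stop("AUC needs at least one DE and one non-DE gene")
  r <- rank(scores)
  (sum(r[truth]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' ROC curve points
#'
#' FPR/TPR pairs of the ROC curve traced by thresholding the scores, for
#' plotting or vertical averaging. NA scores are excluded.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns `fpr` and `tpr`, from (0,0) to (1,1).
#' @export
rocCurve <- function(scores, truth) {
  if (is(scores, "DEAResult")) scores <- scores@score
  if (is.data.frame(truth)) truth <- truth$isDE
  truth <- as.logical(truth)
  ok <- !is.na(scores)
  scores <- scores[ok]; truth <- truth[ok]
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0L || nN == 0L)
    stop("ROC needs at least one DE and one non-DE gene")
  ord <- order(-scores)
  s <- scores[ord]; y <- truth[ord]
  keep <- c(diff(s) != 0, TRUE)      # one point per distinct threshold
  data.frame(fpr = c(0, cumsum(!y)[keep] / nN),
             tpr = c(0, cumsum(y)[keep] / nP))
}

#' Fold-change reference genes for label-free evaluation
#'
#' On size-factor-scaled counts, flags genes whose absolute log2 fold change
#' between group means (with a pseudocount) strictly exceeds `threshold`
#' (default 1, i.e. beyond two-fold). Used as the reference DE set when no
#' simulation ground truth exists, e.g. for real count matrices.
#'
#' @inheritParams runDEAMethod
#' @param threshold positive log2 fold-change cutoff (strict inequality).
#' @param pseudocount offset protecting the ratio at zero means; with
#'   `pseudocount = 0`, a gene with both group means zero gets log2FC 0 and
#'   a gene expressed in only one group an infinite (flagged) fold change.
#' @param sizeFactors optional per-sample factors overriding the
#'   median-of-ratios estimate.
#' @return data.frame with `gene_id`, `log2FC` and logical `isReference`.
#' @export
referenceGenesFoldChange <- function(x, groups = NULL, threshold = 1,
                                     pseudocount = 0.5, sizeFactors = NULL) {
  groups <- .resolveGroups(x, groups)
  m <- .validateCounts(.asCountMatrix(x))
  if (threshold <= 0) stop("'threshold' must be positive")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(m)
  sc <- sweep(m, 2L, sizeFactors, "/")
  gi <- .groupIdx(groups)
  m1 <- rowMeans(sc[, gi$g1, drop = FALSE])
  m2 <- rowMeans(sc[, gi$g2, drop = FALSE])
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  lfc[m1 + pseudocount == 0 & m2 + pseudocount == 0] <- 0
  data.frame(gene_id = rownames(m), log2FC = lfc,
             isReference = abs(lfc) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate one called result against ground truth
#'
#' Computes the full metric panel for one method on one dataset: TPR, FPR,
#' FDR, F1 from the confusion matrix, Mean-Rank and MRSR from the ranked
#' call list, and the ranking AUC from the scores.
#'
#' @param result a called [DEAResult-class].
#' @param truth data.frame from [truthLabels()].
#' @return one-row data.frame with columns `method`, `tpr`, `fpr`, `fdr`,
#'   `f1`, `mean_rank`, `mrsr`, `auc`.
#' @export
evaluateResult <- function(result, truth) {
  stopifnot(is(result, "DEAResult"))
  cc <- confusionCounts(result@called, truth$isDE)
  bm <- basicMetrics(cc)
  mr <- meanRankMRSR(rankedCallList(result), truth)
  auc <- if (all(truth$isDE) || !any(truth$isDE)) NA_real_
         else rocAuc(result@score, truth)
  data.frame(method = result@method, tpr = bm$tpr, fpr = bm$fpr,
             fdr = bm$fdr, f1 = bm$f1, mean_rank = mr$meanRank,
             mrsr = mr$mrsr, auc = auc,
             stringsAsFactors = FALSE)
}
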