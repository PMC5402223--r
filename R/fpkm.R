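#' Assemble a count SummarizedExperiment from long-format inputs
#'
#' @param counts \code{data.frame} with columns \code{gene_id},
#'   \code{condition}, \code{replicate}, \code{count}.
#' @param models \code{data.frame} with columns \code{gene_id},
#'   \code{length}; every counted gene must be a known model.
#' @return \code{SummarizedExperiment} with assay \code{"counts"},
#'   \code{rowData$length}, and \code{colData} \code{condition},
#'   \code{replicate}.
#' @export
makeCountSE <- function(counts, models) {
  stopifnot(all(c("gene_id", "condition", "replicate", "count") %in%
                  colnames(counts)),
            all(c("gene_id", "length") %in% colnames(models)))
  unknown <- setdiff(unique(counts$gene_id), models$gene_id)
  if (length(unknown))
    stop("count table contains gene_ids absent from the gene models: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  if (any(counts$count < 0))
    stop("counts must be non-negative", call. = FALSE)
  sample_id <- sprintf("%s_rep%s", counts$condition, counts$replicate)
  usamp <- unique(data.frame(sample_id = sample_id,
                             condition = counts$condition,
                             replicate = counts$replicate,
                             stringsAsFactors = FALSE))
  m <- matrix(0, nrow = nrow(models), ncol = nrow(usamp),
              dimnames = list(models$gene_id, usamp$sample_id))
  m[cbind(match(counts$gene_id, models$gene_id),
          match(sample_id, usamp$sample_id))] <- counts$count
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(length = models$length,
                                   row.names = models$gene_id),
    colData = S4Vectors::DataFrame(condition = usamp$condition,
                                   replicate = usamp$replicate,
                                   row.names = usamp$sample_id))
}

#' Compute FPKM per replicate
#'
#' FPKM for gene g in a replicate is
#' \deqn{FPKM_g = c_g \times 10^9 / (L_g \times T)}
#' where \eqn{c_g} is the mapped-read count, \eqn{L_g} the transcript length
#' in bases and \eqn{T} the replicate's total mapped reads, taken as the sum
#' of that replicate's per-gene counts (the count table is the read
#' universe). Scale-invariant: multiplying every count in a replicate by a
#' positive constant leaves its FPKM column unchanged.
#'
#' @param se count \code{SummarizedExperiment} (see [makeCountSE()] or
#'   [generateCounts()]); needs \code{rowData()$length}.
#' @return \code{se} with an added \code{"fpkm"} assay.
#' @examples
#' counts <- data.frame(gene_id = "g1", condition = "premature",
#'                      replicate = 1, count = 100)
#' models <- data.frame(gene_id = "g1", length = 1000)
#' # a lone gene holds all 100 reads of its library: FPKM = 1e7
#' SummarizedExperiment::assay(computeFPKM(makeCountSE(counts, models)),
#'                             "fpkm")
#' @export
computeFPKM <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  len <- SummarizedExperiment::rowData(se)$length
  if (is.null(len)) stop("rowData(se)$length is required", call. = FALSE)
  total <- colSums(counts)
  if (any(total == 0))
    stop("empty library: replicate(s) with zero total counts: ",
         paste(colnames(counts)[total == 0], collapse = ", "),
         call. = FALSE)
  fpkm <- sweep(counts * 1e9 / len, 2L, total, "/")
  SummarizedExperiment::assays(se)$fpkm <- fpkm
  se
}

#' Average per-replicate FPKM within conditions
#'
#' Arithmetic mean of the per-replicate FPKM values per gene and condition.
#' Replicate tables are congruent by construction of the
#' \code{SummarizedExperiment} (same gene universe in every column).
#'
#' @param se \code{SummarizedExperiment} carrying an \code{"fpkm"} assay
#'   (see [computeFPKM()]).
#' @return numeric matrix, genes x conditions.
#' @export
averageReplicates <- function(se) {
  if (!"fpkm" %in% SummarizedExperiment::assayNames(se))
    stop("run computeFPKM() first", call. = FALSE)
  fpkm <- SummarizedExperiment::assay(se, "fpkm")
  cond <- SummarizedExperiment::colData(se)$condition
  conds <- unique(cond)
  out <- vapply(conds,
                function(cc) rowMeans(fpkm[, cond == cc, drop = FALSE]),
                numeric(nrow(fpkm)))
  colnames(out) <- conds
  out
}

#' Expressed-gene filter
#'
#' A gene counts as expressed in a condition iff its replicate-averaged
#' FPKM is strictly greater than \code{threshold} (default 1): a gene at
#' exactly FPKM 1 is not expressed.
#'
#' @param fpkmMean genes x conditions matrix from [averageReplicates()].
#' @param threshold strict FPKM cutoff.
#' @return named list: per condition, the character vector of expressed
#'   gene ids.
#' @export
filterExpressed <- function(fpkmMean, threshold = 1) {
  lapply(setNames(colnames(fpkmMean), colnames(fpkmMean)),
         function(cc) rownames(fpkmMean)[fpkmMean[, cc] > threshold])
}

#' Classify differential expression by FPKM ratio
#'
#' For every gene of the classification universe the premature/mature FPKM
#' ratio is formed and thresholded: ratio strictly greater than
#' \code{upRatio} (1.5) is \code{premature_up}, strictly less than
#' \code{downRatio} (0.67) is \code{mature_up}, anything else
#' \code{neither}. The thresholds are used exactly as printed — 0.67 is not
#' 1/1.5, so the bands are asymmetric by design. A zero mature FPKM with
#' positive premature FPKM yields ratio \code{+Inf}, hence
#' \code{premature_up}; this keeps the three classes a partition of the
#' universe.
#'
#' The universe defaults to the union of the two conditions' expressed
#' gene sets (strict FPKM > \code{exprThreshold} in at least one
#' condition); \code{"intersection"} and \code{"all"} are available.
#'
#' @param fpkmMean genes x conditions matrix from [averageReplicates()].
#' @param preCondition,matCondition column names of the two conditions.
#' @param exprThreshold expressed-gene FPKM cutoff (strict).
#' @param upRatio,downRatio classification thresholds (strict).
#' @param universe one of \code{"union"}, \code{"intersection"},
#'   \code{"all"}.
#' @return \code{data.frame}: \code{gene_id}, \code{fpkm_pre},
#'   \code{fpkm_mat}, \code{ratio}, \code{de_class}.
#' @export
classifyDE <- function(fpkmMean, preCondition = "premature",
                       matCondition = "mature", exprThreshold = 1,
                       upRatio = 1.5, downRatio = 0.67,
                       universe = c("union", "intersection", "all")) {
  universe <- match.arg(universe)
  stopifnot(all(c(preCondition, matCondition) %in% colnames(fpkmMean)))
  pre <- fpkmMean[, preCondition]
  mat <- fpkmMean[, matCondition]
  in_universe <- switch(universe,
    union = pre > exprThreshold | mat > exprThreshold,
    intersection = pre > exprThreshold & mat > exprThreshold,
    all = rep(TRUE, length(pre)))
  pre <- pre[in_universe]; mat <- mat[in_universe]
  ratio <- ifelse(mat == 0, ifelse(pre > 0, Inf, NaN), pre / mat)
  cls <- ifelse(ratio > upRatio, "premature_up",
                ifelse(ratio < downRatio, "mature_up", "neither"))
  data.frame(gene_id = rownames(fpkmMean)[in_universe],
             fpkm_pre = pre, fpkm_mat = mat, ratio = ratio,
             de_class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read long-format count tables
#'
#' TSV with header \code{gene_id<TAB>condition<TAB>replicate<TAB>count}.
#'
#' @param se count \code{SummarizedExperiment}.
#' @param path file path.
#' @return \code{path} (write) or a \code{data.frame} (read), invisibly for
#'   the writer.
#' @export
writeCountTable <- function(se, path) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  long <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j)
    data.frame(gene_id = rownames(counts), condition = cd$condition[j],
               replicate = cd$replicate[j], count = counts[, j],
               stringsAsFactors = FALSE)))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read gene-model tables (\code{gene_id<TAB>length})
#'
#' @param models \code{data.frame} with \code{gene_id}, \code{length}.
#' @param path file path.
#' @export
writeGeneModels <- function(models, path) {
  write.table(models[, c("gene_id", "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneModels
#' @export
readGeneModels <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
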