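# Readers/writers for the expression matrix and phenotype label files.
#
# Matrix: tab-delimited, header row "gene<TAB>sample1<TAB>...", one gene per
# row. Labels: two tab-delimited columns (sample, phenotype), no header.

#' Read an expression study from a matrix file and a label file
#'
#' Duplicate gene identifiers (e.g. multiple probes per gene) are collapsed to
#' the row with the highest mean expression — deterministic and rank-safe;
#' missing or non-numeric cells are rejected with an error naming the cell,
#' because silent imputation would alter the per-patient ranks at the core of
#' the filtering step. Samples present in the matrix but absent from the label
#' file are an error.
#'
#' @param matrixPath tab-delimited expression matrix; first column gene
#'   identifier, header row of sample identifiers.
#' @param labelsPath two-column tab-delimited file (sample, phenotype),
#'   no header.
#' @return An \linkS4class{ExpressionStudy}.
#' @export
readExpression <- function(matrixPath, labelsPath) {
  raw <- read.delim(matrixPath, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("malformed header: expected a gene column plus sample columns")
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample identifiers in header")
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("missing or non-numeric value at gene '%s', sample '%s'",
                   genes[bad[1L]], samples[j]))
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    rowMean <- rowMeans(vals)
    o <- order(-rowMean, seq_len(nrow(vals)), method = "radix")
    keep <- o[!duplicated(genes[o])]
    keep <- sort(keep)            # preserve original row order
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes

  lab <- read.delim(labelsPath, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(lab) < 2L) stop("label file needs 2 columns: sample, phenotype")
  labels <- stats::setNames(lab[[2L]], lab[[1L]])
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    stop("unlabelled sample(s): ", paste(missing, collapse = ", "))
  ExpressionStudy(vals, labels)
}

#' Write an expression study to a matrix file and a label file
#'
#' Inverse of \code{\link{readExpression}} (up to duplicate-row collapsing).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param matrixPath,labelsPath output file paths.
#' @return Invisibly, the two paths.
#' @export
writeExpression <- function(study, matrixPath, labelsPath) {
  x <- exprValues(study)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- phenotypeLabels(study)
  write.table(data.frame(names(labels), unname(labels)), labelsPath,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(matrixPath, labelsPath))
}
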