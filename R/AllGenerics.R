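# Accessors and show methods. Slots are never accessed with @ by user code.

#' @rdname ExpressionStudy
#' @param study an \linkS4class{ExpressionStudy}.
#' @return \code{exprValues}: the genes-by-samples matrix.
#' @export
exprValues <- function(study) SummarizedExperiment::assay(study, 1L)

#' @rdname ExpressionStudy
#' @return \code{phenotypeLabels}: named character vector sample -> phenotype,
#'   in study sample order.
#' @export
phenotypeLabels <- function(study) {
  stats::setNames(
    as.character(SummarizedExperiment::colData(study)$phenotype),
    colnames(study))
}

#' @rdname ExpressionStudy
#' @return \code{phenotypeNames}: the distinct phenotype names, in order of
#'   first appearance.
#' @export
phenotypeNames <- function(study) unique(unname(phenotypeLabels(study)))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  print(table(phenotype = phenotypeLabels(object)))
})

#' @rdname PathwayDB
#' @param db a \linkS4class{PathwayDB}.
#' @return \code{pathwayNames}: character vector of pathway names.
#' @export
pathwayNames <- function(db) names(db@pathways)

#' @rdname PathwayDB
#' @param pathway pathway name.
#' @return \code{pathwayEdges}: the edge table of one pathway.
#' @export
pathwayEdges <- function(db, pathway) {
  if (!pathway %in% names(db@pathways)) stop("unknown pathway: ", pathway)
  db@pathways[[pathway]]
}

#' @rdname PathwayDB
#' @return \code{pathwayGenes}: genes appearing in the pathway's edges (or in
#'   any pathway when \code{pathway} is missing).
#' @export
pathwayGenes <- function(db, pathway) {
  if (missing(pathway)) {
    sort(unique(unlist(lapply(db@pathways,
                              function(e) c(e$gene_a, e$gene_b)),
                       use.names = FALSE)))
  } else {
    e <- pathwayEdges(db, pathway)
    sort(unique(c(e$gene_a, e$gene_b)))
  }
}

#' @rdname PathwayDB
#' @return \code{nPathways}: number of pathways.
#' @export
nPathways <- function(db) length(db@pathways)

setMethod("show", "PathwayDB", function(object) {
  ne <- vapply(object@pathways, nrow, integer(1))
  cat("PathwayDB:", length(object@pathways), "pathways,",
      sum(ne), "edges,", length(pathwayGenes(object)), "genes\n")
})

setMethod("show", "SNetParams", function(object) {
  cat(sprintf(
    "SNetParams: alpha=%g%% beta=%g%% nPerm=%d pCutoff=%g minSize=%d seed=%d sizeBin=%s\n",
    object@alpha, object@beta, object@nPerm, object@pCutoff,
    object@minSize, object@seed, object@sizeBin))
})

#' Subnetwork accessors
#'
#' @param x a \linkS4class{Subnetwork} (or \linkS4class{ScoredSubnetwork}).
#' @return The corresponding field.
#' @name subnetwork-accessors
NULL

#' @rdname subnetwork-accessors
#' @export
snName <- function(x) x@name

#' @rdname subnetwork-accessors
#' @export
snPhenotype <- function(x) x@phenotype

#' @rdname subnetwork-accessors
#' @export
snPathway <- function(x) x@pathway

#' @rdname subnetwork-accessors
#' @export
snGenes <- function(x) x@genes

#' @rdname subnetwork-accessors
#' @export
snEdges <- function(x) x@edges

#' @rdname subnetwork-accessors
#' @export
snSize <- function(x) length(x@genes)

#' @rdname subnetwork-accessors
#' @export
patientScores <- function(x) x@perPatientScore

#' @rdname subnetwork-accessors
#' @export
scoreVecD <- function(x) x@scoreVecD

#' @rdname subnetwork-accessors
#' @export
scoreVecNotD <- function(x) x@scoreVecNotD

#' @rdname subnetwork-accessors
#' @export
tStat <- function(x) x@tStat

#' @rdname subnetwork-accessors
#' @export
pValue <- function(x) x@pValue

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf("Subnetwork %s [%s]: %d genes, %d edges\n",
              object@name, object@pathway,
              length(object@genes), nrow(object@edges)))
})

setMethod("show", "ScoredSubnetwork", function(object) {
  cat(sprintf("ScoredSubnetwork %s [%s]: %d genes, t=%.3f, p=%s\n",
              object@name, object@pathway, length(object@genes),
              object@tStat,
              if (is.na(object@pValue)) "NA" else format(object@pValue)))
})

#' NullDistribution accessors
#'
#' @param null a \linkS4class{NullDistribution}.
#' @return \code{nullEntries}: data.frame with columns \code{size},
#'   \code{tStat}; \code{nPermDone}: permutations performed.
#' @export
nullEntries <- function(null) {
  data.frame(size = null@sizes, tStat = null@tStats)
}

#' @rdname nullEntries
#' @export
nPermDone <- function(null) null@nPermDone

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d entries from %d permutations\n",
              length(object@sizes), object@nPermDone))
})

#' SNetResult accessors
#'
#' @param result an \linkS4class{SNetResult}.
#' @return \code{allSubnetworks}: list of every scored subnetwork;
#'   \code{significantSubnetworks}: those with p <= pCutoff;
#'   \code{significantGenes}: union of their gene sets;
#'   \code{resultTable}: one-row-per-subnetwork data.frame;
#'   \code{paramsOf}: the run parameters; \code{nullOf}: the shared null.
#' @export
allSubnetworks <- function(result) result@scored

#' @rdname allSubnetworks
#' @export
significantSubnetworks <- function(result) {
  Filter(function(s) !is.na(s@pValue) && s@pValue <= result@params@pCutoff,
         result@scored)
}

#' @rdname allSubnetworks
#' @export
significantGenes <- function(result) {
  sort(unique(unlist(lapply(significantSubnetworks(result), snGenes),
                     use.names = FALSE)))
}

#' @rdname allSubnetworks
#' @export
paramsOf <- function(result) result@params

#' @rdname allSubnetworks
#' @export
nullOf <- function(result) result@null

#' @rdname allSubnetworks
#' @export
resultTable <- function(result) {
  sn <- result@scored
  data.frame(
    name = vapply(sn, snName, character(1)),
    phenotype = vapply(sn, snPhenotype, character(1)),
    pathway = vapply(sn, snPathway, character(1)),
    size = vapply(sn, snSize, integer(1)),
    t_stat = vapply(sn, tStat, numeric(1)),
    p_value = vapply(sn, pValue, numeric(1)),
    significant = vapply(sn, function(s)
      !is.na(s@pValue) && s@pValue <= result@params@pCutoff, logical(1)),
    genes = vapply(sn, function(s) paste(s@genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}

setMethod("show", "SNetResult", function(object) {
  cat(sprintf("SNetResult: %d scored subnetworks, %d significant at p <= %g\n",
              length(object@scored),
              length(significantSubnetworks(object)),
              object@params@pCutoff))
})
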