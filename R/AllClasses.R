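#' @importFrom methods new validObject setClass setGeneric setMethod is slot show
#' @importFrom stats var pt rnorm runif setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame
NULL

#' Two-phenotype (or more) expression study
#'
#' An \code{ExpressionStudy} is a \linkS4class{SummarizedExperiment} holding a
#' genes-by-samples matrix of normalized expression intensities together with a
#' \code{phenotype} column in its \code{colData}. The matrix is assumed to be
#' already normalized; values are compared only within a sample (per-patient
#' ranking), so any monotone per-sample transform leaves the analysis
#' unchanged.
#'
#' Validity requires unique gene and sample identifiers, no missing values, a
#' phenotype label for every sample, at least two distinct phenotypes, and at
#' least two samples per phenotype (a t-statistic needs both group variances).
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character(0)
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("ExpressionStudy needs one assay (the expression matrix)")
  x <- SummarizedExperiment::assay(object, 1L)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (!is.numeric(x) || anyNA(x))
    msg <- c(msg, "expression values must be numeric with no missing values")
  cd <- SummarizedExperiment::colData(object)
  if (!"phenotype" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'phenotype' column")
  } else {
    ph <- as.character(cd$phenotype)
    if (anyNA(ph)) msg <- c(msg, "every sample needs a phenotype label")
    tab <- table(ph)
    if (length(tab) < 2L)
      msg <- c(msg, "need at least 2 distinct phenotypes")
    if (any(tab < 2L))
      msg <- c(msg, "need at least 2 samples per phenotype")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param labels named character vector mapping sample identifier to phenotype
#'   name; every column of \code{values} must be present.
#' @return An \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' es <- ExpressionStudy(m, c(s1 = "case", s2 = "case",
#'                            s3 = "control", s4 = "control"))
#' phenotypeLabels(es)
#' @export
ExpressionStudy <- function(values, labels) {
  if (!is.matrix(values)) values <- as.matrix(values)
  missing <- setdiff(colnames(values), names(labels))
  if (length(missing))
    stop("unlabelled sample(s): ", paste(missing, collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(
      phenotype = as.character(labels[colnames(values)]),
      row.names = colnames(values)))
  obj <- new("ExpressionStudy", se)
  validObject(obj)
  obj
}

#' Pathway database of typed gene-gene relationships
#'
#' Named pathways, each a set of undirected gene-gene edges annotated with a
#' relation, either \code{"activate"} or \code{"inhibit"}. The relation is
#' carried through to the output files (SIF) but plays no role in subnetwork
#' extraction or scoring, which use the edges purely for connectivity.
#'
#' @slot pathways named list; each element a \code{data.frame} with columns
#'   \code{gene_a}, \code{gene_b}, \code{relation}.
#' @export
setClass("PathwayDB", representation(pathways = "list"))

setValidity("PathwayDB", function(object) {
  pw <- object@pathways
  if (length(pw) == 0L) return("pathway set is empty")
  if (is.null(names(pw)) || anyDuplicated(names(pw)) || any(!nzchar(names(pw))))
    return("pathways must have unique non-empty names")
  for (nm in names(pw)) {
    e <- pw[[nm]]
    if (!is.data.frame(e) ||
        !all(c("gene_a", "gene_b", "relation") %in% colnames(e)))
      return(sprintf("pathway '%s': edges need gene_a/gene_b/relation", nm))
    if (any(e$gene_a == e$gene_b))
      return(sprintf("pathway '%s': self-edge (gene_a == gene_b)", nm))
    if (!all(e$relation %in% c("activate", "inhibit")))
      return(sprintf("pathway '%s': unknown relation token", nm))
  }
  TRUE
})

#' Construct a PathwayDB
#'
#' Edges are undirected: duplicates of the same unordered gene pair with the
#' same relation are collapsed. Relations are matched case-insensitively and
#' stored lowercase; anything outside activate/inhibit is rejected.
#'
#' @param pathways named list of edge tables (data.frame with columns
#'   \code{gene_a}, \code{gene_b}, \code{relation}, or a 3-column structure
#'   coercible to one).
#' @return A \linkS4class{PathwayDB}.
#' @examples
#' db <- PathwayDB(list(p53_signalling = data.frame(
#'   gene_a = c("ATM", "MDM2"), gene_b = c("CHK1", "p53"),
#'   relation = c("activate", "inhibit"))))
#' pathwayGenes(db, "p53_signalling")
#' @export
PathwayDB <- function(pathways) {
  pathways <- lapply(pathways, .canonicalEdges)
  obj <- new("PathwayDB", pathways = pathways)
  validObject(obj)
  obj
}

# lowercase relations, validate tokens, drop duplicate unordered pairs
.canonicalEdges <- function(e) {
  e <- as.data.frame(e, stringsAsFactors = FALSE)
  if (ncol(e) < 3L) stop("edge table needs 3 columns (gene_a, gene_b, relation)")
  if (!all(c("gene_a", "gene_b", "relation") %in% colnames(e)))
    colnames(e)[1:3] <- c("gene_a", "gene_b", "relation")
  e$gene_a <- as.character(e$gene_a)
  e$gene_b <- as.character(e$gene_b)
  e$relation <- tolower(as.character(e$relation))
  bad <- setdiff(unique(e$relation), c("activate", "inhibit"))
  if (length(bad))
    stop("unknown relation token(s): ", paste(bad, collapse = ", "))
  if (any(e$gene_a == e$gene_b))
    stop("self-edge: gene_a equals gene_b")
  lo <- pmin(e$gene_a, e$gene_b)
  hi <- pmax(e$gene_a, e$gene_b)
  e <- e[!duplicated(paste(lo, hi, e$relation, sep = "\r")), , drop = FALSE]
  rownames(e) <- NULL
  e[, c("gene_a", "gene_b", "relation")]
}

#' Parameters of a subnetwork discovery run
#'
#' @slot alpha percentage of top-ranked genes kept per patient (0, 100].
#' @slot beta frequency threshold in percent: a gene enters the candidate list
#'   when it is highly expressed in strictly more than \code{beta}\% of the
#'   phenotype's patients.
#' @slot nPerm number of phenotype-label permutations for the null.
#' @slot pCutoff significance threshold (inclusive).
#' @slot minSize minimum number of genes of a reported subnetwork.
#' @slot seed RNG seed for the permutation null.
#' @slot sizeBin \code{"tail"} (null entries with size >= observed) or
#'   \code{"exact"} (size == observed).
#' @export
setClass("SNetParams", representation(
  alpha = "numeric", beta = "numeric", nPerm = "integer",
  pCutoff = "numeric", minSize = "integer", seed = "integer",
  sizeBin = "character"))

setValidity("SNetParams", function(object) {
  msg <- character(0)
  if (!(object@alpha > 0 && object@alpha <= 100))
    msg <- c(msg, "alpha must be in (0, 100]")
  if (!(object@beta >= 0 && object@beta < 100))
    msg <- c(msg, "beta must be in [0, 100)")
  if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
  if (!(object@pCutoff > 0 && object@pCutoff <= 1))
    msg <- c(msg, "pCutoff must be in (0, 1]")
  if (object@minSize < 2L) msg <- c(msg, "minSize must be >= 2")
  if (!object@sizeBin %in% c("tail", "exact"))
    msg <- c(msg, "sizeBin must be 'tail' or 'exact'")
  if (length(msg)) msg else TRUE
})

#' Construct run parameters
#'
#' Defaults follow the method's published operating point: keep each patient's
#' top 10\% of genes, require a gene in more than 50\% of the phenotype's
#' patients, 1000 label permutations, significance at p <= 0.05, and report
#' subnetworks of at least 5 genes.
#'
#' @param alpha,beta,nPerm,pCutoff,minSize,seed,sizeBin see
#'   \linkS4class{SNetParams}.
#' @return An \linkS4class{SNetParams}.
#' @examples
#' SNetParams(nPerm = 100, seed = 7)
#' @export
SNetParams <- function(alpha = 10, beta = 50, nPerm = 1000, pCutoff = 0.05,
                       minSize = 5, seed = 1L, sizeBin = "tail") {
  obj <- new("SNetParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
             nPerm = as.integer(nPerm), pCutoff = as.numeric(pCutoff),
             minSize = as.integer(minSize), seed = as.integer(seed),
             sizeBin = sizeBin)
  validObject(obj)
  obj
}

#' A connected subnetwork within one pathway
#'
#' A connected component of a pathway's relationship graph restricted to a
#' candidate gene list, tagged with the phenotype it was extracted for.
#'
#' @slot name subnetwork name, \code{<phenotype>_<pathway>_<hub gene>} with the
#'   hub being the maximum-degree gene (ties broken lexicographically).
#' @slot phenotype the phenotype the subnetwork was extracted for (may be
#'   \code{NA} outside a phenotype-specific run).
#' @slot pathway name of the pathway the component lives in.
#' @slot genes character vector of member genes.
#' @slot edges data.frame (gene_a, gene_b, relation) of the induced edges.
#' @export
setClass("Subnetwork", representation(
  name = "character", phenotype = "character", pathway = "character",
  genes = "character", edges = "data.frame"))

setValidity("Subnetwork", function(object) {
  msg <- character(0)
  g <- object@genes
  e <- object@edges
  if (anyDuplicated(g)) msg <- c(msg, "duplicate genes")
  if (nrow(e)) {
    if (!all(c(e$gene_a, e$gene_b) %in% g))
      msg <- c(msg, "edge endpoint outside the gene set")
    comp <- .ufComponents(e$gene_a, e$gene_b)
    if (length(comp) != 1L || length(setdiff(g, comp[[1L]])) > 0L)
      msg <- c(msg, "subnetwork graph is not connected")
  } else if (length(g) > 1L) {
    msg <- c(msg, "subnetwork with >1 gene needs edges (must be connected)")
  }
  if (length(msg)) msg else TRUE
})

#' A subnetwork with patient scores, t-statistic and p-value
#'
#' @slot perPatientScore named numeric vector, one non-negative score per
#'   sample of the study (all phenotypes).
#' @slot scoreVecD scores of the phenotype-d patients, in study sample order.
#' @slot scoreVecNotD scores of the remaining patients.
#' @slot tStat Welch t-statistic between the two score vectors.
#' @slot pValue permutation p-value (NA before the null is attached).
#' @export
setClass("ScoredSubnetwork", contains = "Subnetwork", representation(
  perPatientScore = "numeric", scoreVecD = "numeric", scoreVecNotD = "numeric",
  tStat = "numeric", pValue = "numeric"))

#' Null distribution of (size, t-statistic) pairs
#'
#' Pooled over all label permutations and all phenotypes: every subnetwork
#' re-extracted under a permuted label assignment contributes one
#' (size, t-statistic) entry. This two-dimensional histogram is the reference
#' against which observed subnetworks are assigned p-values.
#'
#' @slot sizes integer vector of subnetwork sizes.
#' @slot tStats numeric vector of the matching t-statistics.
#' @slot nPermDone number of permutations performed.
#' @export
setClass("NullDistribution", representation(
  sizes = "integer", tStats = "numeric", nPermDone = "integer"))

setValidity("NullDistribution", function(object) {
  if (length(object@sizes) != length(object@tStats))
    return("sizes and tStats must have equal length")
  TRUE
})

#' Result of a subnetwork discovery run
#'
#' @slot params the \linkS4class{SNetParams} used.
#' @slot scored list of \linkS4class{ScoredSubnetwork}, all phenotypes pooled,
#'   exact duplicates removed, sorted by ascending p-value.
#' @slot null the shared \linkS4class{NullDistribution}.
#' @export
setClass("SNetResult", representation(
  params = "SNetParams", scored = "list", null = "NullDistribution"))

#' Synthetic study configuration
#'
#' Describes the generative model of the fixture generator: random connected
#' pathway graphs, a two-group cohort with i.i.d. Gaussian log-scale
#' expression, and planted connected components up-shifted in the
#' \code{"case"} group.
#'
#' @slot nPathways number of pathways.
#' @slot genesPerPathway length-2 integer range of pathway sizes.
#' @slot edgeProb probability of each non-spanning-tree edge.
#' @slot nBackgroundGenes genes outside every pathway (so the top-percentile
#'   cut is not dominated by pathway genes).
#' @slot nD,nNotD samples per phenotype (case / control).
#' @slot baselineMean,baselineSd log-scale expression baseline.
#' @slot effectSize mean shift of planted genes in cases, in baseline-sd units.
#' @slot plantSpecs list of \code{list(pathway = <index>, size = <genes>)}.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig", representation(
  nPathways = "integer", genesPerPathway = "integer", edgeProb = "numeric",
  nBackgroundGenes = "integer", nD = "integer", nNotD = "integer",
  baselineMean = "numeric", baselineSd = "numeric", effectSize = "numeric",
  plantSpecs = "list", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nPathways < 1L) msg <- c(msg, "nPathways must be positive")
  if (length(object@genesPerPathway) != 2L ||
      any(object@genesPerPathway < 2L) ||
      object@genesPerPathway[1L] > object@genesPerPathway[2L])
    msg <- c(msg, "genesPerPathway must be an increasing range >= 2")
  if (!(object@edgeProb >= 0 && object@edgeProb < 1))
    msg <- c(msg, "edgeProb must be in [0, 1)")
  if (object@nBackgroundGenes < 0L) msg <- c(msg, "nBackgroundGenes >= 0")
  if (object@nD < 2L || object@nNotD < 2L)
    msg <- c(msg, "need at least 2 samples per phenotype")
  if (object@baselineSd <= 0) msg <- c(msg, "baselineSd must be positive")
  for (ps in object@plantSpecs) {
    if (!all(c("pathway", "size") %in% names(ps)))
      msg <- c(msg, "each plant spec needs pathway and size")
    else if (ps$pathway < 1L || ps$pathway > object@nPathways)
      msg <- c(msg, "plant pathway index out of range")
    else if (ps$size > object@genesPerPathway[2L])
      msg <- c(msg, "planted component larger than any pathway can be")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic study configuration
#'
#' Defaults describe a compact microarray-like cohort: 20 pathways of 12-16
#' genes, 200 pathway-free background genes, 15 cases vs 15 controls, log-scale
#' baseline Normal(8, 1), and one planted 8-gene connected component shifted by
#' 3 baseline standard deviations in cases.
#'
#' @param nPathways,genesPerPathway,edgeProb,nBackgroundGenes,nD,nNotD
#'   see \linkS4class{SimConfig}.
#' @param baselineMean,baselineSd,effectSize,plantSpecs,seed
#'   see \linkS4class{SimConfig}.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(effectSize = 0, plantSpecs = list(), seed = 3)
#' @export
simConfig <- function(nPathways = 20, genesPerPathway = c(12, 16),
                      edgeProb = 0.25, nBackgroundGenes = 200,
                      nD = 15, nNotD = 15, baselineMean = 8, baselineSd = 1,
                      effectSize = 3,
                      plantSpecs = list(list(pathway = 1L, size = 8L)),
                      seed = 1L) {
  obj <- new("SimConfig", nPathways = as.integer(nPathways),
             genesPerPathway = as.integer(genesPerPathway),
             edgeProb = as.numeric(edgeProb),
             nBackgroundGenes = as.integer(nBackgroundGenes),
             nD = as.integer(nD), nNotD = as.integer(nNotD),
             baselineMean = as.numeric(baselineMean),
             baselineSd = as.numeric(baselineSd),
             effectSize = as.numeric(effectSize),
             plantSpecs = lapply(plantSpecs, function(p)
               list(pathway = as.integer(p$pathway), size = as.integer(p$size))),
             seed = as.integer(seed))
  validObject(obj)
  obj
}
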