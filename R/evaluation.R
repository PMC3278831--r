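# Cross-dataset consistency metrics and the per-gene t-test baseline used to
# benchmark subnetwork discovery against single-gene ranking.

#' Per-gene Welch t-test ranking
#'
#' Welch t-test of phenotype \code{d} against the pooled remainder for every
#' gene, on the raw expression rows. Returned sorted by ascending p-value,
#' ties broken by descending |t| and then gene identifier. Genes with zero
#' variance in both groups get t = 0, p = 1 for equal means (and a signed
#' sentinel t with p = 0 for distinct means).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param d the phenotype of interest.
#' @return \code{data.frame} with columns \code{gene}, \code{t}, \code{df},
#'   \code{p}, one row per gene.
#' @export
ttestRank <- function(study, d) {
  labels <- phenotypeLabels(study)
  if (!d %in% labels) stop("unknown phenotype: ", d)
  x <- exprValues(study)
  a <- x[, labels == d, drop = FALSE]
  b <- x[, labels != d, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (ma == mb)
    t[eq] <- 0
    p[eq] <- 1
    ne <- degenerate & (ma != mb)
    t[ne] <- sign(ma[ne] - mb[ne]) * 1e9
    p[ne] <- 0
    df[degenerate] <- NA_real_
  }
  out <- data.frame(gene = rownames(x), t = unname(t), df = unname(df),
                    p = unname(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$t), out$gene, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Top genes of a t-test ranking
#'
#' @param ranking a \code{\link{ttestRank}} result.
#' @param k number of genes to take from the top.
#' @return Character vector of \code{k} gene identifiers.
#' @export
topRankedGenes <- function(ranking, k) {
  if (k < 1L || k > nrow(ranking)) stop("k out of range")
  ranking$gene[seq_len(k)]
}

#' Percentage overlap of two gene lists
#'
#' The overlap is counted against the smaller list: with gamma = min(|a|, |b|),
#' the percentage is 100 * |intersection| / gamma. A Jaccard denominator
#' (|union|) is available as an alternative.
#'
#' @param listA,listB non-empty character vectors (duplicates ignored).
#' @param denominator \code{"min"} (default) or \code{"jaccard"}.
#' @return List with \code{gamma} (size of the smaller list),
#'   \code{overlapPct}, and \code{matched} (the shared genes, sorted).
#' @examples
#' geneOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))
#' @export
geneOverlap <- function(listA, listB, denominator = c("min", "jaccard")) {
  denominator <- match.arg(denominator)
  a <- unique(as.character(listA))
  b <- unique(as.character(listB))
  if (length(a) == 0L || length(b) == 0L) stop("empty gene list")
  shared <- intersect(a, b)
  gamma <- min(length(a), length(b))
  den <- if (denominator == "min") gamma else length(union(a, b))
  list(gamma = gamma,
       overlapPct = 100 * length(shared) / den,
       matched = .csort(shared))
}

# normalize Subnetwork objects / plain records to list(pathway, genes, name)
.snRec <- function(x) {
  if (is(x, "Subnetwork"))
    list(name = x@name, pathway = x@pathway, genes = x@genes)
  else
    list(name = if (is.null(x$name)) NA_character_ else x$name,
         pathway = x$pathway, genes = x$genes)
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Percentage overlap of two subnetwork lists
#'
#' Two subnetworks match when they come from the same pathway, share at least
#' one gene, and their gene-set Jaccard index is at least \code{jaccardMin}.
#' Candidate pairs are matched greedily by descending Jaccard, each subnetwork
#' used at most once; the percentage is 100 * #matches / min(|a|, |b|).
#'
#' @param snA,snB non-empty lists of \linkS4class{Subnetwork} objects (or
#'   plain \code{list(pathway=, genes=)} records, e.g. from
#'   \code{\link{readResults}}).
#' @param jaccardMin minimum gene-set Jaccard for a match (default 0: any
#'   shared gene).
#' @return List with \code{gamma} (size of the smaller list),
#'   \code{overlapPct}, and \code{matched} (data.frame of matched pairs with
#'   their Jaccard index).
#' @export
subnetworkOverlap <- function(snA, snB, jaccardMin = 0) {
  if (length(snA) == 0L || length(snB) == 0L) stop("empty subnetwork list")
  a <- lapply(snA, .snRec)
  b <- lapply(snB, .snRec)
  cand <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (a[[i]]$pathway != b[[j]]$pathway) next
    if (length(intersect(a[[i]]$genes, b[[j]]$genes)) == 0L) next
    jac <- .jaccard(a[[i]]$genes, b[[j]]$genes)
    if (jac < jaccardMin) next
    cand <- rbind(cand, data.frame(i = i, j = j, jaccard = jac))
  }
  gamma <- min(length(a), length(b))
  if (is.null(cand))
    return(list(gamma = gamma, overlapPct = 0,
                matched = data.frame(nameA = character(0),
                                     nameB = character(0),
                                     jaccard = numeric(0))))
  cand <- cand[order(-cand$jaccard, cand$i, cand$j), , drop = FALSE]
  usedA <- logical(length(a))
  usedB <- logical(length(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]
    j <- cand$j[r]
    if (!usedA[i] && !usedB[j]) {
      keep[r] <- TRUE
      usedA[i] <- TRUE
      usedB[j] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  list(gamma = gamma,
       overlapPct = 100 * nrow(m) / gamma,
       matched = data.frame(
         nameA = vapply(m$i, function(i) a[[i]]$name, character(1)),
         nameB = vapply(m$j, function(j) b[[j]]$name, character(1)),
         jaccard = m$jaccard))
}

#' Component sizes formed by a gene list inside each pathway
#'
#' Runs the connected-component extraction at \code{minSize = 2} over the
#' given genes and tabulates the component sizes — used to contrast the
#' substantial subnetworks formed by subnetwork-discovery gene lists with the
#' fragmentary ones formed by equally sized single-gene-test lists.
#'
#' @param topGenes character vector of genes.
#' @param db a \linkS4class{PathwayDB}.
#' @return List with \code{sizes} (integer vector, one entry per component)
#'   and \code{histogram} (data.frame size, count).
#' @export
topGeneComponentSizes <- function(topGenes, db) {
  comps <- extractSubnetworks(topGenes, db, minSize = 2)
  sizes <- vapply(comps, snSize, integer(1))
  if (length(sizes)) {
    tab <- table(sizes)
    hist <- data.frame(size = as.integer(names(tab)),
                       count = as.integer(tab))
  } else {
    hist <- data.frame(size = integer(0), count = integer(0))
  }
  list(sizes = sizes, histogram = hist)
}

#' Agreement of a subnetwork with the per-gene t-test
#'
#' Percentage of the subnetwork's genes that are individually significant in
#' a t-test ranking (p strictly below the threshold).
#'
#' @param sp a \linkS4class{Subnetwork} or a character vector of genes.
#' @param ranking a \code{\link{ttestRank}} result covering every subnetwork
#'   gene.
#' @param pThreshold per-gene significance threshold (default 0.05, strict).
#' @return Percentage in [0, 100].
#' @export
subnetworkTtestConsistency <- function(sp, ranking, pThreshold = 0.05) {
  genes <- if (is(sp, "Subnetwork")) snGenes(sp) else as.character(sp)
  if (length(genes) == 0L) stop("empty subnetwork")
  hit <- match(genes, ranking$gene)
  if (anyNA(hit))
    stop("subnetwork gene(s) absent from the ranking: ",
         paste(genes[is.na(hit)], collapse = ", "))
  100 * sum(ranking$p[hit] < pThreshold) / length(genes)
}
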