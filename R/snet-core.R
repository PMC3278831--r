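# The subnetwork discovery algorithm: per-patient top-rank filtering, a
# cross-patient frequency filter, per-pathway connected-component extraction,
# per-patient subnetwork scoring, a Welch t-statistic between phenotype
# groups, and a label-permutation null over (size, t) pairs.

## ---- Step 1: filtering -----------------------------------------------------

# Logical genes x samples matrix: TRUE where the gene is in the sample's
# top-alpha% set. The cut keeps ceiling(alpha/100 * G) genes; ties at the
# boundary are broken by gene identifier (ascending, C collation) so the set
# is deterministic. Top sets depend only on within-sample ranks, never on
# phenotype labels, so they are computed once per study.
.topSetMatrix <- function(study, alpha) {
  x <- exprValues(study)
  g <- nrow(x)
  k <- ceiling(alpha / 100 * g)
  ids <- rownames(x)
  m <- matrix(FALSE, g, ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    o <- order(-x[, j], ids, method = "radix")
    m[o[seq_len(k)], j] <- TRUE
  }
  m
}

#' Top-ranked genes of one patient
#'
#' The \code{ceiling(alpha/100 * G)} highest-expressed genes of a sample,
#' where \code{G} is the total gene count. Ties at the cut boundary are broken
#' by gene identifier (ascending) so the set is deterministic.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param sample a sample identifier.
#' @param alpha percentage of genes to keep, in (0, 100].
#' @return Character vector of gene identifiers (in descending expression
#'   order).
#' @examples
#' m <- matrix(seq_len(40), 10, 4,
#'             dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
#' es <- ExpressionStudy(m, setNames(rep(c("a", "b"), 2), paste0("s", 1:4)))
#' topAlphaGenes(es, "s1", alpha = 20)
#' @export
topAlphaGenes <- function(study, sample, alpha = 10) {
  if (!sample %in% colnames(study)) stop("unknown sample: ", sample)
  if (!(alpha > 0 && alpha <= 100)) stop("alpha must be in (0, 100]")
  x <- exprValues(study)
  k <- ceiling(alpha / 100 * nrow(x))
  o <- order(-x[, sample], rownames(x), method = "radix")
  rownames(x)[o[seq_len(k)]]
}

#' Top-ranked gene sets of every patient
#'
#' @inheritParams topAlphaGenes
#' @return Named list (one element per sample, in study order) of character
#'   gene vectors.
#' @export
patientTopSets <- function(study, alpha = 10) {
  m <- .topSetMatrix(study, alpha)
  ids <- rownames(m)
  stats::setNames(lapply(seq_len(ncol(m)), function(j) ids[m[, j]]),
                  colnames(m))
}

#' Frequency filter across the patients of one phenotype
#'
#' A gene is retained when it appears in the top-ranked set of strictly more
#' than \code{beta}\% of the given patients.
#'
#' @param topSets list of character gene vectors, one per phenotype-d patient
#'   (e.g. a subset of \code{\link{patientTopSets}}).
#' @param beta frequency threshold in percent, in [0, 100).
#' @return Sorted character vector of candidate genes.
#' @examples
#' frequencyFilter(list(c("A", "B"), c("A"), c("A", "C"), c("B")), beta = 50)
#' @export
frequencyFilter <- function(topSets, beta = 50) {
  if (length(topSets) == 0L) stop("empty list of patient gene sets")
  if (!(beta >= 0 && beta < 100)) stop("beta must be in [0, 100)")
  n <- length(topSets)
  cnt <- table(unlist(lapply(topSets, unique), use.names = FALSE))
  .csort(names(cnt)[cnt > beta / 100 * n])
}

## ---- connected-component extraction ---------------------------------------

.hubGene <- function(genes, edges) {
  if (nrow(edges) == 0L) return(.csort(genes)[1L])
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  .csort(names(deg)[deg == max(deg)])[1L]
}

.makeName <- function(phenotype, pathway, hub) {
  if (is.na(phenotype) || !nzchar(phenotype)) paste(pathway, hub, sep = "_")
  else paste(phenotype, pathway, hub, sep = "_")
}

#' Extract connected subnetworks of a gene list within each pathway
#'
#' For each pathway independently, the pathway graph is restricted to edges
#' whose both endpoints belong to \code{genes}; every connected component with
#' at least \code{minSize} genes is returned as a \linkS4class{Subnetwork}.
#' Genes of the list with no surviving edge in a pathway are solitary there
#' and are discarded. A gene may appear in subnetworks of several pathways.
#'
#' @param genes character vector of candidate genes (e.g. from
#'   \code{\link{frequencyFilter}}).
#' @param db a \linkS4class{PathwayDB}.
#' @param minSize minimum component size in genes (>= 2).
#' @param phenotype optional phenotype tag carried into the subnetwork names.
#' @return List of \linkS4class{Subnetwork}, in pathway order then component
#'   discovery order.
#' @examples
#' db <- PathwayDB(list(p = data.frame(
#'   gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
#'   relation = "activate")))
#' extractSubnetworks(c("A", "B", "C", "D"), db, minSize = 2)
#' @export
extractSubnetworks <- function(genes, db, minSize = 5,
                               phenotype = NA_character_) {
  out <- list()
  for (pw in pathwayNames(db)) {
    e <- pathwayEdges(db, pw)
    keep <- e$gene_a %in% genes & e$gene_b %in% genes
    if (!any(keep)) next
    e <- e[keep, , drop = FALSE]
    comps <- .ufComponents(e$gene_a, e$gene_b)
    for (comp in comps) {
      if (length(comp) < minSize) next
      ce <- e[e$gene_a %in% comp & e$gene_b %in% comp, , drop = FALSE]
      rownames(ce) <- NULL
      g <- .csort(comp)
      out[[length(out) + 1L]] <- new(
        "Subnetwork",
        name = .makeName(phenotype, pw, .hubGene(g, ce)),
        phenotype = phenotype, pathway = pw, genes = g, edges = ce)
    }
  }
  out
}

## ---- Step 2: scoring -------------------------------------------------------

#' Per-patient subnetwork score
#'
#' The overall expression level of subnetwork \code{sp} in one patient: the
#' sum, over subnetwork genes \code{g} that are highly expressed (top-alpha)
#' in that patient, of \code{k_g / n}, where \code{k_g} is the number of
#' phenotype-d patients with \code{g} highly expressed and \code{n} the number
#' of phenotype-d patients. The patient may be of any phenotype; \code{k} and
#' \code{n} always refer to the phenotype-d group the subnetwork was extracted
#' for. The score lies in \code{[0, |sp|]}.
#'
#' @param sp a \linkS4class{Subnetwork} (or anything with \code{snGenes}).
#' @param patient sample identifier.
#' @param topSets named list of per-patient top-alpha gene vectors over all
#'   samples (see \code{\link{patientTopSets}}).
#' @param dSamples sample identifiers of the phenotype-d group.
#' @return Non-negative numeric score.
#' @export
scoreSubnetworkForPatient <- function(sp, patient, topSets, dSamples) {
  n <- length(dSamples)
  if (n == 0L) stop("phenotype-d group is empty")
  if (!patient %in% names(topSets)) stop("unknown patient: ", patient)
  genes <- if (is(sp, "Subnetwork")) snGenes(sp) else as.character(sp)
  hi <- intersect(genes, topSets[[patient]])
  if (length(hi) == 0L) return(0)
  k <- vapply(hi, function(g)
    sum(vapply(dSamples, function(s) g %in% topSets[[s]], logical(1))),
    numeric(1))
  sum(k / n)
}

#' Score vectors of a subnetwork for the two patient groups
#'
#' Scores every patient of the study with \code{\link{scoreSubnetworkForPatient}}
#' and splits the scores into the phenotype-d group and the pooled remainder,
#' each in study sample order.
#'
#' @param sp a \linkS4class{Subnetwork}.
#' @param study an \linkS4class{ExpressionStudy}.
#' @param d the phenotype of interest.
#' @param alpha top-rank percentage used to build the top sets.
#' @param topSets optional precomputed \code{\link{patientTopSets}} result.
#' @return List with elements \code{d} and \code{notD}, named numeric vectors.
#' @export
scoreVectors <- function(sp, study, d, alpha = 10, topSets = NULL) {
  labels <- phenotypeLabels(study)
  if (!d %in% labels) stop("unknown phenotype: ", d)
  dSamples <- names(labels)[labels == d]
  oSamples <- names(labels)[labels != d]
  if (length(dSamples) < 2L || length(oSamples) < 2L)
    stop("each group needs at least 2 patients")
  if (is.null(topSets)) topSets <- patientTopSets(study, alpha)
  sc <- vapply(names(labels), function(s)
    scoreSubnetworkForPatient(sp, s, topSets, dSamples), numeric(1))
  list(d = sc[dSamples], notD = sc[oSamples])
}

#' Welch two-sample t-statistic
#'
#' Unequal-variance t-statistic, positive when \code{mean(a) > mean(b)}. When
#' both sample variances are zero the statistic is 0 for equal means and a
#' signed large sentinel (1e9) otherwise, so such degenerate subnetworks sort
#' above any finite statistic.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return The t-statistic.
#' @examples
#' welchT(c(3, 4, 5), c(1, 2, 3))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  ma <- mean(a)
  mb <- mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(0)
    return(sign(ma - mb) * 1e9)
  }
  (ma - mb) / sqrt(va / length(a) + vb / length(b))
}

## ---- one pass of Steps 1-2 over all phenotypes -----------------------------

# Pathway edges pre-resolved to indices in the study's gene universe; edges
# touching a gene absent from the study can never survive the candidate
# filter and are dropped here once.
.pathwayIndex <- function(db, geneIds) {
  idx <- list()
  for (pw in pathwayNames(db)) {
    e <- pathwayEdges(db, pw)
    ia <- match(e$gene_a, geneIds)
    ib <- match(e$gene_b, geneIds)
    keep <- !is.na(ia) & !is.na(ib)
    if (!any(keep)) next
    idx[[length(idx) + 1L]] <- list(
      name = pw, ia = ia[keep], ib = ib[keep],
      relation = e$relation[keep])
  }
  idx
}

# Steps 1 + 2 for every phenotype under one label assignment. Returns a list
# of records: phenotype, pathway, gene indices, edge indices (into the
# pathway's index entry), per-sample scores, dIdx and t. Used both for the
# observed labels and, with detail = FALSE (sizes and t only), inside the
# permutation loop.
.snetOnePass <- function(topM, labels, idx, params, detail = FALSE) {
  nSamp <- ncol(topM)
  recs <- list()
  for (d in unique(labels)) {
    dIdx <- which(labels == d)
    nd <- length(dIdx)
    if (nd < 2L || nSamp - nd < 2L) next
    cnt <- rowSums(topM[, dIdx, drop = FALSE])
    gl <- cnt > params@beta / 100 * nd
    for (p in seq_along(idx)) {
      pw <- idx[[p]]
      keep <- gl[pw$ia] & gl[pw$ib]
      if (!any(keep)) next
      ea <- pw$ia[keep]
      eb <- pw$ib[keep]
      comps <- .ufComponents(ea, eb)
      for (comp in comps) {
        if (length(comp) < params@minSize) next
        w <- cnt[comp] / nd
        sc <- colSums(topM[comp, , drop = FALSE] * w)
        t <- welchT(sc[dIdx], sc[-dIdx])
        rec <- if (detail) {
          list(phenotype = d, pathwayIdx = p, genes = comp,
               edgeSel = which(keep)[ea %in% comp & eb %in% comp],
               scores = sc, dIdx = dIdx, size = length(comp), t = t)
        } else {
          list(size = length(comp), t = t)
        }
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  recs
}

## ---- Step 3: permutation null and p-values ---------------------------------

#' Build the label-permutation null distribution
#'
#' For each permutation the phenotype labels are reshuffled across all samples
#' (group sizes preserved), the candidate-gene filter and component extraction
#' are rerun for every phenotype, and every resulting subnetwork contributes
#' one (size, t-statistic) entry. Per-patient top-alpha sets do not depend on
#' the labels and are computed once.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param db a \linkS4class{PathwayDB}.
#' @param params an \linkS4class{SNetParams}; \code{params@seed} seeds the
#'   permutations.
#' @return A \linkS4class{NullDistribution}.
#' @export
buildNull <- function(study, db, params) {
  topM <- .topSetMatrix(study, params@alpha)
  idx <- .pathwayIndex(db, rownames(study))
  labels <- unname(phenotypeLabels(study))
  .buildNullFast(topM, idx, labels, params)
}

.buildNullFast <- function(topM, idx, labels, params) {
  sizes <- vector("list", params@nPerm)
  ts <- vector("list", params@nPerm)
  set.seed(params@seed)
  for (p in seq_len(params@nPerm)) {
    perm <- sample(labels)
    recs <- .snetOnePass(topM, perm, idx, params, detail = FALSE)
    if (length(recs)) {
      sizes[[p]] <- vapply(recs, `[[`, integer(1), "size")
      ts[[p]] <- vapply(recs, `[[`, numeric(1), "t")
    }
  }
  new("NullDistribution",
      sizes = as.integer(unlist(sizes, use.names = FALSE)),
      tStats = as.numeric(unlist(ts, use.names = FALSE)),
      nPermDone = params@nPerm)
}

#' Permutation p-value of one subnetwork
#'
#' Conditions the null on subnetwork size and takes a two-sided tail in the
#' t-statistic with an add-one pseudocount:
#' \code{p = (1 + #\{entries: |t| >= |tObs|\}) / (1 + #entries)}. With
#' \code{sizeBin = "tail"} (default) the conditioning set holds every null
#' entry with size >= the observed size; \code{"exact"} restricts to equal
#' size. An empty conditioning set yields the degenerate p = 1.
#'
#' @param size observed subnetwork size (genes).
#' @param tObs observed t-statistic.
#' @param null a \linkS4class{NullDistribution}.
#' @param sizeBin \code{"tail"} or \code{"exact"}.
#' @return p-value in (0, 1].
#' @examples
#' nd <- new("NullDistribution", sizes = c(5L, 5L, 6L),
#'           tStats = c(1, 3, 2.5), nPermDone = 1L)
#' nullPValue(5, 2.0, nd)   # (1 + 2) / (1 + 3)
#' @export
nullPValue <- function(size, tObs, null, sizeBin = c("tail", "exact")) {
  sizeBin <- match.arg(sizeBin)
  sel <- if (sizeBin == "tail") null@sizes >= size else null@sizes == size
  (1 + sum(abs(null@tStats[sel]) >= abs(tObs))) / (1 + sum(sel))
}

## ---- full run --------------------------------------------------------------

#' Run the full subnetwork discovery procedure
#'
#' Takes every phenotype of the study in turn as the phenotype of interest,
#' applies the top-rank and frequency filters, extracts per-pathway connected
#' components, scores them per patient and computes the group t-statistic;
#' pools the subnetworks of all phenotypes, removes exact duplicates (same
#' pathway, same gene set) keeping the occurrence with the larger |t|, and
#' attaches p-values from one shared label-permutation null. Subnetworks with
#' p <= \code{pCutoff} (inclusive) are flagged significant.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param db a \linkS4class{PathwayDB}.
#' @param params an \linkS4class{SNetParams}.
#' @return An \linkS4class{SNetResult}.
#' @examples
#' \donttest{
#' sim <- snetPreset("planted-small", seed = 1)
#' res <- runSNet(sim$study, sim$db, sim$params)
#' resultTable(res)
#' }
#' @export
runSNet <- function(study, db, params = SNetParams()) {
  validObject(study)
  validObject(params)
  topM <- .topSetMatrix(study, params@alpha)
  idx <- .pathwayIndex(db, rownames(study))
  labels <- phenotypeLabels(study)
  geneIds <- rownames(study)
  recs <- .snetOnePass(topM, unname(labels), idx, params, detail = TRUE)

  sn <- lapply(recs, function(r) {
    pw <- idx[[r$pathwayIdx]]
    ce <- data.frame(gene_a = geneIds[pw$ia[r$edgeSel]],
                     gene_b = geneIds[pw$ib[r$edgeSel]],
                     relation = pw$relation[r$edgeSel],
                     stringsAsFactors = FALSE)
    g <- .csort(geneIds[r$genes])
    sc <- stats::setNames(r$scores, names(labels))
    new("ScoredSubnetwork",
        name = .makeName(r$phenotype, pw$name, .hubGene(g, ce)),
        phenotype = r$phenotype, pathway = pw$name, genes = g, edges = ce,
        perPatientScore = sc,
        scoreVecD = sc[r$dIdx], scoreVecNotD = sc[-r$dIdx],
        tStat = r$t, pValue = NA_real_)
  })

  # deduplicate identical (pathway, gene set) pairs, keeping the larger |t|
  if (length(sn)) {
    key <- vapply(sn, function(s)
      paste(s@pathway, paste(s@genes, collapse = ";"), sep = "\r"),
      character(1))
    absT <- vapply(sn, function(s) abs(s@tStat), numeric(1))
    o <- order(absT, decreasing = TRUE)
    sn <- sn[o][!duplicated(key[o])]
  }

  null <- .buildNullFast(topM, idx, unname(labels), params)
  sn <- lapply(sn, function(s) {
    s@pValue <- nullPValue(length(s@genes), s@tStat, null, params@sizeBin)
    s
  })

  if (length(sn)) {
    p <- vapply(sn, pValue, numeric(1))
    absT <- vapply(sn, function(s) abs(s@tStat), numeric(1))
    nm <- vapply(sn, snName, character(1))
    sn <- sn[order(p, -absT, nm, method = "radix")]
  }
  new("SNetResult", params = params, scored = sn, null = null)
}
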