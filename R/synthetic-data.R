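# Synthetic fixture generator: random connected pathway graphs, two-phenotype
# Gaussian expression cohorts with planted up-shifted connected components,
# and paired "platform" cohorts with independent noise, samples and gene
# dropout. All generation is a pure function of (config, seed).

# random connected graph on `genes`: a random spanning tree (each vertex
# joins a uniformly chosen earlier vertex of a shuffled order) plus each
# remaining pair independently with probability edgeProb
.randomConnectedEdges <- function(genes, edgeProb) {
  n <- length(genes)
  ord <- sample(genes)
  a <- character(0)
  b <- character(0)
  for (i in seq_len(n)[-1L]) {
    a <- c(a, ord[sample.int(i - 1L, 1L)])
    b <- c(b, ord[i])
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pa <- genes[pairs[, 1L]]
  pb <- genes[pairs[, 2L]]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  inTree <- paste(pmin(pa, pb), pmax(pa, pb)) %in% paste(lo, hi)
  extra <- !inTree & stats::runif(length(pa)) < edgeProb
  data.frame(gene_a = c(a, pa[extra]), gene_b = c(b, pb[extra]),
             relation = sample(c("activate", "inhibit"),
                               length(a) + sum(extra), replace = TRUE),
             stringsAsFactors = FALSE)
}

# grow a connected vertex subset of the given size by random frontier
# expansion
.randomConnectedSubset <- function(edges, size) {
  verts <- unique(c(edges$gene_a, edges$gene_b))
  if (size > length(verts))
    stop("planted component size unsatisfiable: pathway has only ",
         length(verts), " genes")
  adj <- split(c(edges$gene_b, edges$gene_a),
               c(edges$gene_a, edges$gene_b))
  sel <- sample(verts, 1L)
  while (length(sel) < size) {
    frontier <- setdiff(unique(unlist(adj[sel], use.names = FALSE)), sel)
    if (length(frontier) == 0L)
      stop("planted component size unsatisfiable: ran out of neighbours")
    sel <- c(sel, sample(frontier, 1L))
  }
  .csort(sel)
}

#' Generate a synthetic pathway database with planted components
#'
#' Each pathway is a connected random graph (random spanning tree plus extra
#' edges with probability \code{edgeProb}), with relations drawn uniformly
#' from activate/inhibit. For every plant spec a connected gene subset of the
#' stated size is selected and recorded in the manifest; the cohort generator
#' up-shifts exactly those genes in the case group.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return List with \code{db} (a \linkS4class{PathwayDB}) and
#'   \code{manifest} (list of \code{list(pathway, genes)} per plant).
#' @examples
#' sim <- generatePathwayDB(simConfig(seed = 42))
#' sim$manifest[[1]]
#' @export
generatePathwayDB <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  pathways <- list()
  for (p in seq_len(cfg@nPathways)) {
    ng <- cfg@genesPerPathway[1L] +
      sample.int(cfg@genesPerPathway[2L] - cfg@genesPerPathway[1L] + 1L,
                 1L) - 1L
    genes <- sprintf("P%02dG%02d", p, seq_len(ng))
    pathways[[sprintf("pathway_%02d", p)]] <-
      .randomConnectedEdges(genes, cfg@edgeProb)
  }
  manifest <- lapply(cfg@plantSpecs, function(ps) {
    pw <- sprintf("pathway_%02d", ps$pathway)
    list(pathway = pw,
         genes = .randomConnectedSubset(pathways[[pw]], ps$size))
  })
  list(db = PathwayDB(pathways), manifest = manifest)
}

#' Generate a two-phenotype expression cohort
#'
#' Genes are all pathway genes plus \code{nBackgroundGenes} pathway-free
#' background genes. Expression is i.i.d. Normal(baselineMean, baselineSd) on
#' a log-like scale; genes listed in the manifest gain
#' \code{effectSize * baselineSd} in the case samples. The first \code{nD}
#' samples are labelled \code{"case"}, the rest \code{"control"}.
#'
#' @param db a \linkS4class{PathwayDB} from \code{\link{generatePathwayDB}}.
#' @param manifest the matching plant manifest.
#' @param cfg the \linkS4class{SimConfig}.
#' @param seed RNG seed for this cohort (defaults to \code{cfg@seed}).
#' @param samplePrefix prefix of the generated sample identifiers.
#' @return An \linkS4class{ExpressionStudy}.
#' @export
generateCohort <- function(db, manifest, cfg, seed = cfg@seed,
                           samplePrefix = "S") {
  set.seed(seed)
  genes <- c(pathwayGenes(db),
             if (cfg@nBackgroundGenes > 0L)
               sprintf("BG%04d", seq_len(cfg@nBackgroundGenes)))
  m <- cfg@nD + cfg@nNotD
  samples <- sprintf("%s%03d", samplePrefix, seq_len(m))
  vals <- matrix(stats::rnorm(length(genes) * m,
                              mean = cfg@baselineMean,
                              sd = cfg@baselineSd),
                 length(genes), m, dimnames = list(genes, samples))
  planted <- unique(unlist(lapply(manifest, `[[`, "genes"),
                           use.names = FALSE))
  if (length(planted) && cfg@effectSize != 0)
    vals[planted, seq_len(cfg@nD)] <-
      vals[planted, seq_len(cfg@nD)] + cfg@effectSize * cfg@baselineSd
  labels <- stats::setNames(rep(c("case", "control"), c(cfg@nD, cfg@nNotD)),
                            samples)
  ExpressionStudy(vals, labels)
}

#' Generate a pair of cohorts emulating two platforms
#'
#' Two cohorts sharing the same pathway database and planted components, with
#' independent noise and disjoint sample draws. Each cohort independently
#' drops a \code{geneDropout} fraction of its non-planted genes, emulating
#' probe-coverage differences between platforms; planted genes are never
#' dropped.
#'
#' @inheritParams generateCohort
#' @param geneDropout fraction of non-planted genes dropped per cohort,
#'   in [0, 1).
#' @return List of two \linkS4class{ExpressionStudy} objects
#'   (\code{studyA}, \code{studyB}).
#' @export
generatePlatformPair <- function(db, manifest, cfg, geneDropout = 0,
                                 seed = cfg@seed) {
  if (!(geneDropout >= 0 && geneDropout < 1))
    stop("geneDropout must be in [0, 1)")
  planted <- unique(unlist(lapply(manifest, `[[`, "genes"),
                           use.names = FALSE))
  one <- function(subSeed, prefix) {
    study <- generateCohort(db, manifest, cfg, seed = subSeed,
                            samplePrefix = prefix)
    if (geneDropout > 0) {
      set.seed(subSeed + 1L)
      g <- rownames(study)
      droppable <- setdiff(g, planted)
      drop <- droppable[stats::runif(length(droppable)) < geneDropout]
      study <- study[!g %in% drop, ]
    }
    study
  }
  list(studyA = one(seed * 2L + 11L, "A"),
       studyB = one(seed * 2L + 12L, "B"))
}
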