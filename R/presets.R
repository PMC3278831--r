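# Named study conditions used by the test-suite, the command-line fixture
# generator and the reproduction script. Each preset bundles the generator
# configuration with the discovery parameters appropriate to it, so every
# consumer runs the same conditions.

#' Standard synthetic study presets
#'
#' \describe{
#'   \item{\code{"null"}}{No planted signal (effect size 0), 20 pathways,
#'     15 + 15 patients — an exchangeable-label cohort for calibration. The
#'     bundled parameters use a permissive filter (alpha = 30, beta = 30):
#'     with the default operating point (alpha = 10, beta = 50) the frequency
#'     filter passes essentially no gene on unstructured data, which is the
#'     method's false-positive defence but leaves nothing to calibrate on.}
#'   \item{\code{"planted-small"}}{One planted 8-gene connected component at
#'     effect size 3 (baseline-sd units); default filter (alpha = 10,
#'     beta = 50). The recovery benchmark.}
#'   \item{\code{"platform-pair"}}{Three planted 8-gene components at effect
#'     size 2.3 with 2000 background genes, 10 + 10 patients and 10\%
#'     per-platform gene dropout — a regime where per-gene t rankings churn
#'     between datasets while the rank-plus-connectivity filter stays stable.
#'     Used for the cross-dataset consistency comparison. Runs 1000
#'     permutations: the size-conditioned null needs enough re-formed large
#'     components for p-values below the cutoff to be reachable.}
#' }
#' The other presets run 200 permutations: enough for p-values near the 0.05
#' cutoff while keeping replicated runs cheap.
#'
#' @param preset preset name.
#' @param seed integer seed; drives the pathway database, the cohort(s) and
#'   the discovery permutations.
#' @return List with \code{cfg}, \code{db}, \code{manifest}, \code{params},
#'   and either \code{study} or (for \code{"platform-pair"}) \code{studyA},
#'   \code{studyB} and \code{geneDropout}.
#' @examples
#' sim <- snetPreset("planted-small", seed = 7)
#' sim$manifest[[1]]$genes
#' @export
snetPreset <- function(preset = c("null", "planted-small", "platform-pair"),
                       seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "null") {
    cfg <- simConfig(nPathways = 20, genesPerPathway = c(12, 16),
                     edgeProb = 0.25, nBackgroundGenes = 200,
                     nD = 15, nNotD = 15, effectSize = 0,
                     plantSpecs = list(), seed = seed)
    params <- SNetParams(alpha = 30, beta = 30, nPerm = 200, minSize = 5,
                         seed = seed + 1L)
  } else if (preset == "planted-small") {
    cfg <- simConfig(nPathways = 20, genesPerPathway = c(12, 16),
                     edgeProb = 0.25, nBackgroundGenes = 200,
                     nD = 15, nNotD = 15, effectSize = 3,
                     plantSpecs = list(list(pathway = 1L, size = 8L)),
                     seed = seed)
    params <- SNetParams(alpha = 10, beta = 50, nPerm = 200, minSize = 5,
                         seed = seed + 1L)
  } else {
    cfg <- simConfig(nPathways = 20, genesPerPathway = c(12, 16),
                     edgeProb = 0.25, nBackgroundGenes = 2000,
                     nD = 10, nNotD = 10, effectSize = 2.3,
                     plantSpecs = list(list(pathway = 1L, size = 8L),
                                       list(pathway = 2L, size = 8L),
                                       list(pathway = 3L, size = 8L)),
                     seed = seed)
    params <- SNetParams(alpha = 10, beta = 50, nPerm = 1000, minSize = 5,
                         seed = seed + 1L)
  }
  gen <- generatePathwayDB(cfg)
  out <- list(cfg = cfg, db = gen$db, manifest = gen$manifest,
              params = params)
  if (preset == "platform-pair") {
    pair <- generatePlatformPair(gen$db, gen$manifest, cfg,
                                 geneDropout = 0.1, seed = seed)
    out$studyA <- pair$studyA
    out$studyB <- pair$studyB
    out$geneDropout <- 0.1
  } else {
    out$study <- generateCohort(gen$db, gen$manifest, cfg, seed = seed + 500L)
  }
  out
}
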