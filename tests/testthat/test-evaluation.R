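evalStudy <- local({
  set.seed(123)
  g <- sprintf("e%02d", 1:30)
  v <- matrix(rnorm(30 * 10, 8, 1), 30, 10,
              dimnames = list(g, sprintf("s%02d", 1:10)))
  v["e01", 1:5] <- v["e01", 1:5] + 4      # strongly shifted gene
  v["e02", ] <- 3                         # identical in both groups
  makeStudy(v, rep(c("d", "c"), each = 5))
})

test_that("per-gene ranking matches stats::t.test and orders by p", {
  rk <- ttestRank(evalStudy, "d")
  expect_equal(nrow(rk), 30L)
  expect_equal(rk$gene[1], "e01")
  # oracle: independent Welch computation per gene
  v <- exprValues(evalStudy)
  for (g in c("e01", "e05", "e17")) {
    tt <- t.test(v[g, 1:5], v[g, 6:10], var.equal = FALSE)
    i <- match(g, rk$gene)
    expect_equal(rk$t[i], unname(tt$statistic))
    expect_equal(rk$p[i], tt$p.value)
  }
  expect_true(all(diff(rk$p) >= 0))
  # constant gene: t = 0, p = 1, ranked last
  i <- match("e02", rk$gene)
  expect_equal(rk$t[i], 0)
  expect_equal(rk$p[i], 1)
  expect_equal(i, 30L)
  expect_length(topRankedGenes(rk, 7), 7L)
  expect_error(topRankedGenes(rk, 0), "out of range")
})

test_that("gene overlap uses the smaller list as denominator", {
  expect_equal(geneOverlap(c("g1", "g2"), c("g1", "g2"))$overlapPct, 100)
  expect_equal(geneOverlap(c("g1", "g2"), c("g3", "g4"))$overlapPct, 0)
  ov <- geneOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))
  expect_equal(ov$gamma, 3L)
  expect_equal(ov$overlapPct, 100 * 2 / 3)
  expect_equal(ov$matched, c("g2", "g3"))
  jac <- geneOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"),
                     denominator = "jaccard")
  expect_equal(jac$overlapPct, 100 * 2 / 5)
  expect_error(geneOverlap(character(0), "g1"), "empty")
})

test_that("overlap metrics are symmetric and bounded", {
  set.seed(31)
  for (rep in 1:20) {
    a <- sample(LETTERS, sample(2:10, 1))
    b <- sample(LETTERS, sample(2:10, 1))
    oab <- geneOverlap(a, b)$overlapPct
    expect_equal(oab, geneOverlap(b, a)$overlapPct)
    expect_gte(oab, 0)
    expect_lte(oab, 100)
  }
})

mkSn <- function(pathway, genes)
  list(name = paste0(pathway, "_", genes[1]), pathway = pathway,
       genes = genes)

test_that("subnetwork overlap matches greedily within pathways, one-to-one", {
  a <- list(mkSn("P", c("A", "B", "C")), mkSn("P", c("D", "E")))
  b <- list(mkSn("P", c("B", "C", "F")))
  ov <- subnetworkOverlap(a, b)
  expect_equal(ov$gamma, 1L)
  expect_equal(ov$overlapPct, 100)      # one match / min(2, 1)
  expect_equal(nrow(ov$matched), 1L)
  expect_equal(ov$matched$jaccard, 2 / 4)
  same <- subnetworkOverlap(a, a)
  expect_equal(same$overlapPct, 100)
  noShare <- subnetworkOverlap(a, list(mkSn("Q", c("A", "B"))))
  expect_equal(noShare$overlapPct, 0)
  # symmetric
  expect_equal(subnetworkOverlap(b, a)$overlapPct, ov$overlapPct)
  # jaccardMin filters weak matches
  strict <- subnetworkOverlap(a, b, jaccardMin = 0.9)
  expect_equal(strict$overlapPct, 0)
})

test_that("component-size histograms reflect the induced graph", {
  db <- PathwayDB(list(p = data.frame(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
    relation = "activate")))
  none <- topGeneComponentSizes(c("X", "Y"), db)
  expect_length(none$sizes, 0L)
  one <- topGeneComponentSizes(c("A", "B", "C"), db)
  expect_equal(one$sizes, 3L)
  db2 <- PathwayDB(list(p = data.frame(
    gene_a = c("A", "C"), gene_b = c("B", "D"), relation = "activate")))
  two <- topGeneComponentSizes(c("A", "B", "C", "D"), db2)
  expect_equal(sort(two$sizes), c(2L, 2L))
  expect_equal(two$histogram, data.frame(size = 2L, count = 2L))
})

test_that("subnetwork/t-test agreement is the percentage of significant members", {
  rk <- data.frame(gene = sprintf("v%02d", 1:11),
                   t = 3, df = 10,
                   p = c(rep(0.01, 8), rep(0.5, 3)))
  expect_equal(subnetworkTtestConsistency(rk$gene, rk), 100 * 8 / 11)
  rkAll <- transform(rk, p = 0.001)
  expect_equal(subnetworkTtestConsistency(rk$gene, rkAll), 100)
  rkNone <- transform(rk, p = 0.9)
  expect_equal(subnetworkTtestConsistency(rk$gene, rkNone), 0)
  # threshold is strict
  rkEdge <- transform(rk, p = 0.05)
  expect_equal(subnetworkTtestConsistency(rk$gene, rkEdge), 0)
  expect_error(subnetworkTtestConsistency(c("v01", "zz"), rk), "absent")
})
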