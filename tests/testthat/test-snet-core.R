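# A 20-gene, 4-sample study with known structure, reused across tests.
coreStudy <- local({
  set.seed(42)
  g <- sprintf("g%02d", 1:20)
  v <- matrix(rnorm(80, 8, 1), 20, 4,
              dimnames = list(g, paste0("s", 1:4)))
  makeStudy(v, c("d", "d", "c", "c"))
})

test_that("top-alpha keeps ceiling(alpha% * G) genes, highest first", {
  top <- topAlphaGenes(coreStudy, "s1", alpha = 10)   # ceil(0.1*20) = 2
  expect_length(top, 2L)
  v <- exprValues(coreStudy)[, "s1"]
  expect_setequal(top, names(sort(v, decreasing = TRUE))[1:2])
  expect_length(topAlphaGenes(coreStudy, "s1", alpha = 100), 20L)
  expect_length(topAlphaGenes(coreStudy, "s1", alpha = 15), 3L)  # ceil(3)
  expect_error(topAlphaGenes(coreStudy, "nope"), "unknown sample")
})

test_that("boundary ties break by gene identifier, ascending", {
  ids <- c("z9", "a1", "m5", "b2", "k4", "c3", "x8", "d4", "y7", "e5")
  es <- makeStudy(matrix(c(rep(5, 10), 1:10, rep(5, 10), 10:1), 10, 4,
                         dimnames = list(ids, paste0("s", 1:4))),
                  c("d", "d", "c", "c"))
  expect_equal(topAlphaGenes(es, "s1", alpha = 10), "a1")
  expect_equal(topAlphaGenes(es, "s3", alpha = 20), c("a1", "b2"))
})

test_that("frequency filter is strictly greater-than beta percent", {
  sets <- list(p1 = c("A", "B"), p2 = c("A"), p3 = c("A", "C"), p4 = c("B"))
  expect_equal(frequencyFilter(sets, beta = 50), "A")      # 3 of 4 > 2
  expect_false("B" %in% frequencyFilter(sets, beta = 50))  # 2 of 4, not > 2
  expect_setequal(frequencyFilter(sets, beta = 0), c("A", "B", "C"))
  expect_error(frequencyFilter(list(), 50), "empty")
})

test_that("raising beta never adds a gene (monotonicity)", {
  set.seed(7)
  for (rep in 1:20) {
    sets <- lapply(1:6, function(i) sample(LETTERS[1:12], sample(3:8, 1)))
    prev <- frequencyFilter(sets, 0)
    for (beta in c(20, 40, 60, 80)) {
      cur <- frequencyFilter(sets, beta)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("subnetworks are induced per-pathway components; solitary genes drop", {
  db <- PathwayDB(list(p = data.frame(
    gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
    relation = "activate")))
  sn <- extractSubnetworks(c("A", "B", "C", "D"), db, minSize = 2)
  expect_length(sn, 1L)   # D's only edge reaches E, outside the list
  expect_equal(snGenes(sn[[1]]), c("A", "B", "C"))
  expect_equal(nrow(snEdges(sn[[1]])), 2L)
  expect_length(extractSubnetworks(character(0), db, minSize = 2), 0L)
})

test_that("a gene connected in two pathways appears in a subnetwork of each", {
  db <- PathwayDB(list(
    p1 = data.frame(gene_a = c("X", "U"), gene_b = c("U", "V"),
                    relation = "activate"),
    p2 = data.frame(gene_a = c("X", "W"), gene_b = c("W", "Z"),
                    relation = "inhibit")))
  sn <- extractSubnetworks(c("X", "U", "V", "W", "Z"), db, minSize = 2)
  expect_equal(vapply(sn, snPathway, ""), c("p1", "p2"))
  expect_true(all(vapply(sn, function(s) "X" %in% snGenes(s), TRUE)))
})

test_that("subnetwork names use the maximum-degree hub, ties lexicographic", {
  db <- PathwayDB(list(hubpw = data.frame(
    gene_a = c("B", "B", "B"), gene_b = c("A", "C", "D"),
    relation = "activate")))
  sn <- extractSubnetworks(c("A", "B", "C", "D"), db, minSize = 2,
                           phenotype = "ph")
  expect_equal(snName(sn[[1]]), "ph_hubpw_B")
  # 4-cycle: all degrees equal, lexicographically smallest wins
  db2 <- PathwayDB(list(cyc = data.frame(
    gene_a = c("N", "M", "Q", "P"), gene_b = c("M", "Q", "P", "N"),
    relation = "activate")))
  sn2 <- extractSubnetworks(c("M", "N", "P", "Q"), db2, minSize = 2)
  expect_equal(snName(sn2[[1]]), "cyc_M")
})

test_that("per-patient score sums k/n over the patient's highly expressed genes", {
  topSets <- list(d1 = c("A", "C"), d2 = c("A"), d3 = c("A", "B"),
                  d4 = c("C"), o1 = c("A", "B"), o2 = c("Z"))
  dS <- c("d1", "d2", "d3", "d4")
  # patient o1 holds A (k=3) and B (k=1); n=4 -> 3/4 + 1/4 = 1
  expect_equal(scoreSubnetworkForPatient(c("A", "B", "C"), "o1",
                                         topSets, dS), 1.0)
  expect_equal(scoreSubnetworkForPatient(c("A", "B", "C"), "o2",
                                         topSets, dS), 0)
  # every gene in every d-patient's set and in the scored patient's set
  full <- list(d1 = c("A", "B"), d2 = c("A", "B"), o1 = c("A", "B"))
  expect_equal(scoreSubnetworkForPatient(c("A", "B"), "o1", full,
                                         c("d1", "d2")), 2)
})

test_that("scores stay within [0, |sp|] on randomized inputs", {
  set.seed(99)
  genes <- LETTERS[1:15]
  for (rep in 1:50) {
    topSets <- lapply(1:8, function(i) sample(genes, sample(1:10, 1)))
    names(topSets) <- paste0("p", 1:8)
    dS <- paste0("p", 1:4)
    sp <- sample(genes, sample(2:8, 1))
    sc <- scoreSubnetworkForPatient(sp, sample(names(topSets), 1),
                                    topSets, dS)
    expect_gte(sc, 0)
    expect_lte(sc, length(sp))
  }
})

test_that("score vectors split by group; k and n always come from d", {
  sp <- new("Subnetwork", name = "t", phenotype = "d", pathway = "p",
            genes = c("g01", "g02"),
            edges = data.frame(gene_a = "g01", gene_b = "g02",
                               relation = "activate"))
  sv <- scoreVectors(sp, coreStudy, "d", alpha = 50)
  expect_length(sv$d, 2L)
  expect_length(sv$notD, 2L)
  # oracle: recompute a not-d patient's score with d-group k/n by hand
  ts <- patientTopSets(coreStudy, 50)
  k <- vapply(c("g01", "g02"), function(g)
    sum(g %in% ts$s1, g %in% ts$s2), numeric(1))
  hand <- sum((k / 2)[c("g01", "g02") %in% ts$s3])
  expect_equal(unname(sv$notD["s3"]), hand)
  expect_error(scoreVectors(sp, coreStudy, "z"), "unknown phenotype")
})

test_that("welch t matches the textbook computation and honours sentinels", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welchT(c(2, 2, 2), c(1, 1, 1)), 1e9)
  expect_equal(welchT(c(1, 1, 1), c(2, 2, 2)), -1e9)
  a <- c(3, 4, 5)
  b <- c(1, 2, 3)
  expect_equal(welchT(a, b),
               unname(t.test(a, b, var.equal = FALSE)$statistic))
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(sample(3:9, 1))
    y <- rnorm(sample(3:9, 1), mean = 1)
    expect_equal(welchT(x, y),
                 unname(t.test(x, y, var.equal = FALSE)$statistic))
  }
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("the permutation null is deterministic and centred for null data", {
  set.seed(314)
  v <- matrix(rnorm(60 * 12, 8, 1), 60, 12,
              dimnames = list(sprintf("n%02d", 1:60), sprintf("s%02d", 1:12)))
  es <- makeStudy(v, rep(c("d", "c"), each = 6))
  db <- PathwayDB(list(p = data.frame(
    gene_a = sprintf("n%02d", 1:19), gene_b = sprintf("n%02d", 2:20),
    relation = "activate")))
  params <- SNetParams(alpha = 40, beta = 30, nPerm = 40, minSize = 3,
                       seed = 9)
  n1 <- buildNull(es, db, params)
  n2 <- buildNull(es, db, params)
  expect_identical(nullEntries(n1), nullEntries(n2))
  expect_identical(nPermDone(n1), 40L)
  ents <- nullEntries(n1)
  expect_true(all(ents$size >= 3))
  # exchangeable labels: null t-statistics sit near zero on the scale of a
  # genuine signal (|t| ~ 10+). The candidate filter conditions on the
  # permuted d-group, so a small positive offset (< one null sd) is expected
  # and shared by observed and permuted statistics alike.
  expect_lt(abs(mean(ents$tStat)), 1.5)
  expect_gt(mean(ents$tStat < 0), 0.05)  # both signs occur
})

test_that("p-values follow the size-conditioned pseudocount formula", {
  nd <- new("NullDistribution", sizes = c(5L, 5L, 6L),
            tStats = c(1.0, 3.0, 2.5), nPermDone = 1L)
  expect_equal(nullPValue(5, 2.0, nd), (1 + 2) / (1 + 3))
  expect_equal(nullPValue(5, 0, nd), 1.0)
  expect_equal(nullPValue(6, 2.0, nd, sizeBin = "exact"), (1 + 1) / (1 + 1))
  expect_equal(nullPValue(9, 2.0, nd), 1.0)   # empty conditioning set
  big <- new("NullDistribution", sizes = rep(5L, 1000),
             tStats = rnorm(1000), nPermDone = 10L)
  expect_equal(nullPValue(5, 1e6, big), 1 / 1001)
})

test_that("p-values never increase as |t| grows", {
  set.seed(21)
  nd <- new("NullDistribution", sizes = sample(5:9, 400, replace = TRUE),
            tStats = rt(400, df = 5), nPermDone = 20L)
  for (size in 5:9) {
    p <- vapply(seq(0, 6, by = 0.25), function(t)
      nullPValue(size, t, nd), numeric(1))
    expect_true(all(diff(p) <= 0))
  }
})

test_that("identical gene sets found for both phenotypes collapse to one record", {
  # with alpha=100 every gene is 'top' for everyone, so both phenotypes
  # produce the same candidate list and the same components
  set.seed(8)
  v <- matrix(rnorm(40, 8, 1), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
  es <- makeStudy(v, c("d", "d", "c", "c"))
  db <- PathwayDB(list(p = data.frame(
    gene_a = sprintf("g%02d", 1:4), gene_b = sprintf("g%02d", 2:5),
    relation = "activate")))
  res <- runSNet(es, db, SNetParams(alpha = 100, beta = 10, nPerm = 5,
                                    minSize = 3, seed = 1))
  keys <- vapply(allSubnetworks(res), function(s)
    paste(snPathway(s), paste(snGenes(s), collapse = ";")), "")
  expect_false(any(duplicated(keys)))
  expect_length(allSubnetworks(res), 1L)
})

test_that("the significance cutoff is inclusive", {
  sp <- new("ScoredSubnetwork", name = "n", phenotype = "d", pathway = "p",
            genes = c("A", "B"),
            edges = data.frame(gene_a = "A", gene_b = "B",
                               relation = "activate"),
            perPatientScore = c(s1 = 1, s2 = 1, s3 = 0, s4 = 0),
            scoreVecD = c(1, 1), scoreVecNotD = c(0, 0),
            tStat = 5, pValue = 0.05)
  res <- new("SNetResult", params = SNetParams(nPerm = 1),
             scored = list(sp),
             null = new("NullDistribution", sizes = integer(0),
                        tStats = numeric(0), nPermDone = 1L))
  expect_length(significantSubnetworks(res), 1L)
  expect_true(resultTable(res)$significant)
})

test_that("a full run is deterministic given the seed", {
  sim <- snetPreset("planted-small", seed = 5)
  p <- SNetParams(alpha = 10, beta = 50, nPerm = 30, minSize = 5, seed = 17)
  r1 <- resultTable(runSNet(sim$study, sim$db, p))
  r2 <- resultTable(runSNet(sim$study, sim$db, p))
  expect_identical(r1, r2)
})
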