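test_that("hypergeometric upper tail handles the support boundaries", {
  expect_identical(hypergeomUpperTail(0, 5, 5, 20), 1)
  expect_identical(hypergeomUpperTail(0, 0, 7, 12), 1)
  # minimum feasible overlap: certain event even when k > 0
  expect_identical(hypergeomUpperTail(2, 6, 6, 10), 1)
  # maximum feasible overlap
  expect_equal(hypergeomUpperTail(5, 5, 5, 10), 1 / choose(10, 5))
  expect_error(hypergeomUpperTail(6, 5, 5, 10), "support")
  expect_error(hypergeomUpperTail(1, 6, 6, 10), "support")
  expect_error(hypergeomUpperTail(0, 11, 5, 10), "margins")
})

test_that("N=6 case matches exhaustive enumeration of all C(6,3) draws", {
  expect_equal(hypergeomUpperTail(2, 3, 3, 6), enumHyperOracle(2, 3, 3, 6),
               tolerance = 1e-14)
  # full enumeration agreement for every (k, nA, nB) with N <= 8
  for (N in 2:8) for (nA in 0:N) for (nB in 0:N) {
    for (k in max(0, nA + nB - N):min(nA, nB)) {
      expect_equal(hypergeomUpperTail(k, nA, nB, N),
                   enumHyperOracle(k, nA, nB, N), tolerance = 1e-12)
    }
  }
})

test_that("N=20 case matches direct term-by-term summation", {
  expect_equal(hypergeomUpperTail(3, 5, 5, 20),
               sum(choose(5, 3:5) * choose(15, 5 - (3:5))) / choose(20, 5),
               tolerance = 1e-14)
})

test_that("tail probabilities are monotone in k and in the margins", {
  N <- 40; nB <- 12
  for (nA in c(5, 18, 33)) {
    ks <- max(0, nA + nB - N):min(nA, nB)
    p <- hypergeomUpperTail(ks, nA, nB, N)
    expect_true(all(diff(p) <= 1e-15))
  }
  # non-decreasing in nA at fixed k
  p <- vapply(10:30, function(nA) hypergeomUpperTail(5, nA, 12, N),
              numeric(1))
  expect_true(all(diff(p) >= -1e-15))
})

test_that("extreme overlaps keep a positive log-space probability", {
  p <- hypergeomUpperTail(500, 500, 500, 27416)
  expect_gt(p, 0)
  expect_lt(p, 1e-300)
  # cross-check a representable case against stats::phyper
  expect_equal(hypergeomUpperTail(100, 500, 600, 27416),
               phyper(99, 500, 27416 - 500, 600, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("the depletion flag gives the lower tail", {
  expect_identical(hypergeomUpperTail(5, 5, 5, 10, tail = "lower"), 1)
  expect_equal(hypergeomUpperTail(1, 4, 4, 12, tail = "lower"),
               phyper(1, 4, 8, 4), tolerance = 1e-12)
})

test_that("overlapTest counts, partitions and scores a hand-built pair", {
  u <- tinyUniverse(10)
  a <- signedGeneSet(c("G0001", "G0002", "G0003"), c(1L, 1L, -1L),
                     label = "a")
  b <- signedGeneSet(c("G0002", "G0003", "G0004"), c(1L, 1L, -1L),
                     label = "b")
  r <- overlapTest(a, b, u)
  expect_identical(overlapCount(r), 2L)
  expect_identical(directionPartition(r),
                   c(concordant_up = 1L, concordant_down = 0L,
                     discordant_a_up = 0L, discordant_a_down = 1L))
  expect_equal(overlapPvalue(r), sumHyperOracle(2, 3, 3, 10),
               tolerance = 1e-12)
  # per-class p uses per-direction margins over the same N
  expect_equal(partitionPvalues(r)[["concordant_up"]],
               sumHyperOracle(1, 2, 2, 10), tolerance = 1e-12)
  expect_equal(partitionPvalues(r)[["discordant_a_down"]],
               sumHyperOracle(1, 1, 2, 10), tolerance = 1e-12)
})

test_that("total self-overlap of the universe is forced and uninformative", {
  u <- tinyUniverse(12)
  all <- signedGeneSet(geneIds(u), 1L, label = "everything")
  r <- overlapTest(all, all, u)
  expect_identical(overlapCount(r), 12L)
  expect_identical(overlapPvalue(r), 1)
  expect_error(overlapTest(all, all, geneUniverse(character(0))),
               "non-empty universe")
})

test_that("partition counts sum to k and dropping signs changes nothing", {
  withr::with_seed(42, {
    u <- tinyUniverse(300)
    for (i in 1:25) {
      a <- randomSignedSet(u, sample(20:80, 1), "a")
      b <- randomSignedSet(u, sample(20:80, 1), "b")
      r <- overlapTest(a, b, u)
      expect_identical(sum(directionPartition(r)), overlapCount(r))
      # unsigned comparison via an annotation track with the same members
      bTrack <- annotationTrack("b", geneIds(b), u)
      r2 <- overlapTest(a, bTrack, u)
      expect_identical(overlapCount(r2), overlapCount(r))
      expect_identical(overlapPvalue(r2), overlapPvalue(r))
      expect_length(directionPartition(r2), 0L)
    }
  })
})

test_that("sets with unassigned directions cannot be partitioned", {
  u <- tinyUniverse(5)
  a <- signedGeneSet(c("G0001", "G0002"), c(1L, 0L), label = "raw")
  b <- signedGeneSet("G0001", 1L, label = "b")
  expect_error(overlapTest(a, b, u), "filterDEGs")
})

test_that("percentages report exact, one-decimal and integer styles", {
  u <- tinyUniverse(500)
  a <- signedGeneSet(geneIds(u)[1:150], 1L, label = "a")
  b <- signedGeneSet(geneIds(u)[100:400], 1L, label = "b")
  r <- overlapTest(a, b, u)  # k = 51
  expect_equal(percentOfA(r), 100 * 51 / 150)
  expect_equal(percentOfA(r, "decimal"), 34)
  expect_equal(percentOfB(r, "decimal"), round(100 * 51 / 301, 1))
  expect_equal(percentOfB(r, "integer"), 17)
})

test_that("stratified overlap reduces to overlapTest on the full universe", {
  u <- tinyUniverse(60)
  withr::with_seed(3, a <- randomSignedSet(u, 20, "a"))
  full <- annotationTrack("all", geneIds(u), u)
  res <- stratifiedOverlap(a, list(full), u)
  direct <- overlapTest(a, full, u)
  expect_identical(overlapCount(res$all), overlapCount(direct))
  expect_identical(overlapPvalue(res$all), overlapPvalue(direct))
})

test_that("disjoint strata partitioning a track have additive overlaps", {
  u <- tinyUniverse(100)
  b <- annotationTrack("b", geneIds(u)[1:40], u)
  s1 <- annotationTrack("s1", geneIds(u)[1:15], u)
  s2 <- annotationTrack("s2", geneIds(u)[16:40], u)
  withr::with_seed(9, a <- randomSignedSet(u, 30, "a"))
  res <- stratifiedOverlap(a, list(s1, s2), u)
  expect_identical(overlapCount(res$s1) + overlapCount(res$s2),
                   overlapCount(overlapTest(a, b, u)))
  expect_identical(universeSize(s1), 100L)
})

test_that("enrichment planted in one stratum yields the smaller p there", {
  hits <- 0L
  for (seed in 1:40) {
    cfg <- generatorConfig(
      universeSize = 3000,
      tracks = list(list(label = "s1", size = 400),
                    list(label = "s2", size = 400)),
      degLists = list(list(label = "d", size = 200, theta = 4,
                           track = "s1")),
      seed = seed)
    u <- generateUniverse(cfg)
    tr <- generateTracks(cfg, u)
    d <- generateDegLists(cfg, u, tr)$d
    res <- stratifiedOverlap(d, tr, u)
    if (overlapPvalue(res$s1) < overlapPvalue(res$s2)) hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% of replicates
})

test_that("intersectTracks builds the conjunction stratum", {
  u <- tinyUniverse(30)
  t1 <- annotationTrack("t1", geneIds(u)[1:20], u)
  t2 <- annotationTrack("t2", geneIds(u)[15:25], u)
  both <- intersectTracks(t1, t2)
  expect_setequal(geneIds(both), geneIds(u)[15:20])
  expect_identical(geneSetLabel(both), "t1 AND t2")
})

test_that("Fisher enrichment p equals the hypergeometric mapping exactly", {
  tables <- list(c(2, 1, 1, 2), c(5, 0, 0, 5), c(0, 3, 4, 6),
                 c(7, 2, 3, 11), c(1, 1, 1, 1))
  for (tb in tables) {
    expect_identical(fisherExactUpper(tb[1], tb[2], tb[3], tb[4]),
                     hypergeomUpperTail(tb[1], tb[1] + tb[2],
                                        tb[1] + tb[3], sum(tb)))
  }
  # smallest achievable p for the (5,0,0,5) margins
  expect_equal(fisherExactUpper(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-14)
  # margin-preserving enumeration for (2,1,1,2): overlap of two 3-sets in N=6
  expect_equal(fisherExactUpper(2, 1, 1, 2), enumHyperOracle(2, 3, 3, 6),
               tolerance = 1e-12)
  # independent route: stats::fisher.test one-sided
  expect_equal(fisherExactUpper(7, 2, 3, 11),
               fisher.test(matrix(c(7, 3, 2, 11), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("BY adjustment matches the hand-computed rank formula", {
  expect_identical(benjaminiYekutieli(numeric(0)), numeric(0))
  expect_equal(benjaminiYekutieli(0.02), 0.02)  # m = 1, c(1) = 1
  byEq <- benjaminiYekutieli(rep(0.01, 5))
  expect_true(all(byEq == byEq[1]))  # symmetry: equal inputs, equal outputs
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(benjaminiYekutieli(p), byOracle(p), tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- runif(sample(2:10, 1))
      expect_equal(benjaminiYekutieli(p), byOracle(p), tolerance = 1e-12)
    }
  })
})

test_that("BY is at least as conservative as BH, which is above raw p", {
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- runif(sample(3:30, 1))
      by <- benjaminiYekutieli(p)
      bh <- p.adjust(p, "BH")
      expect_true(all(by >= bh - 1e-15))
      expect_true(all(bh >= p - 1e-15))
      expect_true(all(by <= 1))
    }
  })
})

test_that("overlap results flatten to the report table", {
  u <- tinyUniverse(50)
  a <- signedGeneSet(geneIds(u)[1:10], 1L, label = "a")
  b <- signedGeneSet(geneIds(u)[5:20], -1L, label = "b")
  tab <- as.data.frame(overlapTest(a, b, u))
  expect_identical(tab$k, 6L)
  expect_identical(tab$n_concordant_up, 0L)
  expect_identical(tab$n_discordant_a_up, 6L)
  expect_identical(tab$percent_of_a, 60)
})
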