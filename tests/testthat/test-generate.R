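test_that("generator config validates its knobs", {
  expect_s3_class(generatorConfig(universeSize = 100, tracks = list()),
                  "GeneratorConfig")
  expect_error(generatorConfig(universeSize = 10,
                               tracks = list(list(label = "t", size = 20))),
               "larger than the universe")
  expect_error(generatorConfig(rho = 1.2, tracks = list()))
  expect_error(generatorConfig(universeSize = 100, tracks = list(),
                               degLists = list(list(label = "d", size = 5,
                                                    theta = -1))),
               "theta")
  expect_error(generatorConfig(tracks = list(),
                               phenotype = list(sigma = -1)))
})

test_that("the default configuration reflects the study set sizes", {
  cfg <- generatorConfig()
  expect_identical(cfg$universeSize, 27416L)
  sizes <- vapply(cfg$tracks, `[[`, numeric(1), "size")
  labels <- vapply(cfg$tracks, `[[`, character(1), "label")
  expect_identical(sizes[labels == "high_H2A.Z"], 4081)
  expect_identical(sizes[labels == "H3K9ac"], 1984)
  u <- generateUniverse(cfg)
  expect_identical(length(u), 27416L)
})

test_that("universes are unique, AGI-styled and deterministic", {
  cfg <- generatorConfig(universeSize = 5, tracks = list(), seed = 2)
  u <- generateUniverse(cfg)
  expect_length(geneIds(u), 5L)
  expect_false(anyDuplicated(geneIds(u)) > 0)
  expect_true(all(grepl("^AT[1-5]G\\d{5}$", geneIds(u))))
  expect_identical(geneIds(generateUniverse(cfg)), geneIds(u))
})

test_that("tracks respect sizes, seeds and forced overlaps", {
  cfg <- generatorConfig(
    universeSize = 1000,
    tracks = list(list(label = "empty", size = 0),
                  list(label = "big", size = 300),
                  list(label = "nested", size = 50, overlapWith = "big",
                       overlap = 50)),
    seed = 7)
  u <- generateUniverse(cfg)
  tr <- generateTracks(cfg, u)
  expect_length(tr$empty, 0L)
  expect_length(tr$big, 300L)
  # forced overlap equal to the smaller size implies nesting
  expect_true(all(geneIds(tr$nested) %in% geneIds(tr$big)))
  # determinism
  tr2 <- generateTracks(cfg, u)
  expect_identical(geneIds(tr2$big), geneIds(tr$big))
})

test_that("the H3K9ac / high-H2A.Z fixture overlap is hit exactly", {
  cfg <- generatorConfig(seed = 3)  # defaults: 4081- and 1984-gene tracks
  cfg$tracks[[2]]$overlapWith <- "high_H2A.Z"
  cfg$tracks[[2]]$overlap <- 850
  u <- generateUniverse(cfg)
  tr <- generateTracks(cfg, u)
  expect_identical(
    length(intersect(geneIds(tr$H3K9ac), geneIds(tr$high_H2A.Z))), 850L)
})

test_that("infeasible overlap requests are refused", {
  cfg <- generatorConfig(
    universeSize = 100,
    tracks = list(list(label = "a", size = 30),
                  list(label = "b", size = 90, overlapWith = "a",
                       overlap = 10)),
    seed = 1)
  u <- generateUniverse(cfg)
  expect_error(generateTracks(cfg, u), "infeasible")
  cfg$tracks[[2]] <- list(label = "b", size = 20, overlapWith = "a",
                          overlap = 25)
  expect_error(generateTracks(cfg, u), "infeasible")
})

test_that("DEG lists have exact sizes and theta = Inf nests in the track", {
  cfg <- generatorConfig(
    universeSize = 500,
    tracks = list(list(label = "t", size = 100)),
    degLists = list(list(label = "inTrack", size = 60, theta = Inf,
                         track = "t"),
                    list(label = "plain", size = 80, theta = 1)),
    seed = 5)
  u <- generateUniverse(cfg)
  tr <- generateTracks(cfg, u)
  degs <- generateDegLists(cfg, u, tr)
  expect_length(degs$inTrack, 60L)
  expect_true(all(geneIds(degs$inTrack) %in% geneIds(tr$t)))
  expect_length(degs$plain, 80L)
  # generators are pure functions of (config, seed)
  again <- generateDegLists(cfg, u, tr)
  expect_identical(geneDirections(again$plain), geneDirections(degs$plain))
})

test_that("planted enrichment raises the track overlap over the null", {
  overlaps <- function(theta) {
    vapply(1:30, function(seed) {
      cfg <- generatorConfig(
        universeSize = 3000,
        tracks = list(list(label = "t", size = 600)),
        degLists = list(list(label = "d", size = 150, theta = theta,
                             track = "t")),
        seed = seed)
      u <- generateUniverse(cfg)
      tr <- generateTracks(cfg, u)
      d <- generateDegLists(cfg, u, tr)$d
      length(intersect(geneIds(d), geneIds(tr$t)))
    }, numeric(1))
  }
  expect_gt(median(overlaps(4)), median(overlaps(1)))
})

test_that("detection rate increases monotonically along a theta grid", {
  thetas <- c(1, 2, 4, 8)
  medLogP <- vapply(thetas, function(theta) {
    lp <- vapply(1:15, function(seed) {
      cfg <- generatorConfig(
        universeSize = 5000,
        tracks = list(list(label = "t", size = 1000)),
        degLists = list(list(label = "d", size = 300, theta = theta,
                             track = "t")),
        seed = 100 + seed)
      u <- generateUniverse(cfg)
      tr <- generateTracks(cfg, u)
      d <- generateDegLists(cfg, u, tr)$d
      log10(overlapPvalue(overlapTest(d, tr$t, u)))
    }, numeric(1))
    median(lp)
  }, numeric(1))
  expect_gte(cor(thetas, -medLogP, method = "spearman"), 0.9)
})

test_that("rho controls which direction classes dominate the partition", {
  classBalance <- function(rho) {
    cfg <- generatorConfig(
      universeSize = 2000, tracks = list(),
      degLists = list(list(label = "d1", size = 700),
                      list(label = "d2", size = 700)),
      rho = rho, seed = 17)
    u <- generateUniverse(cfg)
    degs <- generateDegLists(cfg, u, list())
    part <- directionPartition(overlapTest(degs$d1, degs$d2, u))
    conc <- part[["concordant_up"]] + part[["concordant_down"]]
    disc <- part[["discordant_a_up"]] + part[["discordant_a_down"]]
    c(conc = conc, disc = disc)
  }
  high <- classBalance(0.9)
  expect_gt(high[["conc"]], high[["disc"]])
  low <- classBalance(0.1)
  expect_lt(low[["conc"]], low[["disc"]])
})

test_that("noiseless phenotypes obey the closed-form interaction SS", {
  cfg0 <- generatorConfig(tracks = list(),
                          phenotype = list(sigma = 0, betaInt = 0, n = 6),
                          seed = 9)
  res0 <- twoWayAnovaInteraction(generatePhenotypes(cfg0))
  expect_equal(res0@ss[["interaction"]], 0, tolerance = 1e-20)

  cfg2 <- generatorConfig(tracks = list(),
                          phenotype = list(sigma = 0, betaInt = 2, n = 6),
                          seed = 9)
  res2 <- twoWayAnovaInteraction(generatePhenotypes(cfg2))
  expect_equal(res2@ss[["interaction"]], 6 * 2^2 / 4, tolerance = 1e-10)
})

test_that("phenotype generation is balanced and reproducible", {
  cfg <- generatorConfig(tracks = list(),
                         phenotype = list(n = 15, sigma = 0.5), seed = 23)
  df <- generatePhenotypes(cfg)
  expect_identical(nrow(df), 60L)
  expect_true(all(table(df$factor_a, df$factor_b) == 15L))
  expect_identical(generatePhenotypes(cfg)$value, df$value)
})

test_that("writeSyntheticInputs emits consumable files plus a manifest", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(
    universeSize = 300,
    tracks = list(list(label = "t", size = 50)),
    degLists = list(list(label = "d", size = 40, theta = 2, track = "t")),
    seed = 8)
  paths <- writeSyntheticInputs(cfg, dir)
  u <- geneUniverse(readLines(paths$universe))
  expect_identical(length(u), 300L)
  tracks <- readGeneList(paths$tracks, format = "gmt")
  expect_length(geneIds(tracks$t), 50L)
  d <- readGeneList(paths[["deg_d"]], format = "tsv")
  expect_length(d, 40L)
  expect_true(all(geneIds(d) %in% geneIds(u)))
  manifest <- yaml::read_yaml(paths$manifest)
  expect_identical(manifest$seed, 8L)
  pheno <- readPhenotypeTable(paths$phenotypes)
  expect_s3_class(pheno, "data.frame")
})
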