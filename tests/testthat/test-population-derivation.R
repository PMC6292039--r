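test_that("hybrid genotype deduction follows the marker-wise rules", {
  map <- GeneticMap(chrom = rep("C01", 4), marker = paste0("m", 1:4),
                    pos = c(0, 10, 20, 30))
  calls <- rbind(r1 = c(0L, 0L, 2L, 1L),
                 r2 = c(0L, 2L, 2L, 0L))
  colnames(calls) <- paste0("m", 1:4)
  rils <- GenotypeMatrix(calls, "RIL", map)
  design <- CrossDesign(
    if2Pairs = data.frame(hybrid = "h1", female = "r1", male = "r2",
                          stringsAsFactors = FALSE),
    backcrosses = data.frame(hybrid = c("b1", "b2", "c1", "c2"),
                             ril = c("r1", "r2", "r1", "r2"),
                             recurrent = c("P1", "P1", "P2", "P2"),
                             stringsAsFactors = FALSE))
  if2 <- genotypeCalls(deduceHybridGenotypes(rils, design, "IF2"))
  expect_identical(unname(if2["h1", ]), c(0L, 1L, 2L, NA))
  hs <- genotypeCalls(deduceHybridGenotypes(rils, design, "HSBCF1"))
  expect_identical(unname(hs["b1", ]), c(0L, 0L, 1L, NA))  # AA->AA, BB->AB
  expect_identical(unname(hs["b2", ]), c(0L, 1L, 1L, 0L))
  mar <- genotypeCalls(deduceHybridGenotypes(rils, design, "MARBCF1"))
  expect_identical(unname(mar["c1", ]), c(1L, 1L, 2L, NA)) # AA->AB, BB->BB
  expect_error(
    deduceHybridGenotypes(rils, CrossDesign(
      if2Pairs = data.frame(hybrid = "h", female = "r1", male = "zz")),
      "IF2"),
    "unknown RIL id")
})

test_that("backcross hybrids carry exactly two genotype classes", {
  rils <- toyRils(n = 60, seed = 4)
  bc <- makeBackcrossDesign(rils)
  hs <- genotypeCalls(deduceHybridGenotypes(rils, bc, "HSBCF1"))
  expect_true(all(hs %in% c(0L, 1L) | is.na(hs)))
  mar <- genotypeCalls(deduceHybridGenotypes(rils, bc, "MARBCF1"))
  expect_true(all(mar %in% c(1L, 2L) | is.na(mar)))
})

test_that("IF2 design is two derangement rounds covering every RIL", {
  ids <- sprintf("R%03d", 1:188)
  d <- if2Pairs(makeIf2Design(ids, seed = 6))
  expect_equal(nrow(d), 376)
  expect_true(all(d$female != d$male))
  for (r in 1:2) {
    round <- d[((r - 1) * 188 + 1):(r * 188), ]
    expect_setequal(round$female, ids)
    expect_setequal(round$male, ids)
  }
})

test_that("IF2 heterozygosity at a marker is near one half", {
  rils <- toyRils(n = 400, seed = 8)
  if2 <- deduceHybridGenotypes(rils, makeIf2Design(rils, seed = 9), "IF2")
  calls <- genotypeCalls(if2)[, 1]
  het <- mean(calls == 1L, na.rm = TRUE)
  se <- sqrt(0.25 / sum(!is.na(calls)))
  expect_lt(abs(het - 0.5), 3 * se + 0.01)
})

test_that("HB reproduces the printed worked example and propagates NA", {
  rilPh <- phenoFromValues("r1", 536.19)
  p1 <- phenoFromValues("P1", 653.07)
  p2 <- phenoFromValues("P2", 500.98)
  hb <- computeHB(rilPh, p1, p2)
  d <- phenoData(hb)
  expect_equal(d$value, -40.835)
  expect_equal(d$percent, -7.077, tolerance = 1e-4)
  ## RIL equal to MP gives 0; parent missing in an environment gives NA
  hb0 <- computeHB(phenoFromValues("r1", 577.025), p1, p2)
  expect_equal(phenoData(hb0)$value, 0)
  ril2 <- PhenotypeTable(data.frame(individual = "r1", trait = "SY",
                                    environment = c("E1", "E2"),
                                    replicate = 1L, value = c(10, 20)))
  hb2 <- computeHB(ril2, p1, p2)   # parents typed in E1 only
  d2 <- phenoData(hb2)
  expect_true(is.na(d2$value[d2$environment == "E2"]))
})

test_that("MPH arithmetic and the noiseless dominance expectation hold", {
  design <- CrossDesign(if2Pairs = data.frame(hybrid = "h1", female = "r1",
                                              male = "r2",
                                              stringsAsFactors = FALSE))
  hyb <- phenoFromValues("h1", 10)
  rils <- PhenotypeTable(data.frame(individual = c("r1", "r2"),
                                    trait = "SY", environment = "E1",
                                    replicate = 1L, value = c(8, 6)))
  mph <- computeMPH(hyb, design, "IF2", rils)
  expect_equal(phenoData(mph)$value, 3)
  mph0 <- computeMPH(phenoFromValues("h1", 7), design, "IF2", rils)
  expect_equal(phenoData(mph0)$value, 0)

  ## simulated single-locus d = 2, no noise: population-mean IF2 MPH
  ## equals 2 x expected heterozygosity at the locus
  map <- toyMap()
  cfg <- simConfig(nRil = 150, seed = 23)
  g <- toyRils(n = 150, seed = 23, map = map)
  dsn <- makeIf2Design(g, seed = 24)
  if2 <- deduceHybridGenotypes(g, dsn, "IF2")
  arch <- oneLocusArch(chrom = "C01", pos = 40, a = 0, d = 2, sigmaE = 0)
  phR <- simulatePhenotypes(g, arch, cfg)
  phH <- simulatePhenotypes(if2, arch, cfg, seed = 99)
  mphTab <- suppressWarnings(computeMPH(phH, dsn, "IF2", phR))
  hetExp <- mean(hetqtl:::.probEngine(
    if2, data.frame(chrom = "C01", pos = 40))$pAB[, 1])
  md <- phenoData(mphTab)
  expect_equal(mean(md$value[md$environment == "E1"]), 2 * hetExp,
               tolerance = 1e-8)
})

test_that("pure additive loci give IF2 hybrids zero expected MPH", {
  map <- toyMap()
  cfg <- simConfig(nRil = 200, seed = 33)
  g <- toyRils(n = 200, seed = 33, map = map)
  dsn <- makeIf2Design(g, seed = 34)
  if2 <- deduceHybridGenotypes(g, dsn, "IF2")
  arch <- oneLocusArch(chrom = "C02", pos = 30, a = 1.4, d = 0, sigmaE = 0)
  phR <- simulatePhenotypes(g, arch, cfg)
  phH <- simulatePhenotypes(if2, arch, cfg, seed = 3)
  md <- phenoData(suppressWarnings(computeMPH(phH, dsn, "IF2", phR)))
  expect_lt(abs(mean(md$value[md$environment == "E1"])), 0.02)
})

test_that("heterosis summaries cover the degenerate cases", {
  pt <- PhenotypeTable(data.frame(individual = c("h1", "h2"),
                                  trait = "SY", environment = "E1",
                                  replicate = 1L, value = c(1, 2),
                                  percent = c(-1, 3)), kind = "MPH")
  s <- summarizeHeterosis(pt)
  expect_equal(c(s$mean, s$min, s$max), c(1, -1, 3))
  ptc <- PhenotypeTable(data.frame(individual = paste0("h", 1:5),
                                   trait = "SY", environment = "E1",
                                   replicate = 1L, value = 0,
                                   percent = 5), kind = "MPH")
  sc <- summarizeHeterosis(ptc)
  expect_equal(c(sc$mean, sc$min, sc$max, sc$topMean), rep(5, 4))
  ## top-k equal to n reduces to the plain mean
  sk <- summarizeHeterosis(pt, topK = 2)
  expect_equal(sk$topMean, sk$mean)
})
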