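test_that("m-QTL scan refuses a single environment", {
  g <- toyRils(n = 40, seed = 3)
  pr <- genotypeProbabilities(g, step = 10)
  ph <- phenoFromValues(individuals(g), rnorm(40))
  expect_error(mqtlScan(ph, pr, "SY", nPerm = 0), ">= 2 environments")
})

test_that("QE variance partition separates main and interaction effects", {
  map <- toyMap()
  cfg2 <- simConfig(nRil = 150, environments = 2, seed = 101)
  g <- simulateRilGenotypes(map, cfg2)
  pr <- genotypeProbabilities(g, step = 5)
  em <- matrix(0, 1, 2, dimnames = list("SY", c("E1", "E2")))
  ## constant additive effect, no QE, no noise: PV(AE) = 0 at the locus
  archA <- qtlArchitecture(loci = data.frame(trait = "SY", chrom = "C01",
                                             pos = 40, a = 1, d = 0),
                           envMeans = em, sigmaE = 0)
  phA <- simulatePhenotypes(g, archA, cfg2)
  mA <- mqtlScan(phA, pr, "SY", nPerm = 30, seed = 1)
  at <- which(mA$profile$chrom == "C01" & mA$profile$pos == 40)
  expect_lt(mA$profile$pvAE[at], 1e-8)
  expect_gt(mA$profile$pvA[at], 50)
  ## pure crossover QE (+1/-1): PV(A) ~ 0, PV(AE) > 0
  archX <- qtlArchitecture(loci = data.frame(trait = "SY", chrom = "C01",
                                             pos = 40, a = 0, d = 0),
                           qe = matrix(c(1, -1), 1), envMeans = em,
                           sigmaE = 0)
  phX <- simulatePhenotypes(g, archX, cfg2)
  mX <- mqtlScan(phX, pr, "SY", nPerm = 30, seed = 2)
  expect_lt(mX$profile$pvA[at], 0.5)
  expect_gt(mX$profile$pvAE[at], 50)
})

test_that("sequential SS decomposition is exact on balanced data", {
  map <- toyMap()
  cfg <- simConfig(nRil = 60, seed = 111)
  g <- simulateRilGenotypes(map, cfg)
  pr <- genotypeProbabilities(g, step = 10)
  arch <- oneLocusArch(chrom = "C02", pos = 40, a = 0.8, d = 0,
                       sigmaE = 1)
  ph <- simulatePhenotypes(g, arch, cfg)
  em <- hetqtl:::.envMatrix(ph, pr, "SY")
  y <- as.vector(em$y)
  n <- nrow(em$y); E <- ncol(em$y); N <- n * E
  ED <- kronecker(diag(E), rep(1, n))
  C <- kronecker(stats::contr.sum(E), rep(1, n))
  at <- which(pr@grid$chrom == "C02" & pr@grid$pos == 40)
  u <- rep((pr@pAA - pr@pBB)[, at], E)
  tss <- sum((y - mean(y))^2)
  r0g <- sum(lm.fit(matrix(1, N, 1), y)$residuals^2) # grand-mean model
  r0 <- sum(lm.fit(ED, y)$residuals^2)
  r1 <- sum(lm.fit(cbind(ED, u), y)$residuals^2)
  r2 <- sum(lm.fit(cbind(ED, u, u * C), y)$residuals^2)
  pvEnv <- 100 * (r0g - r0) / tss
  pvA <- 100 * (r0 - r1) / tss
  pvAE <- 100 * (r1 - r2) / tss
  resid <- 100 * r2 / tss
  expect_equal(pvEnv + pvA + pvAE + resid, 100, tolerance = 1e-8)
  ## and the scan reports the same pvA/pvAE at that position
  m <- mqtlScan(ph, pr, "SY", nPerm = 30, seed = 3, maxCofactors = 0)
  expect_equal(m$profile$pvA[at], pvA, tolerance = 1e-8)
  expect_equal(m$profile$pvAE[at], pvAE, tolerance = 1e-8)
})

test_that("e-QTL engine equals a brute-force two-marker regression oracle", {
  map <- toyMap()                       # 3 chromosomes x 10 markers
  cfg2 <- simConfig(nRil = 80, environments = 2, seed = 121)
  g <- simulateRilGenotypes(map, cfg2)
  pr <- genotypeProbabilities(g, step = 10)
  em <- matrix(0, 1, 2, dimnames = list("SY", c("E1", "E2")))
  arch <- qtlArchitecture(
    loci = data.frame(trait = "SY", chrom = "C01", pos = 40, a = 0.5,
                      d = 0),
    epistasis = data.frame(trait = "SY", chrom1 = "C01", pos1 = 40,
                           chrom2 = "C03", pos2 = 50, aa = 1, ad = 0,
                           da = 0, dd = 0),
    envMeans = em, sigmaE = 0.6)
  ph <- simulatePhenotypes(g, arch, cfg2)
  sc <- eqtlScan(ph, pr, "SY", step = 10, nPerm = 0, maxCofactors = 0)
  emat <- hetqtl:::.envMatrix(ph, pr, "SY")
  y <- as.vector(emat$y)
  n <- nrow(emat$y); E <- 2; N <- n * E
  env <- factor(rep(1:2, each = n))
  X <- pr@pAA - pr@pBB
  set.seed(14)
  for (k in sample(nrow(sc$pairs), 12)) {
    p <- sc$pairs[k, ]
    i <- which(pr@grid$chrom == p$chrom1 & pr@grid$pos == p$pos1)
    j <- which(pr@grid$chrom == p$chrom2 & pr@grid$pos == p$pos2)
    u1 <- rep(X[, i], E); u2 <- rep(X[, j], E)
    f0 <- lm(y ~ env + u1 + u2 + u1:env + u2:env)
    f2 <- lm(y ~ env + u1 + u2 + u1:env + u2:env + u1:u2 + u1:u2:env)
    lodOracle <- (N / 2) *
      log10(sum(f0$residuals^2) / sum(f2$residuals^2))
    expect_equal(p$lod, lodOracle, tolerance = 1e-8)
  }
  ## the true interacting pair carries the maximal LOD
  best <- sc$pairs[which.max(sc$pairs$lod), ]
  expect_identical(c(best$chrom1, best$chrom2), c("C01", "C03"))
  expect_lt(abs(best$pos1 - 40), 10 + 1e-9)
  expect_lt(abs(best$pos2 - 50), 10 + 1e-9)
})

test_that("within-chromosome pairs closer than minDist are excluded", {
  g <- toyRils(n = 40, seed = 5)
  pr <- genotypeProbabilities(g, step = 10)
  cfg2 <- simConfig(nRil = 40, environments = 2, seed = 5)
  arch <- qtlArchitecture(loci = data.frame(),
                          envMeans = matrix(0, 1, 2,
                                            dimnames = list("SY",
                                                            c("E1", "E2"))),
                          sigmaE = 1)
  ph <- simulatePhenotypes(g, arch, cfg2)
  sc <- eqtlScan(ph, pr, "SY", step = 10, minDist = 20, nPerm = 0)
  same <- sc$pairs$chrom1 == sc$pairs$chrom2
  expect_true(all(abs(sc$pairs$pos1 - sc$pairs$pos2)[same] > 20))
})

test_that("epistasis typing counts coincident m-QTL loci", {
  eq <- data.frame(name = "RmeqSY-1", dataset = "RIL", trait = "SY",
                   chrom1 = "C01", pos1 = 40, chrom2 = "C02", pos2 = 60,
                   lod = 6, pvAA = 10, pvAAE = 5,
                   stringsAsFactors = FALSE)
  mq <- function(chrom, pos)
    data.frame(name = "m", dataset = "RIL", trait = "SY", chrom = chrom,
               pos = pos, lod = 5, pvTotal = 5, pvA = 4, pvAE = 1,
               stringsAsFactors = FALSE)
  both <- rbind(mq("C01", 42), mq("C02", 58))
  expect_identical(classifyEpistasisType(eq, both)$type, "I")
  one <- mq("C01", 44)
  expect_identical(classifyEpistasisType(eq, one)$type, "II")
  none <- mq("C03", 40)
  expect_identical(classifyEpistasisType(eq, none)$type, "III")
  ## beyond the radius does not count
  far <- mq("C01", 47)
  expect_identical(classifyEpistasisType(eq, far, radius = 5)$type, "III")
})

test_that("congruence is containment of m-QTL peaks in support intervals", {
  single <- data.frame(name = c("qSY-C01-1", "qSY-C02-1"), trait = "SY",
                       chrom = c("C01", "C02"), lo = c(38, 10),
                       hi = c(47, 20), stringsAsFactors = FALSE)
  mq <- data.frame(name = c("RmaqSY-C01-1", "ImaqSY-C01-1",
                            "RmaqSY-C03-1"),
                   dataset = c("RIL", "IF2", "RIL"), trait = "SY",
                   chrom = c("C01", "C01", "C03"), pos = c(42, 44, 15),
                   stringsAsFactors = FALSE)
  cg <- congruence(single, mq)
  expect_true(cg$overlap[1])
  expect_equal(cg$nMqtls[1], 2)        # one interval, two m-QTLs
  expect_identical(cg$mqtls[1], "RmaqSY-C01-1,ImaqSY-C01-1")
  expect_false(cg$overlap[2])          # different chromosome/position
})

test_that("PV totals add over records and handle emptiness", {
  one <- data.frame(name = "ImeqSY-1", dataset = "IF2", trait = "SY",
                    chrom1 = "C01", pos1 = 0, chrom2 = "C02", pos2 = 0,
                    lod = 5, pvAA = 10, pvAAE = 5,
                    stringsAsFactors = FALSE)
  s <- summarizePv(one)
  expect_equal(c(s$sum, s$pvAA, s$pvAAE, s$pv), c(1, 10, 5, 15))
  empty <- one[0, ]
  expect_equal(nrow(summarizePv(empty)), 0)
  ## two orthogonal-locus records: totals are additive
  two <- rbind(one, transform(one, name = "ImeqSY-2", pvAA = 8,
                              pvAAE = 2))
  s2 <- summarizePv(two)
  expect_equal(s2$pvAA, 18)
  expect_equal(s2$sum, 2)
})

test_that("locus order within an e-QTL pair is canonical", {
  map <- toyMap()
  cfg2 <- simConfig(nRil = 100, environments = 2, seed = 131)
  g <- simulateRilGenotypes(map, cfg2)
  pr <- genotypeProbabilities(g, step = 10)
  arch <- qtlArchitecture(
    loci = data.frame(),
    epistasis = data.frame(trait = "SY", chrom1 = "C03", pos1 = 40,
                           chrom2 = "C01", pos2 = 20, aa = 1.5, ad = 0,
                           da = 0, dd = 0),
    envMeans = matrix(0, 1, 2, dimnames = list("SY", c("E1", "E2"))),
    sigmaE = 0.5)
  ph <- simulatePhenotypes(g, arch, cfg2)
  sc <- eqtlScan(ph, pr, "SY", step = 10, nPerm = 30, seed = 7)
  if (nrow(sc$records)) {
    expect_true(all(match(sc$records$chrom1, c("C01", "C02", "C03")) <=
                      match(sc$records$chrom2, c("C01", "C02", "C03"))))
  }
  expect_gt(nrow(sc$records), 0)
})
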