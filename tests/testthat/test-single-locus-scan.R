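test_that("genotype probabilities collapse, symmetrize and match theory", {
  map <- GeneticMap(chrom = rep("C01", 2), marker = c("m1", "m2"),
                    pos = c(0, 20))
  calls <- rbind(conc = c(0L, 0L), disc = c(0L, 2L), half = c(0L, NA))
  colnames(calls) <- c("m1", "m2")
  g <- GenotypeMatrix(calls, "RIL", map)
  pr <- genotypeProbabilities(g, step = 10)
  mid <- which(pr@grid$pos == 10)
  at0 <- which(pr@grid$pos == 0)
  ## indicator at a typed marker
  expect_equal(pr@pAA[, at0], c(conc = 1, disc = 1, half = 1))
  ## discordant flanks at the midpoint: exactly 1/2 by symmetry
  expect_equal(unname(pr@pAA["disc", mid]), 0.5)
  ## concordant flanks: two-point conditional probability
  r <- haldaneRecomb(10)
  expect_equal(unname(pr@pAA["conc", mid]),
               (1 - r)^2 / ((1 - r)^2 + r^2), tolerance = 1e-12)
  ## single informative flank: 1 - r
  expect_equal(unname(pr@pAA["half", mid]), 1 - r, tolerance = 1e-12)
  ## class probabilities always sum to one
  expect_equal(pr@pAA + pr@pAB + pr@pBB,
               matrix(1, 3, ncol(pr@pAA)), ignore_attr = TRUE)
  expect_error(genotypeProbabilities(g, step = 0), "positive")
})

test_that("RIL conditional probabilities agree with chain enumeration", {
  ## brute-force oracle: enumerate the two-state chain over three points
  map <- GeneticMap(chrom = rep("C01", 2), marker = c("m1", "m2"),
                    pos = c(0, 30))
  calls <- rbind(i1 = c(0L, 2L))
  colnames(calls) <- c("m1", "m2")
  g <- GenotypeMatrix(calls, "RIL", map)
  pr <- genotypeProbabilities(g, step = 5)
  for (p in c(5, 10, 25)) {
    rL <- haldaneRecomb(p); rR <- haldaneRecomb(30 - p)
    states <- expand.grid(s = 0:1)
    joint <- vapply(states$s, function(s) {
      tL <- if (s == 0) 1 - rL else rL       # from A at m1
      tR <- if (s == 0) rR else 1 - rR       # to B at m2
      tL * tR
    }, 0)
    oracle <- joint[1] / sum(joint)
    expect_equal(unname(pr@pAA[1, pr@grid$pos == p]), oracle,
                 tolerance = 1e-12)
  }
})

test_that("IF2 probabilities match two-chain enumeration at a midpoint", {
  map <- GeneticMap(chrom = rep("C01", 2), marker = c("m1", "m2"),
                    pos = c(0, 20))
  calls <- rbind(hh = c(1L, 1L), ha = c(1L, 0L))
  colnames(calls) <- c("m1", "m2")
  g <- GenotypeMatrix(calls, "IF2", map)
  pr <- genotypeProbabilities(g, step = 10)
  mid <- which(pr@grid$pos == 10)
  r <- haldaneRecomb(10)
  ## oracle: enumerate ordered chain states at both flanks and midpoint
  tr <- function(s1, s2, rr) if (s1 == s2) 1 - rr else rr
  enum <- function(leftStates, rightStates) {
    pg <- c(AA = 0, AB = 0, BB = 0)
    for (L in leftStates) for (R in rightStates)
      for (s1 in 0:1) for (s2 in 0:1) {
        w <- tr(L[1], s1, r) * tr(s1, R[1], r) *
          tr(L[2], s2, r) * tr(s2, R[2], r)
        gcl <- c("AA", "AB", "BB")[s1 + s2 + 1]
        pg[gcl] <- pg[gcl] + w / (length(leftStates) * length(rightStates))
      }
    pg / sum(pg)
  }
  hetL <- list(c(0, 1), c(1, 0))
  oHH <- enum(hetL, hetL)
  expect_equal(unname(pr@pAB["hh", mid]), unname(oHH["AB"]),
               tolerance = 1e-12)
  expect_equal(unname(pr@pAA["hh", mid]), unname(oHH["AA"]),
               tolerance = 1e-12)
  oHA <- enum(hetL, list(c(0, 0)))
  expect_equal(unname(pr@pAA["ha", mid]), unname(oHA["AA"]),
               tolerance = 1e-12)
  expect_equal(unname(pr@pAB["ha", mid]), unname(oHA["AB"]),
               tolerance = 1e-12)
})

test_that("with one marker and no cofactors the scan is single-marker ANOVA", {
  set.seed(61)
  map <- GeneticMap(chrom = "C01", marker = c("m1", "m2"), pos = c(0, 40))
  calls <- cbind(m1 = sample(c(0L, 2L), 20, TRUE),
                 m2 = sample(c(0L, 2L), 20, TRUE))
  rownames(calls) <- sprintf("i%02d", 1:20)
  g <- GenotypeMatrix(calls, "RIL", map)
  pr <- genotypeProbabilities(g, step = 40)
  y <- rnorm(20) + 0.8 * (1 - calls[, 1])
  ph <- phenoFromValues(rownames(calls), y)
  prof <- cimScan(ph, pr, "SY", cofactors = character(0))
  gd <- scanGrid(prof)
  for (k in 1:2) {
    x <- 1 - calls[, k]
    lodOracle <- as.numeric(logLik(lm(y ~ x)) - logLik(lm(y ~ 1))) / log(10)
    expect_equal(gd$lod[gd$pos == c(0, 40)[k]], lodOracle,
                 tolerance = 1e-8)
    expect_equal(gd$a[gd$pos == c(0, 40)[k]],
                 unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
  }
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  g <- toyRils(n = 80, seed = 41)
  pr <- genotypeProbabilities(g, step = 3)
  set.seed(42)
  y <- rnorm(80) + 0.5 * (pr@pAA[, 30] - pr@pBB[, 30])
  ids <- individuals(g)
  p1 <- cimScan(phenoFromValues(ids, y), pr, "SY")
  p2 <- cimScan(phenoFromValues(ids, 3.7 * y - 11), pr, "SY")
  expect_equal(scanGrid(p1)$lod, scanGrid(p2)$lod, tolerance = 1e-8)
})

test_that("a perfect fit is capped with the exact effect recovered", {
  g <- toyRils(n = 50, seed = 51)
  pr <- genotypeProbabilities(g, step = 5)
  x <- 1 - genotypeCalls(g)[, "C01M003"]   # marker at 20 cM
  ph <- phenoFromValues(individuals(g), 2 * x)
  prof <- cimScan(ph, pr, "SY", cofactors = character(0))
  gd <- scanGrid(prof)
  at <- which(gd$chrom == "C01" & gd$pos == 20)
  expect_equal(gd$lod[at], 50)
  expect_equal(gd$a[at], 2, tolerance = 1e-8)
})

test_that("noiseless IF2 effect estimates equal the architecture exactly", {
  rils <- toyRils(n = 100, seed = 71)
  if2 <- deduceHybridGenotypes(rils, makeIf2Design(rils, seed = 72), "IF2")
  cfg <- simConfig(nRil = 100, seed = 71)
  arch <- oneLocusArch(chrom = "C02", pos = 30, a = 1, d = 0.5, sigmaE = 0)
  ph <- simulatePhenotypes(if2, arch, cfg)
  pr <- genotypeProbabilities(if2, step = 5)
  prof <- cimScan(ph, pr, "SY", environment = "E1",
                  cofactors = character(0))
  gd <- scanGrid(prof)
  at <- which(gd$chrom == "C02" & gd$pos == 30)
  expect_equal(gd$a[at], 1, tolerance = 1e-8)
  expect_equal(gd$d[at], 0.5, tolerance = 1e-8)
})

test_that("permutation thresholds handle degenerate inputs and refuse tiny runs", {
  g <- toyRils(n = 40, seed = 81)
  pr <- genotypeProbabilities(g, step = 10)
  ids <- individuals(g)
  constant <- phenoFromValues(ids, rep(3, 40))
  thr <- permutationThreshold(constant, pr, "SY", nPerm = 25, seed = 1)
  expect_equal(thr, 0)
  thrA1 <- permutationThreshold(constant, pr, "SY", nPerm = 25,
                                alpha = 1, seed = 1)
  expect_equal(thrA1, 0)
  expect_error(permutationThreshold(constant, pr, "SY", nPerm = 10),
               "refused")
})

test_that("QTL calling names, numbers and merges loci as specified", {
  expect_identical(formatQtlName("single", trait = "BN", chrom = "C01",
                                 number = 2), "qBN-C01-2")
  mk <- function(env, peak, lo, hi, lod, ds = "IF2")
    data.frame(name = "tmp", dataset = ds, trait = "BN",
               environment = env, chrom = "C01", peak = peak, lo = lo,
               hi = hi, lod = lod, pve = 10, a = 1, d = 0.2,
               composite = NA_real_, favorable = "P1",
               stringsAsFactors = FALSE)
  two <- rbind(mk("E1", 40, 35, 45, 5), mk("E2", 43, 38, 50, 6))
  m <- mergeQtls(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$stability, 2)
  expect_true(m$stable)
  expect_equal(m$peak, 43)
  expect_equal(c(m$lo, m$hi), c(35, 50))
  ## disjoint intervals stay apart and are numbered by position
  apart <- rbind(mk("E1", 10, 5, 15, 5), mk("E1", 60, 55, 70, 7))
  m2 <- mergeQtls(apart)
  expect_equal(m2$name, c("qBN-C01-1", "qBN-C01-2"))
  ## a profile entirely below threshold yields no QTLs
  prof <- new("ScanProfile", dataset = "RIL", trait = "BN",
              environment = "E1",
              grid = data.frame(chrom = "C01", pos = 0:10, lod = 0.2,
                                a = 1, d = NA_real_,
                                composite = NA_real_, pve = 1),
              cofactors = character(0), threshold = 3, nPerm = 100L,
              step = 1)
  expect_equal(nrow(callQtls(prof)), 0)
})
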