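test_that("effect estimation reproduces the class-mean formulas", {
  e <- estimateEffects(if2Means = c(AA = 4, AB = 7, BB = 2))
  expect_equal(c(e$a, e$d), c(1, 4))
  expect_equal(e$ratio, 4)
  expect_equal(estimateEffects(rilMeans = c(AA = 6, BB = 2))$a, 2)
  e2 <- estimateEffects(rilMeans = c(AA = 6, BB = 2),
                        mphMeans = c(het = 1.2, hom = 0.2))
  expect_equal(c(e2$a, e2$d), c(2, 1))
  expect_identical(c(e2$aSource, e2$dSource), c("RIL", "MPH"))
  ## IF2 estimates take precedence when both are available
  e3 <- estimateEffects(if2Means = c(AA = 4, AB = 7, BB = 2),
                        rilMeans = c(AA = 9, BB = 1))
  expect_identical(e3$aSource, "IF2")
  expect_equal(e3$a, 1)
  expect_equal(estimateEffects(bcMeans = c(het = 5, hom = 3))$composite, 2)
})

test_that("noiseless simulated IF2 recovers architecture effects exactly", {
  rils <- toyRils(n = 90, seed = 91)
  if2 <- deduceHybridGenotypes(rils, makeIf2Design(rils, seed = 92), "IF2")
  cfg <- simConfig(nRil = 90, seed = 91)
  arch <- oneLocusArch(chrom = "C03", pos = 50, a = 1, d = 0.5, sigmaE = 0)
  ph <- simulatePhenotypes(if2, arch, cfg)
  d <- phenoData(ph)
  v <- d$value[d$environment == "E1" & d$replicate == 1]
  names(v) <- d$individual[d$environment == "E1" & d$replicate == 1]
  calls <- genotypeCalls(if2)[, "C03M006"]    # marker at 50 cM
  ok <- !is.na(calls)
  means <- tapply(v[individuals(if2)][ok], calls[ok], mean)
  e <- estimateEffects(if2Means = c(AA = means[["0"]], AB = means[["1"]],
                                    BB = means[["2"]]))
  expect_equal(c(e$a, e$d), c(1, 0.5), tolerance = 1e-10)
})

test_that("IF2 classification follows the dominance-degree rules", {
  det <- c(ril = FALSE, if2 = TRUE, mph = FALSE)
  est <- function(a, d, env = "E1") data.frame(environment = env, a = a,
                                               d = d)
  expect_identical(classifyIf2(est(0.4, 0.3), det)$class, "PD/D")
  expect_identical(classifyIf2(est(0.4, 0.8), det)$class, "OD")
  ## boundary |d/a| = 1 is PD/D
  expect_identical(classifyIf2(est(0.5, 0.5), det)$class, "PD/D")
  ## a = 0 with d != 0 counts as infinite dominance degree
  expect_identical(classifyIf2(est(0, 0.3), det)$class, "OD")
  ## MPH-only detection is over-dominant by rule
  mo <- classifyIf2(est(NA, 0.5), c(ril = FALSE, if2 = FALSE, mph = TRUE))
  expect_identical(c(mo$class, mo$ruleCase), c("OD", "IF2-MPH-only"))
  ## environments on both sides of the boundary: uncertain
  un <- classifyIf2(est(c(1, 1), c(0.7, 1.8), env = c("E1", "E2")), det)
  expect_identical(c(un$class, un$ruleCase),
                   c("uncertain", "inconsistent-env"))
  ## consistent environments stay classified
  cons <- classifyIf2(est(c(1, 1), c(0.7, 0.9), env = c("E1", "E2")), det)
  expect_identical(cons$class, "PD/D")
})

test_that("backcross classification covers all three OD cases and additive", {
  est <- function(a = NA, d = NA, comp = NA, env = "E1")
    data.frame(environment = env, a = a, d = d, composite = comp)
  ## case 1: 2|d|(MPH) > |a+d|(BCF1)
  c1 <- classifyBcf1(est(d = 0.8, comp = 1.3),
                     c(ril = FALSE, bc = TRUE, mph = TRUE))
  expect_identical(c(c1$class, c1$ruleCase), c("OD", "BC-case1"))
  c1b <- classifyBcf1(est(d = 0.5, comp = 1.3),
                      c(ril = FALSE, bc = TRUE, mph = TRUE))
  expect_identical(c1b$class, "PD/D")
  ## case 2: RIL + MPH with |d/a| > 1
  c2 <- classifyBcf1(est(a = 0.4, d = 0.9),
                     c(ril = TRUE, bc = FALSE, mph = TRUE))
  expect_identical(c(c2$class, c2$ruleCase), c("OD", "BC-case2"))
  c2b <- classifyBcf1(est(a = 1.0, d = 0.6),
                      c(ril = TRUE, bc = FALSE, mph = TRUE))
  expect_identical(c2b$class, "PD/D")
  ## case 3: MPH only
  c3 <- classifyBcf1(est(d = 0.5), c(ril = FALSE, bc = FALSE, mph = TRUE))
  expect_identical(c(c3$class, c3$ruleCase), c("OD", "BC-case3"))
  ## detected only in the backcross F1: additive
  ad <- classifyBcf1(est(comp = 0.7), c(ril = FALSE, bc = TRUE,
                                        mph = FALSE))
  expect_identical(c(ad$class, ad$ruleCase), c("A", "BC-additive"))
  ## all three datasets: judged by the case-1 effect ratio
  a3 <- classifyBcf1(est(a = 0.5, d = 0.9, comp = 1.0),
                     c(ril = TRUE, bc = TRUE, mph = TRUE))
  expect_identical(c(a3$class, a3$ruleCase), c("OD", "BC-all-three"))
})

test_that("the rule engine is total over detection patterns and strata", {
  ## every detection pattern x effect stratum yields exactly one class
  strata <- list(list(a = 1, d = 0.5), list(a = 1, d = 1),
                 list(a = 0.5, d = 1), list(a = 0, d = 0.5))
  classes <- c("A", "PD/D", "OD", "uncertain", "none")
  for (ril in c(FALSE, TRUE)) for (pop in c(FALSE, TRUE))
    for (mph in c(FALSE, TRUE)) for (s in strata) {
      ei <- data.frame(environment = "E1", a = s$a, d = s$d)
      ci <- classifyIf2(ei, c(ril = ril, if2 = pop, mph = mph))
      expect_equal(nrow(ci), 1)
      expect_true(ci$class %in% classes)
      eb <- data.frame(environment = "E1", a = s$a, d = s$d,
                       composite = s$a + s$d)
      cb <- classifyBcf1(eb, c(ril = ril, bc = pop, mph = mph),
                         population = "MARBCF1")
      expect_equal(nrow(cb), 1)
      expect_true(cb$class %in% classes)
      ## "none" only without any hybrid-dataset detection
      expect_identical(ci$class == "none", !pop && !mph)
      expect_identical(cb$class == "none", !pop && !mph)
    }
})

test_that("class summaries reproduce the published percentage layout", {
  calls <- data.frame(
    population = c(rep("IF2", 94), rep("HSBCF1", 99), rep("MARBCF1", 92)),
    class = c(rep("PD/D", 25), rep("OD", 67), rep("uncertain", 2),
              rep("A", 34), rep("PD/D", 2), rep("OD", 63),
              rep("A", 47), rep("PD/D", 6), rep("OD", 39)),
    stringsAsFactors = FALSE)
  s <- summarizeClasses(calls, pool = list(BCF1 = c("HSBCF1", "MARBCF1")))
  pick <- function(pop, cl) s$percent[s$population == pop & s$class == cl]
  expect_equal(pick("IF2", "PD/D"), 26.60)
  expect_equal(pick("IF2", "OD"), 71.28)
  expect_equal(pick("HSBCF1", "A"), 34.34)
  expect_equal(pick("BCF1", "A"), 42.41)
  expect_equal(pick("BCF1", "PD/D"), 4.19)
  expect_equal(pick("BCF1", "OD"), 53.40)
  ## percentages sum to 100 within rounding per population
  for (p in unique(s$population))
    expect_lt(abs(sum(s$percent[s$population == p]) - 100), 0.02)
  ## a single class is 100.00
  one <- summarizeClasses(data.frame(population = "IF2",
                                     class = rep("OD", 10)))
  expect_equal(one$percent[one$class == "OD"], 100)
})

test_that("scan records feed the classifier end to end", {
  rec <- function(ds, env, a = NA, d = NA, comp = NA, lo = 35, hi = 45)
    data.frame(name = paste0("q", ds, env), dataset = ds, trait = "SY",
               environment = env, chrom = "C01", peak = 40, lo = lo,
               hi = hi, lod = 5, pve = 8, a = a, d = d, composite = comp,
               favorable = "P1", stringsAsFactors = FALSE)
  recs <- rbind(rec("IF2", "E1", a = 1, d = 0.4),
                rec("IF2MPH", "E1", d = 0.45),
                rec("RIL", "E2", a = 0.9),
                rec("MARBCF1", "E1", comp = 1.2),
                rec("MARBCF1MPH", "E1", d = 0.9))
  if2calls <- classifyGeneActions(recs, "IF2")
  expect_equal(nrow(if2calls), 1)
  expect_identical(if2calls$class, "PD/D")    # |d/a| = 0.4
  bccalls <- classifyGeneActions(recs, "MARBCF1")
  expect_equal(nrow(bccalls), 1)
  expect_identical(bccalls$class, "OD")       # 2*0.9 > 1.2
})
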