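## Stage-specific child seeds so that toggling one stochastic stage does
## not shift another's randomness.
.SEED_OFFSETS <- c(genotypes = 0L, design = 104729L, phenotypes = 224737L,
                   permutations = 350377L, null = 479909L)

.childSeed <- function(seed, stage) {
  off <- .SEED_OFFSETS[[stage]]
  (as.integer(seed) + off) %% .Machine$integer.max
}

#' Simulate a genetic map
#'
#' Evenly spaced (default) or uniformly scattered markers on `nChrom`
#' chromosomes. Defaults approximate the scale of a dense intraspecific
#' SNP map: 2618 markers on 26 chromosomes.
#'
#' @param nChrom number of chromosomes.
#' @param nMarkers total marker count, split as evenly as possible.
#' @param chromLength chromosome length in cM (recycled).
#' @param spacing "even" or "uniform" (random positions; needs `seed`).
#' @param seed seed for random spacing.
#' @return A [GeneticMap-class].
#' @export
simulateMap <- function(nChrom = 26, nMarkers = 2618, chromLength = 150,
                        spacing = c("even", "uniform"), seed = 1) {
  spacing <- match.arg(spacing)
  chromLength <- rep_len(chromLength, nChrom)
  per <- rep(nMarkers %/% nChrom, nChrom)
  extra <- nMarkers %% nChrom
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (spacing == "uniform") set.seed(seed)
  chrom <- marker <- character(0); pos <- numeric(0)
  for (k in seq_len(nChrom)) {
    cid <- sprintf("C%02d", k)
    p <- if (spacing == "even") seq(0, chromLength[k], length.out = per[k])
         else sort(runif(per[k], 0, chromLength[k]))
    chrom <- c(chrom, rep(cid, per[k]))
    marker <- c(marker, sprintf("%sM%03d", cid, seq_len(per[k])))
    pos <- c(pos, p)
  }
  GeneticMap(chrom = chrom, marker = marker, pos = pos)
}

## One meiotic gamete per individual for a single chromosome.
## h1, h2: n x m haplotype matrices (0 = P1 allele, 1 = P2 allele);
## r: recombination fractions between adjacent markers (length m - 1).
.gamete <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  start <- runif(n) < 0.5
  if (m > 1L) {
    sw <- matrix(runif(n * (m - 1L)) < rep(r, each = n), n, m - 1L)
    path <- apply(cbind(start, sw), 1, cumsum)    # m x n
    path <- t(path) %% 2L
  } else {
    path <- matrix(as.integer(start), n, 1L)
  }
  out <- h1
  out[path == 1L] <- h2[path == 1L]
  out
}

#' Simulate RIL genotypes by single-seed descent
#'
#' Each line starts as the F1 of the cross AA x BB (heterozygous at
#' every marker) and is selfed for `cfg@selfingGenerations` generations,
#' with crossovers drawn independently per marker interval at the
#' Haldane recombination fraction of the interval length. Residual
#' heterozygosity per locus is therefore about `(1/2)^generations`
#' (0.78\% at F8), as in real F8 lines.
#'
#' @param map a [GeneticMap-class].
#' @param cfg a [SimConfig-class]; `cfg@nRil` lines are produced.
#' @param seed seed (default derived from `cfg@seed`).
#' @param mapFunction map function for interval crossover probabilities.
#' @return A [GenotypeMatrix-class] with population "RIL".
#' @export
simulateRilGenotypes <- function(map, cfg,
                                 seed = .childSeed(cfg@seed, "genotypes"),
                                 mapFunction = "haldane") {
  set.seed(seed)
  rf <- .recombFun(mapFunction)
  n <- cfg@nRil
  calls <- matrix(NA_integer_, n, length(map@marker),
                  dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                  map@marker))
  for (cc in unique(map@chrom)) {
    idx <- which(map@chrom == cc)
    m <- length(idx)
    r <- if (m > 1L) rf(diff(map@pos[idx])) else numeric(0)
    h1 <- matrix(0L, n, m)
    h2 <- matrix(1L, n, m)
    for (g in seq_len(cfg@selfingGenerations)) {
      g1 <- .gamete(h1, h2, r)
      g2 <- .gamete(h1, h2, r)
      h1 <- g1; h2 <- g2
    }
    calls[, idx] <- h1 + h2
  }
  GenotypeMatrix(calls, "RIL", map)
}

#' Parental genotype matrices
#'
#' P1 is homozygous AA at every marker, P2 homozygous BB.
#'
#' @param map a [GeneticMap-class].
#' @param parent "P1" or "P2".
#' @return A single-row [GenotypeMatrix-class].
#' @export
parentalGenotypes <- function(map, parent = c("P1", "P2")) {
  parent <- match.arg(parent)
  calls <- matrix(if (parent == "P1") 0L else 2L, 1,
                  length(map@marker),
                  dimnames = list(parent, map@marker))
  GenotypeMatrix(calls, parent, map)
}

#' Simulate multi-environment replicated phenotypes
#'
#' Forward model matching the analysis assumptions:
#' `y = mu_e + sum_l (a x + d z + qe_e x) + sum_pairs (aa x1 x2 +
#' ad x1 z2 + da z1 x2 + dd z1 z2) + GE + eps`, with `x` in
#' {-1, 0, +1} counting P1-origin alleles and `z = 1` for
#' heterozygotes. A causal position falling between markers uses the
#' flanking-marker expectation of `x` and `z`. Replicates share every
#' term except the residual.
#'
#' @param geno a [GenotypeMatrix-class] (any population).
#' @param arch a [QTLArchitecture-class].
#' @param cfg a [SimConfig-class]; environments/replicates are taken
#'   from it and must match `ncol(arch@envMeans)`.
#' @param seed seed (default derived from `cfg@seed`).
#' @return A [PhenotypeTable-class] of kind "raw".
#' @export
simulatePhenotypes <- function(geno, arch, cfg,
                               seed = .childSeed(cfg@seed, "phenotypes")) {
  set.seed(seed)
  nEnv <- cfg@environments
  if (ncol(arch@envMeans) != nEnv)
    stop("architecture envMeans must have one column per environment")
  envs <- colnames(arch@envMeans)
  if (is.null(envs)) envs <- sprintf("E%d", seq_len(nEnv))
  traits <- rownames(arch@envMeans)
  ids <- individuals(geno)
  n <- length(ids)

  scoreAt <- function(chrom, pos) {
    p <- .probEngine(geno, data.frame(chrom = chrom, pos = pos))
    list(x = p$pAA[, 1] - p$pBB[, 1], z = p$pAB[, 1])
  }

  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    g <- matrix(0, n, nEnv)                      # genetic value per env
    li <- which(arch@loci$trait == tr)
    for (l in li) {
      loc <- arch@loci[l, ]
      if (!loc$chrom %in% unique(geno@map@chrom))
        stop(sprintf("causal locus on unknown chromosome %s", loc$chrom))
      rng <- range(geno@map@pos[geno@map@chrom == loc$chrom])
      if (loc$pos < rng[1] - 1e-9 || loc$pos > rng[2] + 1e-9)
        stop(sprintf("causal position %.2f cM is off the %s map",
                     loc$pos, loc$chrom))
      s <- scoreAt(loc$chrom, loc$pos)
      g <- g + outer(s$x, rep(loc$a, nEnv)) + outer(s$z, rep(loc$d, nEnv))
      g <- g + outer(s$x, arch@qe[l, seq_len(nEnv)])
    }
    ei <- which(arch@epistasis$trait == tr)
    for (l in ei) {
      ep <- arch@epistasis[l, ]
      s1 <- scoreAt(ep$chrom1, ep$pos1)
      s2 <- scoreAt(ep$chrom2, ep$pos2)
      w <- ep$aa * s1$x * s2$x + ep$ad * s1$x * s2$z +
           ep$da * s1$z * s2$x + ep$dd * s1$z * s2$z
      g <- g + w
    }
    ge <- matrix(rnorm(n * nEnv, 0, arch@sigmaGE[tr]), n, nEnv)
    recs <- expand.grid(replicate = seq_len(cfg@replicates),
                        environment = seq_len(nEnv),
                        individual = seq_len(n))
    mu <- arch@envMeans[tr, recs$environment]
    base <- mu + g[cbind(recs$individual, recs$environment)] +
      ge[cbind(recs$individual, recs$environment)]
    y <- base + rnorm(nrow(recs), 0, arch@sigmaE[tr])
    cl <- arch@clamp
    if (nrow(cl) && tr %in% cl$trait) {
      b <- cl[cl$trait == tr, ]
      y <- pmin(pmax(y, b$lo), b$hi)
    }
    out[[ti]] <- data.frame(individual = ids[recs$individual],
                            trait = tr,
                            environment = envs[recs$environment],
                            replicate = recs$replicate,
                            value = y, stringsAsFactors = FALSE)
  }
  PhenotypeTable(do.call(rbind, out), kind = "raw")
}

#' Write the truth ledger of a simulated architecture
#'
#' Machine-readable table of the causal loci with the dominance degree
#' `|d/a|` and the gene-action class each locus would receive under the
#' classification rules (`d = 0` additive; `|d/a| <= 1` partial/complete
#' dominance; `|d/a| > 1`, including `a = 0` with `d != 0`,
#' over-dominance). Used by parameter-recovery tests.
#'
#' @param arch a [QTLArchitecture-class].
#' @param path optional CSV path; written when given.
#' @return The ledger data.frame, invisibly when `path` is given.
#' @export
emitTruthLedger <- function(arch, path = NULL) {
  loci <- arch@loci
  if (!nrow(loci)) {
    led <- data.frame(trait = character(), chrom = character(),
                      pos = numeric(), a = numeric(), d = numeric(),
                      ratio = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  } else {
    ratio <- ifelse(loci$a == 0, ifelse(loci$d == 0, 0, Inf),
                    abs(loci$d / loci$a))
    class <- ifelse(loci$d == 0, "A",
                    ifelse(ratio <= 1, "PD/D", "OD"))
    led <- data.frame(trait = loci$trait, chrom = loci$chrom,
                      pos = loci$pos, a = loci$a, d = loci$d,
                      ratio = ratio, class = class,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.csv(led, path, row.names = FALSE)
    return(invisible(led))
  }
  led
}

#' A demonstration QTL architecture
#'
#' A small architecture for the six yield traits with environment means
#' and noise scales loosely matched to typical upland-cotton field
#' values (plant architecture counts, boll weight in g, lint percentage,
#' plot yields); a handful of loci per trait spanning additive, partial
#' dominance and over-dominant action, mild QTL-by-environment
#' deviations and a couple of digenic interactions. Intended for demos
#' and the pipeline default; tests build their own architectures.
#'
#' @param map a [GeneticMap-class]; loci are placed mid-chromosome on
#'   the first chromosomes.
#' @param environments number of environments.
#' @return A [QTLArchitecture-class].
#' @export
demoArchitecture <- function(map, environments = 4) {
  chr <- chromosomes(map)
  mid <- function(k) {
    p <- map@pos[map@chrom == chr[(k - 1) %% length(chr) + 1]]
    unname(p[1] + 0.55 * diff(range(p)))
  }
  chrAt <- function(k) chr[(k - 1) %% length(chr) + 1]
  base <- c(FB = 8.6, BN = 12.5, BW = 6.1, LP = 37.7, SY = 720, LY = 270)
  sigE <- c(FB = 1.3, BN = 3.4, BW = 0.65, LP = 2.1, SY = 150, LY = 60)
  envMeans <- outer(base, c(1, 0.97, 1.05, 1.02))
  colnames(envMeans) <- sprintf("E%d", seq_len(4))[seq_len(4)]
  envMeans <- envMeans[, seq_len(environments), drop = FALSE]
  mk <- function(trait, ks, a, d)
    data.frame(trait = trait, chrom = vapply(ks, chrAt, ""),
               pos = vapply(ks, mid, 0), a = a, d = d,
               stringsAsFactors = FALSE)
  loci <- rbind(
    mk("FB", 1:2, a = c(0.5, 0.2),  d = c(0.0, 0.6)),
    mk("BN", 2:4, a = c(1.2, 0.8, 0.3), d = c(0.5, 1.6, 0.0)),
    mk("BW", 3:4, a = c(0.25, 0.1), d = c(0.1, 0.3)),
    mk("LP", c(1, 5), a = c(0.9, 0.6), d = c(0.3, 0.0)),
    mk("SY", c(2, 5), a = c(55, 30), d = c(20, 75)),
    mk("LY", c(3, 5), a = c(22, 12), d = c(8, 30)))
  qe <- matrix(0, nrow(loci), environments)
  qe[1, seq_len(min(2, environments))] <- c(0.15, -0.15)[seq_len(min(2, environments))]
  epi <- data.frame(trait = c("SY", "BN"),
                    chrom1 = chrAt(1), pos1 = mid(1),
                    chrom2 = chrAt(4), pos2 = mid(4),
                    aa = c(40, 0.9), ad = 0, da = 0, dd = 0,
                    stringsAsFactors = FALSE)
  qtlArchitecture(loci = loci, envMeans = envMeans, qe = qe,
                  epistasis = epi,
                  sigmaGE = sigE / 4, sigmaE = sigE)
}
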