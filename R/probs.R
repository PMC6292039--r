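## Conditional genotype probabilities from flanking markers.
##
## Every population is reduced to one or two two-state Markov chains
## along the chromosome (state = parental origin of a transmitted
## genome), with switch probability between positions given by the map
## function of the cM distance:
##   RIL       one chain; genotype AA <-> state A, BB <-> state B
##   backcross one chain for the RIL-derived gamete; the recurrent
##             gamete is constant
##   IF2       two exchangeable independent chains (the two RIL-derived
##             genomes); a heterozygous call constrains the unordered
##             pair
## Heterozygous RIL calls cannot be represented by a homozygous chain
## and are treated as missing for interpolation.

## P(chain in state A at the test point) given flank states
## (0 = A, 1 = B, NA = uninformative) and flank recombination fractions.
.chainPostA <- function(sL, sR, rL, rR) {
  aL <- ifelse(is.na(sL), 0.5, ifelse(sL == 0L, 1 - rL, rL))
  bL <- ifelse(is.na(sL), 0.5, ifelse(sL == 0L, rL, 1 - rL))
  aR <- ifelse(is.na(sR), 0.5, ifelse(sR == 0L, 1 - rR, rR))
  bR <- ifelse(is.na(sR), 0.5, ifelse(sR == 0L, rR, 1 - rR))
  num <- aL * aR
  num / (num + bL * bR)
}

## IF2 genotype distribution given flanking genotype calls (0/1/2/NA).
.if2Post <- function(cL, cR, rL, rR) {
  n <- length(cL)
  hetL <- !is.na(cL) & cL == 1L
  hetR <- !is.na(cR) & cR == 1L
  sL <- ifelse(is.na(cL) | hetL, NA_integer_, ifelse(cL == 0L, 0L, 1L))
  sR <- ifelse(is.na(cR) | hetR, NA_integer_, ifelse(cR == 0L, 0L, 1L))
  pAA <- pAB <- pBB <- numeric(n)
  mix <- function(p1, p2)
    list(AA = p1 * p2, AB = p1 * (1 - p2) + p2 * (1 - p1),
         BB = (1 - p1) * (1 - p2))
  i <- !hetL & !hetR
  if (any(i)) {                       # both chains share both constraints
    p <- .chainPostA(sL[i], sR[i], rL[i], rR[i])
    m <- mix(p, p)
    pAA[i] <- m$AA; pAB[i] <- m$AB; pBB[i] <- m$BB
  }
  i <- hetL & !hetR
  if (any(i)) {                       # chains pinned to A and B on the left
    k <- sum(i)
    m <- mix(.chainPostA(rep(0L, k), sR[i], rL[i], rR[i]),
             .chainPostA(rep(1L, k), sR[i], rL[i], rR[i]))
    pAA[i] <- m$AA; pAB[i] <- m$AB; pBB[i] <- m$BB
  }
  i <- !hetL & hetR
  if (any(i)) {
    k <- sum(i)
    m <- mix(.chainPostA(sL[i], rep(0L, k), rL[i], rR[i]),
             .chainPostA(sL[i], rep(1L, k), rL[i], rR[i]))
    pAA[i] <- m$AA; pAB[i] <- m$AB; pBB[i] <- m$BB
  }
  i <- hetL & hetR
  if (any(i)) {
    ## two pairings of left {A,B} with right {A,B}, weighted by the
    ## chain transition probabilities across the whole interval
    k <- sum(i)
    S <- (1 - rL[i]) * (1 - rR[i]) + rL[i] * rR[i]
    D <- 1 - S
    wA <- S^2 / (S^2 + D^2)
    mA <- mix(.chainPostA(rep(0L, k), rep(0L, k), rL[i], rR[i]),
              .chainPostA(rep(1L, k), rep(1L, k), rL[i], rR[i]))
    mC <- mix(.chainPostA(rep(0L, k), rep(1L, k), rL[i], rR[i]),
              .chainPostA(rep(1L, k), rep(0L, k), rL[i], rR[i]))
    pAA[i] <- wA * mA$AA + (1 - wA) * mC$AA
    pAB[i] <- wA * mA$AB + (1 - wA) * mC$AB
    pBB[i] <- wA * mA$BB + (1 - wA) * mC$BB
  }
  list(pAA = pAA, pAB = pAB, pBB = pBB)
}

## Genotype-class probabilities at arbitrary positions.
## positions: data.frame(chrom, pos). Returns pAA/pAB/pBB matrices
## (individuals x positions).
.probEngine <- function(geno, positions, rilHetAsNA = TRUE,
                        mapFunction = "haldane") {
  rf <- .recombFun(mapFunction)
  pop <- geno@population
  calls <- geno@calls
  n <- nrow(calls)
  G <- nrow(positions)
  pAA <- pAB <- pBB <- matrix(0, n, G,
                              dimnames = list(rownames(calls), NULL))
  if (pop %in% c("P1", "P2")) {
    if (pop == "P1") pAA[] <- 1 else pBB[] <- 1
    return(list(pAA = pAA, pAB = pAB, pBB = pBB))
  }
  ## observation matrix feeding the chains; NA = uninformative
  obs <- calls
  if (pop == "RIL") {
    obs[obs == 1L] <- NA_integer_                     # het not chain-codable
  } else if (pop == "HSBCF1") {
    obs[obs == 2L] <- NA_integer_                     # impossible class
  } else if (pop == "MARBCF1") {
    obs[obs == 0L] <- NA_integer_
  }
  map <- geno@map
  for (cc in unique(as.character(positions$chrom))) {
    gi <- which(positions$chrom == cc)
    gp <- positions$pos[gi]
    mi <- which(map@chrom == cc)
    if (!length(mi))
      stop(sprintf("no markers on chromosome %s", cc))
    mpos <- map@pos[mi]
    sub <- obs[, mi, drop = FALSE]
    sL <- sR <- matrix(NA_integer_, n, length(gi))
    dL <- dR <- matrix(NA_real_, n, length(gi))
    for (ind in seq_len(n)) {
      inf <- which(!is.na(sub[ind, ]))
      if (!length(inf)) next
      ip <- mpos[inf]
      li <- findInterval(gp, ip)
      hasL <- li >= 1L
      sL[ind, hasL] <- sub[ind, inf[li[hasL]]]
      dL[ind, hasL] <- gp[hasL] - ip[li[hasL]]
      ri <- li + 1L
      hasR <- ri <= length(inf)
      sR[ind, hasR] <- sub[ind, inf[ri[hasR]]]
      dR[ind, hasR] <- ip[ri[hasR]] - gp[hasR]
    }
    rL <- rf(ifelse(is.na(dL), 0, dL))
    rR <- rf(ifelse(is.na(dR), 0, dR))
    rL[is.na(dL)] <- NA_real_
    rR[is.na(dR)] <- NA_real_
    if (pop == "IF2") {
      post <- .if2Post(as.vector(sL), as.vector(sR),
                       as.vector(rL), as.vector(rR))
      pAA[, gi] <- post$pAA
      pAB[, gi] <- post$pAB
      pBB[, gi] <- post$pBB
    } else {
      pA <- .chainPostA(as.vector(sL), as.vector(sR),
                        as.vector(rL), as.vector(rR))
      pA <- matrix(pA, n)
      if (pop == "RIL") {
        pAA[, gi] <- pA
        pBB[, gi] <- 1 - pA
      } else if (pop == "HSBCF1") {   # state A -> AA, state B -> AB
        pAA[, gi] <- pA
        pAB[, gi] <- 1 - pA
      } else {                        # MARBCF1: state A -> AB, B -> BB
        pAB[, gi] <- pA
        pBB[, gi] <- 1 - pA
      }
    }
  }
  list(pAA = pAA, pAB = pAB, pBB = pBB)
}

## Additive marker scores (x = 1 - call, counting P1 alleles relative
## to heterozygote), mean-imputed, for cofactor regression.
.markerScores <- function(calls) {
  x <- 1 - calls
  cm <- colMeans(x, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- cm[nas[, 2]]
  x
}

#' Genotype probabilities on a scan grid
#'
#' Expected genotype-class probabilities at every grid position,
#' conditional on the nearest informative flanking markers under the
#' chosen map function. At a typed marker the probabilities collapse to
#' an indicator on the observed class; individuals with no informative
#' marker on a chromosome fall back to the population prior.
#'
#' @param geno a [GenotypeMatrix-class] (RIL, IF2 or backcross).
#' @param step grid step in cM (> 0); the grid runs from the first to
#'   the last marker of each chromosome.
#' @param rilHetAsNA treat residual heterozygous RIL calls as missing
#'   (the default; a two-class RIL chain cannot carry them).
#' @param mapFunction "haldane" (default) or "kosambi".
#' @return A [GenotypeProbabilityGrid-class].
#' @export
genotypeProbabilities <- function(geno, step = 1, rilHetAsNA = TRUE,
                                  mapFunction = "haldane") {
  if (step <= 0) stop("step must be positive")
  map <- geno@map
  grid <- do.call(rbind, lapply(unique(map@chrom), function(cc) {
    p <- map@pos[map@chrom == cc]
    gp <- seq(p[1], p[length(p)], by = step)
    if (tail(gp, 1) < p[length(p)] - 1e-9)
      gp <- c(gp, p[length(p)])
    data.frame(chrom = cc, pos = gp, stringsAsFactors = FALSE)
  }))
  post <- .probEngine(geno, grid, rilHetAsNA = rilHetAsNA,
                      mapFunction = mapFunction)
  calls <- geno@calls
  if (geno@population == "RIL" && rilHetAsNA)
    calls[calls == 1L] <- NA_integer_
  new("GenotypeProbabilityGrid",
      population = geno@population,
      individuals = rownames(geno@calls),
      grid = grid,
      pAA = post$pAA, pAB = post$pAB, pBB = post$pBB,
      markerScores = .markerScores(calls),
      map = map, step = step)
}
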