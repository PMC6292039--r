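## Stacked (environment-major) phenotype matrix for joint models.
## Returns list(y = n x E matrix, envs, ids) using complete cases only.
.envMatrix <- function(pheno, probs, trait) {
  d <- phenoData(pheno)
  d <- d[d$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no phenotype records for trait %s", trait))
  envs <- sort(unique(d$environment))
  if (length(envs) < 2L)
    stop("multi-environment scan needs >= 2 environments; use cimScan")
  m <- tapply(d$value, list(d$individual, d$environment), mean,
              na.rm = TRUE)
  m <- m[probs@individuals, envs, drop = FALSE]
  keep <- stats::complete.cases(m)
  if (sum(keep) < nrow(m))
    warning(sprintf("%d individual(s) dropped (incomplete environments)",
                    sum(!keep)))
  list(y = m[keep, , drop = FALSE], envs = envs, keep = keep)
}

## Single locus regressor per dataset type: expected additive score for
## RIL/IF2 values, heterozygote expectation for backcross and MPH data.
.locusScore <- function(probs, type) {
  if (type %in% c("additive", "full")) probs@pAA - probs@pBB
  else probs@pAB
}

## RSS of Y against X for all columns (Y: N x K).
.rssAll <- function(X, Y) {
  q <- qr(X)
  qty <- qr.qty(q, Y)[seq_len(q$rank), , drop = FALSE]
  pmax(colSums(Y^2) - colSums(qty^2), 0)
}

#' Multi-environment main-effect QTL scan
#'
#' Two-stage scan across environments: background markers are first
#' selected by forward-stepwise regression on the environment-mean
#' phenotype with entry threshold `pin`; then at every grid position
#' the stacked per-environment phenotype is fitted with the joint model
#' `y_ie = mu_e + a x_i + (ae)_e x_i + cofactors + eps` and compared to
#' the no-locus model, `LOD = (N/2) log10(RSS0/RSS2)` over the `N`
#' stacked observations. The phenotypic variance percentages are
#' sequential sums of squares over the total phenotypic SS: `PV(A)`
#' from adding the pooled locus effect, `PV(AE)` from adding its
#' environment interaction. The genome-wide threshold comes from
#' permuting individuals (rows of the environment matrix) against fixed
#' genotypes. Supra-threshold regions are called as m-QTLs, named
#' `<abbrev>maq<trait>-<chrom>-<number>`.
#'
#' @param pheno a [PhenotypeTable-class] spanning >= 2 environments.
#' @param probs a [GenotypeProbabilityGrid-class].
#' @param trait trait to scan.
#' @param pin stepwise entry p-value (default 1e-4).
#' @param nPerm permutations for the threshold (default 200).
#' @param alpha genome-wide significance level.
#' @param window cofactor exclusion window (cM).
#' @param maxCofactors maximum background markers.
#' @param lodCap LOD cap for perfect fits.
#' @param seed optional permutation seed.
#' @return List with `records` (data.frame of m-QTLs: name, dataset,
#'   trait, chrom, pos, lod, pvTotal, pvA, pvAE, and one `a_<env>`
#'   column per environment), `profile` (per-position data.frame) and
#'   `threshold`.
#' @export
mqtlScan <- function(pheno, probs, trait, pin = 1e-4, nPerm = 200,
                     alpha = 0.05, window = 10, maxCofactors = 10,
                     lodCap = 50, seed = NULL) {
  em <- .envMatrix(pheno, probs, trait)
  sub <- .subsetProbs(probs, em$keep)
  type <- .scanType(probs@population, phenoKind(pheno))
  n <- nrow(em$y); E <- ncol(em$y); N <- n * E
  cof <- selectCofactors(rowMeans(em$y), sub, maxCofactors = maxCofactors,
                         pEnter = pin)
  if (!is.null(seed)) set.seed(seed)
  YS <- matrix(0, N, 1 + nPerm)
  YS[, 1] <- as.vector(em$y)
  if (nPerm > 0) {
    if (nPerm < 20) stop("nPerm below 20 is refused")
    for (k in seq_len(nPerm))
      YS[, 1 + k] <- as.vector(em$y[sample(n), , drop = FALSE])
  }
  envBlock <- function(v) as.vector(v)            # n-vector -> stacked
  ED <- kronecker(diag(E), rep(1, n))             # environment dummies
  C <- kronecker(stats::contr.sum(E), rep(1, n))  # sum-to-zero env contrasts
  U <- .locusScore(sub, type)
  CSc <- apply(sub@markerScores[, cof, drop = FALSE], 2,
               function(s) rep(s, E))
  CSc <- matrix(CSc, nrow = N)
  mtab <- mapTable(sub@map)
  cofPos <- mtab$pos[match(cof, mtab$marker)]
  cofChr <- mtab$chrom[match(cof, mtab$marker)]
  grid <- sub@grid
  G <- nrow(grid)
  tss <- colSums(YS^2) - N * colMeans(YS)^2
  lod <- matrix(0, G, 1 + nPerm)
  pvA <- pvAE <- rep(0, G)
  aEnv <- matrix(NA_real_, G, E)
  tol <- 1e-12 * pmax(tss, .Machine$double.eps)
  for (g in seq_len(G)) {
    keepC <- which(!(cofChr == grid$chrom[g] &
                       abs(cofPos - grid$pos[g]) <= window))
    u <- rep(U[, g], E)
    M0 <- cbind(ED, CSc[, keepC, drop = FALSE])
    M1 <- cbind(M0, u)
    M2 <- cbind(M1, u * C)
    rss0 <- .rssAll(M0, YS)
    rss1 <- .rssAll(M1, YS)
    rss2 <- .rssAll(M2, YS)
    l <- (N / 2) * log10(rss0 / rss2)
    l[rss2 <= tol] <- lodCap
    l[rss0 <= tol | tss <= .Machine$double.eps] <- 0
    lod[g, ] <- pmin(pmax(l, 0), lodCap)
    pvA[g] <- 100 * max(rss0[1] - rss1[1], 0) / max(tss[1], 1e-300)
    pvAE[g] <- 100 * max(rss1[1] - rss2[1], 0) / max(tss[1], 1e-300)
    q2 <- qr(M2)
    cf <- qr.coef(q2, YS[, 1])
    p <- ncol(M2)
    gamma <- cf[(p - E + 2):p]
    gamma[is.na(gamma)] <- 0
    aMain <- cf[p - E + 1]
    aEnv[g, ] <- aMain + as.vector(stats::contr.sum(E) %*% gamma)
  }
  thr <- if (nPerm > 0)
    quantile(apply(lod[, -1, drop = FALSE], 2, max), 1 - alpha,
             names = FALSE)
  else NA_real_
  profile <- cbind(grid, lod = lod[, 1], pvA = pvA, pvAE = pvAE)
  dataset <- .datasetId(probs@population, phenoKind(pheno))
  recs <- .callPeaks(profile, thr)
  if (nrow(recs)) {
    i <- recs$gridRow
    recs <- data.frame(dataset = dataset, trait = trait,
                       chrom = recs$chrom, pos = recs$pos,
                       lod = recs$lod,
                       pvTotal = pvA[i] + pvAE[i],
                       pvA = pvA[i], pvAE = pvAE[i],
                       stringsAsFactors = FALSE)
    ae <- as.data.frame(aEnv[i, , drop = FALSE])
    names(ae) <- paste0("a_", em$envs)
    recs <- cbind(recs, ae)
    num <- stats::ave(seq_len(nrow(recs)), recs$chrom, FUN = seq_along)
    recs$name <- formatQtlName("mqtl", trait = trait, chrom = recs$chrom,
                               number = num, dataset = dataset)
    recs <- recs[, c("name", setdiff(names(recs), "name"))]
  } else {
    recs <- data.frame(name = character(), dataset = character(),
                       trait = character(), chrom = character(),
                       pos = numeric(), lod = numeric(),
                       pvTotal = numeric(), pvA = numeric(),
                       pvAE = numeric(), stringsAsFactors = FALSE)
  }
  list(records = recs, profile = profile, threshold = thr,
       cofactors = cof)
}

## Peak positions of contiguous supra-threshold runs per chromosome.
.callPeaks <- function(profile, threshold) {
  out <- list()
  if (is.na(threshold)) return(data.frame())
  for (cc in unique(profile$chrom)) {
    gi <- profile[profile$chrom == cc, , drop = FALSE]
    rows <- which(profile$chrom == cc)
    above <- gi$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      seg <- starts[k]:ends[k]
      pk <- seg[which.max(gi$lod[seg])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, pos = gi$pos[pk], lod = gi$lod[pk],
        gridRow = rows[pk], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Two-locus epistatic QTL scan across environments
#'
#' All position pairs on a coarse grid (different chromosomes, or the
#' same chromosome at more than `minDist` cM) are fitted with the joint
#' model containing both main effects, their environment interactions,
#' the epistatic product term(s) and the products' environment
#' interactions; the LOD tests the epistatic block. For IF2 genotype
#' classes the dominance scores and all four product terms (aa, ad, da,
#' dd) enter the epistatic block; RIL-derived two-class datasets use
#' the additive-by-additive product only. `PV(AA)` and `PV(AAE)` are
#' sequential sums of squares of the epistatic main block and its
#' environment interaction over the total phenotypic SS. The threshold
#' permutes individuals and takes the `(1-alpha)` quantile of the
#' maximum epistatic LOD over all pairs. Declared pairs are greedily
#' de-clumped (a pair is dropped when both its loci fall within
#' `declumpRadius` of an already-accepted, higher-LOD pair) and named
#' `<abbrev>meq<trait>-<pair number>`.
#'
#' @inheritParams mqtlScan
#' @param step pair-grid step in cM (default 5).
#' @param minDist minimum within-chromosome separation (default 20 cM).
#' @param nPerm permutations for the epistatic threshold (default 200).
#' @param declumpRadius cM radius for de-clumping declared pairs.
#' @return List with `records` (data.frame: name, dataset, trait,
#'   chrom1, pos1, chrom2, pos2, lod, pvAA, pvAAE), `pairs` (all
#'   tested pairs with their statistics) and `threshold`.
#' @export
eqtlScan <- function(pheno, probs, trait, pin = 1e-4, step = 5,
                     minDist = 20, nPerm = 200, alpha = 0.05,
                     lodCap = 50, declumpRadius = 10, window = 10,
                     maxCofactors = 10, seed = NULL) {
  em <- .envMatrix(pheno, probs, trait)
  sub <- .subsetProbs(probs, em$keep)
  type <- .scanType(probs@population, phenoKind(pheno))
  n <- nrow(em$y); E <- ncol(em$y); N <- n * E
  cof <- selectCofactors(rowMeans(em$y), sub, maxCofactors = maxCofactors,
                         pEnter = pin)
  ## coarse grid: every position a multiple of `step` from the
  ## chromosome start (the last marker is not forced in)
  g0 <- sub@grid
  sel <- abs((g0$pos - stats::ave(g0$pos, g0$chrom, FUN = min)) %%
               step) < 1e-9
  gidx <- which(sel)
  if (length(gidx) < 2L) stop("pair grid has fewer than 2 positions")
  grid <- g0[gidx, , drop = FALSE]
  chromNum <- match(grid$chrom, unique(g0$chrom))
  P <- length(gidx)
  cmb <- which(upper.tri(matrix(TRUE, P, P)), arr.ind = TRUE)
  ok <- chromNum[cmb[, 1]] != chromNum[cmb[, 2]] |
    abs(grid$pos[cmb[, 1]] - grid$pos[cmb[, 2]]) > minDist
  cmb <- cmb[ok, , drop = FALSE]
  if (!nrow(cmb)) stop("no admissible position pairs")
  if (!is.null(seed)) set.seed(seed)
  YS <- matrix(0, N, 1 + nPerm)
  YS[, 1] <- as.vector(em$y)
  if (nPerm > 0) {
    if (nPerm < 20) stop("nPerm below 20 is refused")
    for (k in seq_len(nPerm))
      YS[, 1 + k] <- as.vector(em$y[sample(n), , drop = FALSE])
  }
  ED <- kronecker(diag(E), rep(1, n))
  C <- kronecker(stats::contr.sum(E), rep(1, n))
  CSc <- matrix(apply(sub@markerScores[, cof, drop = FALSE], 2,
                      function(s) rep(s, E)), nrow = N)
  mtab <- mapTable(sub@map)
  cofPos <- mtab$pos[match(cof, mtab$marker)]
  cofChr <- mtab$chrom[match(cof, mtab$marker)]
  X <- (sub@pAA - sub@pBB)[, gidx, drop = FALSE]
  Z <- sub@pAB[, gidx, drop = FALSE]
  useD <- type == "full"                  # IF2 genotype classes
  U <- if (type %in% c("additive", "full")) X else Z
  tss <- colSums(YS^2) - N * colMeans(YS)^2
  tol <- 1e-12 * pmax(tss, .Machine$double.eps)
  K <- nrow(cmb)
  lod <- matrix(0, K, 1 + nPerm)
  pvAA <- pvAAE <- numeric(K)
  rpt <- function(v) rep(v, E)
  for (k in seq_len(K)) {
    i <- cmb[k, 1]; j <- cmb[k, 2]
    u1 <- rpt(U[, i]); u2 <- rpt(U[, j])
    main <- cbind(u1, u2, u1 * C, u2 * C)
    W <- cbind(u1 * u2)
    if (useD) {
      z1 <- rpt(Z[, i]); z2 <- rpt(Z[, j])
      main <- cbind(main, z1, z2, z1 * C, z2 * C)
      W <- cbind(W, u1 * z2, z1 * u2, z1 * z2)
    }
    keepC <- which(!((cofChr == grid$chrom[i] &
                        abs(cofPos - grid$pos[i]) <= window) |
                       (cofChr == grid$chrom[j] &
                          abs(cofPos - grid$pos[j]) <= window)))
    M0 <- cbind(ED, CSc[, keepC, drop = FALSE], main)
    M1 <- cbind(M0, W)
    WE <- do.call(cbind, lapply(seq_len(ncol(W)), function(cw)
      W[, cw] * C))
    M2 <- cbind(M1, WE)
    rss0 <- .rssAll(M0, YS)
    rss1 <- .rssAll(M1, YS)
    rss2 <- .rssAll(M2, YS)
    l <- (N / 2) * log10(rss0 / rss2)
    l[rss2 <= tol] <- lodCap
    l[rss0 <= tol | tss <= .Machine$double.eps] <- 0
    lod[k, ] <- pmin(pmax(l, 0), lodCap)
    pvAA[k] <- 100 * max(rss0[1] - rss1[1], 0) / max(tss[1], 1e-300)
    pvAAE[k] <- 100 * max(rss1[1] - rss2[1], 0) / max(tss[1], 1e-300)
  }
  thr <- if (nPerm > 0)
    quantile(apply(lod[, -1, drop = FALSE], 2, max), 1 - alpha,
             names = FALSE)
  else NA_real_
  pairs <- data.frame(chrom1 = grid$chrom[cmb[, 1]],
                      pos1 = grid$pos[cmb[, 1]],
                      chrom2 = grid$chrom[cmb[, 2]],
                      pos2 = grid$pos[cmb[, 2]],
                      lod = lod[, 1], pvAA = pvAA, pvAAE = pvAAE,
                      stringsAsFactors = FALSE)
  dataset <- .datasetId(probs@population, phenoKind(pheno))
  recs <- pairs[!is.na(thr) & pairs$lod >= thr, , drop = FALSE]
  if (nrow(recs)) {
    ## group supra-threshold pairs into connected ridges: two pairs are
    ## neighbours when both loci sit within declumpRadius on the same
    ## chromosomes (in either locus order); keep the ridge maximum
    near <- function(c1, p1, c2, p2)
      c1 == c2 & abs(p1 - p2) <= declumpRadius + 1e-9
    nr <- nrow(recs)
    comp <- seq_len(nr)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
      straight <- near(recs$chrom1[i], recs$pos1[i],
                       recs$chrom1[j], recs$pos1[j]) &&
        near(recs$chrom2[i], recs$pos2[i], recs$chrom2[j], recs$pos2[j])
      crossed <- near(recs$chrom1[i], recs$pos1[i],
                      recs$chrom2[j], recs$pos2[j]) &&
        near(recs$chrom2[i], recs$pos2[i], recs$chrom1[j], recs$pos1[j])
      if (straight || crossed) comp[find(j)] <- find(i)
    }
    root <- vapply(seq_len(nr), find, 0L)
    recs <- do.call(rbind, lapply(unique(root), function(g) {
      m <- recs[root == g, , drop = FALSE]
      m[which.max(m$lod), , drop = FALSE]
    }))
    ## canonical locus order within a pair
    cn <- match(recs$chrom1, unique(g0$chrom))
    cm2 <- match(recs$chrom2, unique(g0$chrom))
    swap <- cn > cm2 | (cn == cm2 & recs$pos1 > recs$pos2)
    if (any(swap)) {
      tmp <- recs[swap, c("chrom1", "pos1")]
      recs[swap, c("chrom1", "pos1")] <- recs[swap, c("chrom2", "pos2")]
      recs[swap, c("chrom2", "pos2")] <- tmp
    }
    recs <- recs[order(match(recs$chrom1, unique(g0$chrom)), recs$pos1,
                       recs$pos2), , drop = FALSE]
    recs <- data.frame(name = formatQtlName("eqtl", trait = trait,
                                            number = seq_len(nrow(recs)),
                                            dataset = dataset),
                       dataset = dataset, trait = trait, recs,
                       stringsAsFactors = FALSE)
    rownames(recs) <- NULL
  } else {
    recs <- data.frame(name = character(), dataset = character(),
                       trait = character(), chrom1 = character(),
                       pos1 = numeric(), chrom2 = character(),
                       pos2 = numeric(), lod = numeric(),
                       pvAA = numeric(), pvAAE = numeric(),
                       stringsAsFactors = FALSE)
  }
  list(records = recs, pairs = pairs, threshold = thr)
}

#' Type of an epistatic interaction
#'
#' An epistatic locus "has an m-QTL" when it lies within `radius` cM of
#' an m-QTL peak on the same chromosome for the same trait and dataset.
#' Pairs with both loci coincident are type "I", with exactly one
#' type "II", with neither type "III".
#'
#' @param eqtls e-QTL records ([eqtlScan()] `records`).
#' @param mqtls m-QTL records ([mqtlScan()] `records`).
#' @param radius coincidence radius in cM (default 5).
#' @return `eqtls` with a `type` column appended.
#' @export
classifyEpistasisType <- function(eqtls, mqtls, radius = 5) {
  if (!nrow(eqtls)) {
    eqtls$type <- character(0)
    return(eqtls)
  }
  hasM <- function(ds, tr, cc, pp) {
    m <- mqtls[mqtls$dataset == ds & mqtls$trait == tr &
                 mqtls$chrom == cc, , drop = FALSE]
    nrow(m) > 0 && any(abs(m$pos - pp) <= radius)
  }
  cnt <- vapply(seq_len(nrow(eqtls)), function(i) {
    hasM(eqtls$dataset[i], eqtls$trait[i], eqtls$chrom1[i],
         eqtls$pos1[i]) +
      hasM(eqtls$dataset[i], eqtls$trait[i], eqtls$chrom2[i],
           eqtls$pos2[i])
  }, 0L)
  eqtls$type <- c("III", "II", "I")[cnt + 1L]
  eqtls
}

#' Congruence of single-locus QTLs with m-QTLs
#'
#' An m-QTL is congruent with a single-locus QTL when its peak position
#' falls inside the single-locus support interval on the same
#' chromosome for the same trait; one single-locus QTL may harbor
#' several m-QTLs (possibly from different datasets).
#'
#' @param single single-locus QTL records ([callQtls()] or
#'   [mergeQtls()] rows; needs name, trait, chrom, lo, hi).
#' @param mqtls m-QTL records.
#' @return data.frame(single, trait, chrom, overlap, nMqtls, mqtls,
#'   span) with one row per single-locus QTL.
#' @export
congruence <- function(single, mqtls) {
  if (!nrow(single))
    return(data.frame(single = character(), trait = character(),
                      chrom = character(), overlap = logical(),
                      nMqtls = integer(), mqtls = character(),
                      span = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(single)), function(i) {
    m <- mqtls[mqtls$trait == single$trait[i] &
                 mqtls$chrom == single$chrom[i] &
                 mqtls$pos >= single$lo[i] &
                 mqtls$pos <= single$hi[i], , drop = FALSE]
    data.frame(single = single$name[i], trait = single$trait[i],
               chrom = single$chrom[i], overlap = nrow(m) > 0,
               nMqtls = nrow(m),
               mqtls = paste(m$name, collapse = ","),
               span = single$hi[i] - single$lo[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Totals of explained phenotypic variance
#'
#' Per dataset x trait: the number of records and the summed variance
#' percentages — `pvA`/`pvAE` for m-QTLs, `pvAA`/`pvAAE` for e-QTL
#' pairs — plus their total (`pv`).
#'
#' @param records m-QTL or e-QTL records.
#' @return data.frame(dataset, trait, sum, pv, and the two component
#'   columns).
#' @export
summarizePv <- function(records) {
  epi <- "pvAA" %in% names(records)
  cA <- if (epi) "pvAA" else "pvA"
  cE <- if (epi) "pvAAE" else "pvAE"
  if (!nrow(records)) {
    out <- data.frame(dataset = character(), trait = character(),
                      sum = integer(), pv = numeric(), a = numeric(),
                      e = numeric(), stringsAsFactors = FALSE)
    names(out)[5:6] <- c(cA, cE)
    return(out)
  }
  sp <- split(records, paste(records$dataset, records$trait))
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(dataset = g$dataset[1], trait = g$trait[1],
               sum = nrow(g),
               pv = sum(g[[cA]]) + sum(g[[cE]]),
               a = sum(g[[cA]]), e = sum(g[[cE]]),
               stringsAsFactors = FALSE)
  }))
  names(out)[5:6] <- c(cA, cE)
  rownames(out) <- NULL
  out[order(out$dataset, out$trait), , drop = FALSE]
}
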