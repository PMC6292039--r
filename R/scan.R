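## Replicate-averaged phenotype vector for one trait x environment,
## aligned to the probability grid's individuals. NULL environment is
## allowed only when the table holds a single environment.
.alignedPhenotype <- function(pheno, probs, trait, environment = NULL) {
  d <- phenoData(pheno)
  d <- d[d$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no phenotype records for trait %s", trait))
  if (is.null(environment)) {
    environment <- unique(d$environment)
    if (length(environment) > 1L)
      stop("phenotype spans several environments; pass `environment`")
  }
  d <- d[d$environment %in% environment, , drop = FALSE]
  m <- tapply(d$value, d$individual, mean, na.rm = TRUE)
  y <- as.numeric(m[probs@individuals])
  names(y) <- probs@individuals
  y
}

.datasetId <- function(population, kind) {
  if (kind == "MPH") paste0(population, "MPH") else population
}

## Predictor type per dataset: which locus regressors the class set
## supports. MPH datasets test only the dominance (heterozygote vs
## homozygote-mean) contrast; backcross F1 values only the composite
## heterozygote-vs-recurrent-homozygote contrast.
.scanType <- function(population, kind) {
  if (kind == "MPH") return("dominance")
  switch(population,
         RIL = "additive",
         IF2 = "full",
         HSBCF1 = ,
         MARBCF1 = "composite",
         stop(sprintf("cannot scan population %s", population)))
}

#' Forward-stepwise cofactor selection
#'
#' Background marker cofactors for composite interval mapping: markers
#' enter one at a time by smallest partial F-test p-value until no
#' candidate reaches `pEnter` or `maxCofactors` are in the model.
#'
#' @param y numeric phenotype (NA allowed; rows dropped internally).
#' @param probs a [GenotypeProbabilityGrid-class] (its marker scores
#'   are the candidate regressors).
#' @param maxCofactors maximum number of cofactors (default 10).
#' @param pEnter entry p-value threshold (default 0.01).
#' @return Character vector of selected marker names (possibly empty).
#' @export
selectCofactors <- function(y, probs, maxCofactors = 10, pEnter = 0.01) {
  keep <- !is.na(y)
  y <- y[keep]
  X <- probs@markerScores[keep, , drop = FALSE]
  n <- length(y)
  sel <- integer(0)
  res <- y - mean(y)
  Xr <- sweep(X, 2, colMeans(X))           # residualised candidates
  dfDenom <- n - 2L
  while (length(sel) < maxCofactors && dfDenom > 1L) {
    ss <- colSums(Xr^2)
    ok <- ss > 1e-10
    if (!any(ok)) break
    b <- colSums(Xr * res) / ifelse(ok, ss, NA)
    rssRed <- b^2 * ss                     # RSS reduction per candidate
    rss0 <- sum(res^2)
    Fstat <- rssRed / ((rss0 - rssRed) / dfDenom)
    Fstat[!ok | !is.finite(Fstat)] <- NA
    j <- which.max(Fstat)
    if (!length(j) || is.na(Fstat[j])) break
    p <- pf(Fstat[j], 1, dfDenom, lower.tail = FALSE)
    if (is.na(p) || p >= pEnter) break
    sel <- c(sel, j)
    ## sweep the chosen column out of the residuals and the candidates
    xj <- Xr[, j]
    res <- res - xj * sum(xj * res) / ss[j]
    proj <- colSums(Xr * xj) / ss[j]
    Xr <- Xr - outer(xj, proj)
    Xr[, sel] <- 0
    dfDenom <- dfDenom - 1L
  }
  colnames(probs@markerScores)[sel]
}

## Core scan: LOD for every grid position x phenotype column.
## Y: n x K matrix, column 1 = observed phenotype (rows = individuals
## aligned to probs). Returns list(lod = G x K, eff = data.frame of
## effect estimates and PVE for column 1).
.scanEngine <- function(Y, probs, cofactors, window, lodCap, type) {
  grid <- probs@grid
  n <- nrow(Y)
  G <- nrow(grid)
  K <- ncol(Y)
  P1 <- switch(type,
               additive = ,
               full = probs@pAA - probs@pBB,
               dominance = ,
               composite = probs@pAB)
  P2 <- if (type == "full") probs@pAB else NULL
  mtab <- mapTable(probs@map)
  ci <- match(cofactors, mtab$marker)
  cofPos <- mtab$pos[ci]
  cofChr <- mtab$chrom[ci]
  CS <- probs@markerScores[, cofactors, drop = FALSE]
  tss <- pmax(colSums(Y^2) - n * colMeans(Y)^2, 0)
  tol <- 1e-12 * pmax(tss, .Machine$double.eps)
  lod <- matrix(0, G, K)
  aE <- dE <- cE <- rep(NA_real_, G)
  pve <- rep(0, G)
  eps <- 1e-10
  ## positions sharing a retained-cofactor subset are scanned together
  ## as matrix products (residualise against [1, cofactors] once, then
  ## one cross-product for all positions x phenotype columns)
  keepKey <- vapply(seq_len(G), function(g)
    paste(which(!(cofChr == grid$chrom[g] &
                    abs(cofPos - grid$pos[g]) <= window)),
          collapse = ","), "")
  for (key in unique(keepKey)) {
    gs <- which(keepKey == key)
    keep <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]])
            else integer(0)
    X0 <- cbind(rep(1, n), CS[, keep, drop = FALSE])
    q0 <- qr(X0)
    Yr <- qr.resid(q0, Y)
    rss0 <- pmax(colSums(Yr^2), 0)
    R1 <- qr.resid(q0, P1[, gs, drop = FALSE])
    s11 <- colSums(R1^2)
    B1 <- crossprod(R1, Yr)                       # |gs| x K
    if (is.null(P2)) {
      red <- B1^2 / ifelse(s11 > eps, s11, Inf)   # row-wise by position
      b1 <- B1[, 1]
      co <- ifelse(s11 > eps, b1 / s11, NA_real_)
      if (type == "additive") aE[gs] <- co
      else if (type == "dominance") dE[gs] <- co
      else cE[gs] <- co
    } else {
      R2 <- qr.resid(q0, P2[, gs, drop = FALSE])
      s12 <- colSums(R1 * R2)
      s22 <- colSums(R2^2)
      B2 <- crossprod(R2, Yr)
      det <- s11 * s22 - s12^2
      fullRank <- det > eps * pmax(s11 * s22, eps)
      red <- (s22 * B1^2 - 2 * s12 * B1 * B2 + s11 * B2^2) /
        ifelse(fullRank, det, Inf)
      ## collinear dominance column: fall back to the additive score
      red1 <- B1^2 / ifelse(s11 > eps, s11, Inf)
      red[!fullRank, ] <- red1[!fullRank, , drop = FALSE]
      b1 <- B1[, 1]; b2 <- B2[, 1]
      aE[gs] <- ifelse(fullRank, (s22 * b1 - s12 * b2) / det,
                       ifelse(s11 > eps, b1 / s11, NA_real_))
      dE[gs] <- ifelse(fullRank, (s11 * b2 - s12 * b1) / det, NA_real_)
    }
    red <- pmin(red, matrix(rss0, nrow(red), K, byrow = TRUE))
    rss1 <- sweep(-red, 2, rss0, "+")
    l <- (n / 2) * (log10(matrix(rss0, nrow(red), K, byrow = TRUE)) -
                      log10(pmax(rss1, .Machine$double.xmin)))
    l[sweep(rss1, 2, tol, "<=")] <- lodCap
    bad <- rss0 <= tol | tss <= .Machine$double.eps
    if (any(bad)) l[, bad] <- 0
    lod[gs, ] <- pmin(pmax(l, 0), lodCap)
    if (tss[1] > 0) pve[gs] <- 100 * red[, 1] / tss[1]
  }
  list(lod = lod,
       eff = data.frame(a = aE, d = dE, composite = cE, pve = pve))
}

#' Composite-interval-mapping genome scan
#'
#' At each grid position the replicate-averaged phenotype is regressed
#' on the expected genotype scores from [genotypeProbabilities()]
#' (Haley-Knott regression) plus background marker cofactors outside a
#' `window` cM exclusion zone around the tested position;
#' `LOD = (n/2) log10(RSS_null / RSS_full)`. The regressors follow the
#' dataset: RIL values give the additive score only, IF2 values the
#' additive and dominance scores, backcross F1 values the composite
#' heterozygote-minus-recurrent-homozygote contrast, and MPH datasets
#' only the dominance contrast (heterozygote vs mean of the parental
#' homozygotes). A perfect fit is capped at `lodCap`.
#'
#' @param pheno a [PhenotypeTable-class] (raw, HB or MPH).
#' @param probs a [GenotypeProbabilityGrid-class] for the matching
#'   population.
#' @param trait trait to scan.
#' @param environment environment to scan (required when the table
#'   spans several).
#' @param cofactors marker names, or NULL to run [selectCofactors()]
#'   (set `maxCofactors = 0` for none).
#' @param window cofactor exclusion window around the test position, cM.
#' @param maxCofactors,pEnter forwarded to [selectCofactors()].
#' @param nPerm if > 0, also run this many phenotype permutations and
#'   store the genome-wide `alpha`-level threshold on the profile
#'   (cofactor selection is not re-run per permutation).
#' @param alpha genome-wide significance level for the threshold.
#' @param lodCap LOD value reported for perfect fits (default 50).
#' @return A [ScanProfile-class].
#' @export
cimScan <- function(pheno, probs, trait, environment = NULL,
                    cofactors = NULL, window = 10, maxCofactors = 10,
                    pEnter = 0.01, nPerm = 0, alpha = 0.05, lodCap = 50) {
  y <- .alignedPhenotype(pheno, probs, trait, environment)
  keep <- !is.na(y)
  if (sum(keep) < 5L) stop("fewer than 5 phenotyped individuals")
  type <- .scanType(probs@population, phenoKind(pheno))
  sub <- .subsetProbs(probs, keep)
  if (is.null(cofactors))
    cofactors <- selectCofactors(y[keep], sub, maxCofactors = maxCofactors,
                                 pEnter = pEnter)
  Y <- matrix(y[keep], ncol = 1)
  if (nPerm > 0) {
    if (nPerm < 20) stop("nPerm below 20 is refused")
    perm <- replicate(nPerm, sample(Y[, 1]))
    Y <- cbind(Y, perm)
  }
  sc <- .scanEngine(Y, sub, cofactors, window, lodCap, type)
  thr <- NA_real_
  if (nPerm > 0)
    thr <- quantile(apply(sc$lod[, -1, drop = FALSE], 2, max),
                    1 - alpha, names = FALSE)
  grid <- cbind(sub@grid,
                lod = sc$lod[, 1],
                a = sc$eff$a, d = sc$eff$d,
                composite = sc$eff$composite, pve = sc$eff$pve)
  env <- if (is.null(environment))
    unique(phenoData(pheno)$environment) else environment
  new("ScanProfile",
      dataset = .datasetId(probs@population, phenoKind(pheno)),
      trait = trait, environment = as.character(env)[1],
      grid = grid, cofactors = as.character(cofactors),
      threshold = thr, nPerm = as.integer(nPerm), step = probs@step)
}

## Row-subset a probability grid (phenotyped individuals only).
.subsetProbs <- function(probs, keep) {
  new("GenotypeProbabilityGrid",
      population = probs@population,
      individuals = probs@individuals[keep],
      grid = probs@grid,
      pAA = probs@pAA[keep, , drop = FALSE],
      pAB = probs@pAB[keep, , drop = FALSE],
      pBB = probs@pBB[keep, , drop = FALSE],
      markerScores = probs@markerScores[keep, , drop = FALSE],
      map = probs@map, step = probs@step)
}

#' Genome-wide permutation LOD threshold
#'
#' The `(1 - alpha)` quantile of the genome-wide maximum LOD over
#' phenotype permutations (individual labels reshuffled against fixed
#' genotypes). Cofactor selection is performed once on the observed
#' phenotype and held fixed across permutations.
#'
#' @inheritParams cimScan
#' @param nPerm number of permutations (>= 20; 1000 in the protocol).
#' @param seed optional seed for the permutations.
#' @return The LOD threshold (numeric scalar).
#' @export
permutationThreshold <- function(pheno, probs, trait, environment = NULL,
                                 cofactors = NULL, nPerm = 1000,
                                 alpha = 0.05, window = 10,
                                 maxCofactors = 10, pEnter = 0.01,
                                 lodCap = 50, seed = NULL) {
  if (nPerm < 20) stop("nPerm below 20 is refused")
  if (!is.null(seed)) set.seed(seed)
  prof <- cimScan(pheno, probs, trait, environment = environment,
                  cofactors = cofactors, window = window,
                  maxCofactors = maxCofactors, pEnter = pEnter,
                  nPerm = nPerm, alpha = alpha, lodCap = lodCap)
  scanThreshold(prof)
}

#' Call QTLs from a scan profile
#'
#' Contiguous supra-threshold regions become one QTL each, at the
#' position of the maximum LOD; the support interval extends from the
#' peak to where the LOD has dropped by `dropLod` (1-LOD support by
#' default). QTLs on a chromosome are numbered by position and named
#' `q<trait>-<chrom>-<number>`. The favorable allele comes from P1 when
#' the additive effect is positive.
#'
#' @param profile a [ScanProfile-class].
#' @param threshold LOD threshold; defaults to the profile's stored
#'   permutation threshold.
#' @param dropLod support-interval LOD drop (default 1).
#' @return data.frame with one row per QTL: name, dataset, trait,
#'   environment, chrom, peak, lo, hi, lod, pve, a, d, composite,
#'   favorable.
#' @export
callQtls <- function(profile, threshold = scanThreshold(profile),
                     dropLod = 1) {
  if (is.na(threshold))
    stop("no threshold available; run the scan with nPerm > 0 or pass one")
  g <- scanGrid(profile)
  out <- list()
  for (cc in unique(g$chrom)) {
    gi <- g[g$chrom == cc, , drop = FALSE]
    above <- gi$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      seg <- starts[k]:ends[k]
      pk <- seg[which.max(gi$lod[seg])]
      peakLod <- gi$lod[pk]
      ## 1-LOD support: walk outwards over the whole chromosome
      lo <- pk
      while (lo > 1L && gi$lod[lo - 1L] > peakLod - dropLod) lo <- lo - 1L
      hi <- pk
      while (hi < nrow(gi) && gi$lod[hi + 1L] > peakLod - dropLod)
        hi <- hi + 1L
      out[[length(out) + 1L]] <- data.frame(
        dataset = profile@dataset, trait = profile@trait,
        environment = profile@environment, chrom = cc,
        peak = gi$pos[pk], lo = gi$pos[lo], hi = gi$pos[hi],
        lod = peakLod, pve = gi$pve[pk],
        a = gi$a[pk], d = gi$d[pk], composite = gi$composite[pk],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(), dataset = character(),
                      trait = character(), environment = character(),
                      chrom = character(), peak = numeric(),
                      lo = numeric(), hi = numeric(), lod = numeric(),
                      pve = numeric(), a = numeric(), d = numeric(),
                      composite = numeric(), favorable = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(g$chrom)), res$peak), ,
             drop = FALSE]
  num <- stats::ave(seq_len(nrow(res)), res$chrom, FUN = seq_along)
  res$name <- formatQtlName("single", trait = res$trait,
                            chrom = res$chrom, number = num)
  res$favorable <- ifelse(is.na(res$a), NA_character_,
                          ifelse(res$a > 0, "P1", "P2"))
  rownames(res) <- NULL
  res[, c("name", "dataset", "trait", "environment", "chrom", "peak",
          "lo", "hi", "lod", "pve", "a", "d", "composite", "favorable")]
}

#' Merge QTL records across datasets and environments
#'
#' Records for the same trait and chromosome whose support intervals
#' overlap are merged into one locus (transitively). Each merged locus
#' keeps the peak of its highest-LOD record, the union support
#' interval, a stability count (number of distinct dataset x
#' environment detections) and the member record names.
#'
#' @param records data.frame as returned by [callQtls()] (rows from
#'   several profiles may be rbind-ed).
#' @param stableAt detections needed for the stable flag (default 2).
#' @return data.frame with one row per merged locus: name, trait,
#'   chrom, peak, lo, hi, lod, stability, stable, datasets,
#'   environments, members (member record names) and memberRows
#'   (row indices into `records`).
#' @export
mergeQtls <- function(records, stableAt = 2) {
  if (!nrow(records)) {
    return(data.frame(name = character(), trait = character(),
                      chrom = character(), peak = numeric(),
                      lo = numeric(), hi = numeric(), lod = numeric(),
                      stability = integer(), stable = logical(),
                      datasets = character(), environments = character(),
                      members = character(), memberRows = character(),
                      stringsAsFactors = FALSE))
  }
  records$.row <- seq_len(nrow(records))
  out <- list()
  for (key in unique(paste(records$trait, records$chrom))) {
    rec <- records[paste(records$trait, records$chrom) == key, ,
                   drop = FALSE]
    rec <- rec[order(rec$lo), , drop = FALSE]
    grp <- integer(nrow(rec))
    gid <- 0L
    hiSoFar <- -Inf
    for (i in seq_len(nrow(rec))) {
      if (rec$lo[i] > hiSoFar) {
        gid <- gid + 1L
        hiSoFar <- rec$hi[i]
      } else hiSoFar <- max(hiSoFar, rec$hi[i])
      grp[i] <- gid
    }
    for (g in unique(grp)) {
      m <- rec[grp == g, , drop = FALSE]
      best <- which.max(m$lod)
      out[[length(out) + 1L]] <- data.frame(
        trait = m$trait[1], chrom = m$chrom[1],
        peak = m$peak[best], lo = min(m$lo), hi = max(m$hi),
        lod = m$lod[best],
        stability = length(unique(paste(m$dataset, m$environment))),
        datasets = paste(sort(unique(m$dataset)), collapse = ","),
        environments = paste(sort(unique(m$environment)), collapse = ","),
        members = paste(m$name, collapse = ","),
        memberRows = paste(m$.row, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$chrom, res$peak), , drop = FALSE]
  num <- stats::ave(seq_len(nrow(res)), res$trait, res$chrom,
                    FUN = seq_along)
  res$name <- formatQtlName("single", trait = res$trait,
                            chrom = res$chrom, number = num)
  res$stable <- res$stability >= stableAt
  rownames(res) <- NULL
  res[, c("name", "trait", "chrom", "peak", "lo", "hi", "lod",
          "stability", "stable", "datasets", "environments", "members",
          "memberRows")]
}
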