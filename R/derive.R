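#' Random IF2 pairing design
#'
#' Two rounds (by default) of random permutation pairing of the RILs:
#' within a round every RIL appears exactly once as female and once as
#' male; self-pairings are re-drawn. With 188 RILs and two rounds this
#' yields the 376-hybrid immortalized F2 design.
#'
#' @param rilIds RIL ids (character) or a RIL [GenotypeMatrix-class].
#' @param rounds pairing rounds (default 2).
#' @param seed seed for the permutations.
#' @return A [CrossDesign-class] with the IF2 pairs filled in.
#' @export
makeIf2Design <- function(rilIds, rounds = 2, seed = 1) {
  if (is(rilIds, "GenotypeMatrix")) rilIds <- individuals(rilIds)
  set.seed(seed)
  n <- length(rilIds)
  pairs <- list()
  for (r in seq_len(rounds)) {
    repeat {                              # draw until a derangement
      perm <- sample(n)
      if (!any(perm == seq_len(n))) break
    }
    pairs[[r]] <- data.frame(
      hybrid = sprintf("IF2_%03d", (r - 1L) * n + seq_len(n)),
      female = rilIds,
      male = rilIds[perm],
      stringsAsFactors = FALSE)
  }
  CrossDesign(if2Pairs = do.call(rbind, pairs))
}

#' Design-III backcross assignments
#'
#' Every RIL is crossed once to each recurrent parent, giving the two
#' backcross F1 populations.
#'
#' @param rilIds RIL ids or a RIL [GenotypeMatrix-class].
#' @return A [CrossDesign-class] with the backcross table filled in.
#' @export
makeBackcrossDesign <- function(rilIds) {
  if (is(rilIds, "GenotypeMatrix")) rilIds <- individuals(rilIds)
  n <- length(rilIds)
  CrossDesign(backcrosses = data.frame(
    hybrid = c(sprintf("HSBC_%03d", seq_len(n)),
               sprintf("MARBC_%03d", seq_len(n))),
    ril = rep(rilIds, 2),
    recurrent = rep(c("P1", "P2"), each = n),
    stringsAsFactors = FALSE))
}

#' Deduce hybrid genotypes from RIL genotypes
#'
#' Hybrid genotypes follow marker-wise from the parents: for IF2 pairs
#' AAxAA gives AA, BBxBB gives BB and discordant homozygotes give AB;
#' for a backcross to P1 an AA RIL gives AA and a BB RIL gives AB (the
#' mirror for P2). A missing or residually heterozygous RIL call makes
#' the deduced call missing.
#'
#' @param rils the RIL [GenotypeMatrix-class].
#' @param design a [CrossDesign-class].
#' @param population which hybrid population to deduce: "IF2",
#'   "HSBCF1" (recurrent P1) or "MARBCF1" (recurrent P2).
#' @return A [GenotypeMatrix-class] for the hybrids.
#' @export
deduceHybridGenotypes <- function(rils, design,
                                  population = c("IF2", "HSBCF1",
                                                 "MARBCF1")) {
  population <- match.arg(population)
  calls <- genotypeCalls(rils)
  calls[calls == 1L] <- NA_integer_      # residual hets: no hard call
  if (population == "IF2") {
    pairs <- if2Pairs(design)
    if (!nrow(pairs)) stop("design holds no IF2 pairs")
    miss <- setdiff(c(pairs$female, pairs$male), rownames(calls))
    if (length(miss))
      stop(sprintf("design references unknown RIL id '%s'", miss[1]))
    f <- calls[pairs$female, , drop = FALSE]
    m <- calls[pairs$male, , drop = FALSE]
    out <- (f + m) %/% 2L                # AA+BB -> AB; like -> like
    out[is.na(f) | is.na(m)] <- NA_integer_
    rownames(out) <- pairs$hybrid
  } else {
    bc <- backcrosses(design)
    bc <- bc[bc$recurrent == if (population == "HSBCF1") "P1" else "P2", ,
             drop = FALSE]
    if (!nrow(bc)) stop("design holds no backcrosses for this parent")
    miss <- setdiff(bc$ril, rownames(calls))
    if (length(miss))
      stop(sprintf("design references unknown RIL id '%s'", miss[1]))
    r <- calls[bc$ril, , drop = FALSE]
    out <- if (population == "HSBCF1") r %/% 2L   # AA->AA, BB->AB
           else 2L - (2L - r) %/% 2L              # BB->BB, AA->AB
    rownames(out) <- bc$hybrid
  }
  GenotypeMatrix(out, population, rils@map)
}

## Replicate-averaged parental value per trait x environment.
.parentMeans <- function(pheno) {
  d <- phenoData(pheno)
  aggregate(value ~ trait + environment, d, mean)
}

#' Hybrid-breakdown values of the RILs
#'
#' `HB = RIL - MP` per RIL x trait x environment (replicates averaged),
#' with the mid-parent `MP` from the two original parents in the same
#' environment; the percent variant `HB / MP * 100` is carried
#' alongside. A zero mid-parent gives `NA` percent with a warning.
#'
#' @param rilPheno RIL [PhenotypeTable-class] (kind "raw").
#' @param p1Pheno,p2Pheno parental phenotype tables.
#' @return A [PhenotypeTable-class] of kind "HB".
#' @export
computeHB <- function(rilPheno, p1Pheno, p2Pheno) {
  p1 <- .parentMeans(p1Pheno)
  p2 <- .parentMeans(p2Pheno)
  mp <- merge(p1, p2, by = c("trait", "environment"),
              suffixes = c(".p1", ".p2"))
  mp$mp <- midparent(mp$value.p1, mp$value.p2)
  d <- phenoData(rilPheno)
  rils <- aggregate(value ~ individual + trait + environment, d, mean)
  out <- merge(rils, mp[, c("trait", "environment", "mp")],
               by = c("trait", "environment"), all.x = TRUE)
  out$hb <- out$value - out$mp
  zero <- !is.na(out$mp) & out$mp == 0
  if (any(zero)) warning("mid-parent value of 0; percent set to NA")
  out$percent <- ifelse(zero, NA_real_, 100 * out$hb / out$mp)
  PhenotypeTable(data.frame(individual = out$individual,
                            trait = out$trait,
                            environment = out$environment,
                            replicate = 1L, value = out$hb,
                            percent = out$percent,
                            stringsAsFactors = FALSE),
                 kind = "HB")
}

#' Mid-parent heterosis of hybrids
#'
#' `MPH = F1 - MP` per hybrid x trait x environment: for IF2 hybrids
#' `MP` is the mean of the two parental RILs' values, for backcross
#' hybrids the mean of the RIL and the recurrent parent, each in the
#' matching environment with replicates averaged first. A missing
#' parental phenotype propagates to `NA`.
#'
#' @param hybridPheno hybrid [PhenotypeTable-class] (kind "raw").
#' @param design the [CrossDesign-class] that made the hybrids.
#' @param population hybrid population id.
#' @param rilPheno RIL phenotypes (parents of the hybrids).
#' @param p1Pheno,p2Pheno parental phenotypes (for backcrosses).
#' @return A [PhenotypeTable-class] of kind "MPH".
#' @export
computeMPH <- function(hybridPheno, design,
                       population = c("IF2", "HSBCF1", "MARBCF1"),
                       rilPheno, p1Pheno = NULL, p2Pheno = NULL) {
  population <- match.arg(population)
  rd <- aggregate(value ~ individual + trait + environment,
                  phenoData(rilPheno), mean)
  lookup <- function(ids, trait, env, tab) {
    key <- paste(tab$individual, tab$trait, tab$environment)
    tab$value[match(paste(ids, trait, env), key)]
  }
  hd <- aggregate(value ~ individual + trait + environment,
                  phenoData(hybridPheno), mean)
  if (population == "IF2") {
    pairs <- if2Pairs(design)
    i <- match(hd$individual, pairs$hybrid)
    pa <- lookup(pairs$female[i], hd$trait, hd$environment, rd)
    pb <- lookup(pairs$male[i], hd$trait, hd$environment, rd)
  } else {
    bc <- backcrosses(design)
    bc <- bc[bc$recurrent == if (population == "HSBCF1") "P1" else "P2", ,
             drop = FALSE]
    i <- match(hd$individual, bc$hybrid)
    pa <- lookup(bc$ril[i], hd$trait, hd$environment, rd)
    pp <- if (population == "HSBCF1") p1Pheno else p2Pheno
    if (is.null(pp)) stop("backcross MPH needs the recurrent parent data")
    pm <- .parentMeans(pp)
    pb <- pm$value[match(paste(hd$trait, hd$environment),
                         paste(pm$trait, pm$environment))]
  }
  mp <- midparent(pa, pb)
  mph <- hd$value - mp
  zero <- !is.na(mp) & mp == 0
  if (any(zero)) warning("mid-parent value of 0; percent set to NA")
  PhenotypeTable(data.frame(individual = hd$individual, trait = hd$trait,
                            environment = hd$environment, replicate = 1L,
                            value = mph,
                            percent = ifelse(zero, NA_real_,
                                             100 * mph / mp),
                            stringsAsFactors = FALSE),
                 kind = "MPH")
}

#' Summarize heterosis (or hybrid breakdown) percentages
#'
#' Mean, minimum and maximum of the percent variant per trait x
#' environment, plus the mean over the `topK` highest hybrids of each
#' group.
#'
#' @param values a [PhenotypeTable-class] of kind "HB" or "MPH".
#' @param topK size of the top group (default 20).
#' @return data.frame(trait, environment, n, mean, min, max, topMean).
#' @export
summarizeHeterosis <- function(values, topK = 20) {
  if (!phenoKind(values) %in% c("HB", "MPH"))
    stop("summarizeHeterosis expects an HB or MPH table")
  d <- phenoData(values)
  d <- d[!is.na(d$percent), , drop = FALSE]
  if (!nrow(d)) stop("no non-missing percent values")
  sp <- split(d, paste(d$trait, d$environment))
  out <- do.call(rbind, lapply(sp, function(g) {
    k <- min(topK, nrow(g))
    data.frame(trait = g$trait[1], environment = g$environment[1],
               n = nrow(g), mean = mean(g$percent), min = min(g$percent),
               max = max(g$percent),
               topMean = mean(sort(g$percent, decreasing = TRUE)[seq_len(k)]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trait, out$environment), , drop = FALSE]
}
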