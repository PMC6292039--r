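#' Variance components from a replicated multi-environment trial
#'
#' Method-of-moments estimates from the balanced two-way ANOVA expected
#' mean squares: with `g` genotypes, `e` environments and `r`
#' replicates, `V_e = MS_error`, `V_GE = (MS_GE - MS_error) / r` and
#' `V_G = (MS_G - MS_GE) / (r e)`; negative estimates are truncated to
#' zero. Under balance this coincides with MINQUE(1). The balanced sums
#' of squares are computed directly from cell means (the [stats::aov()]
#' route gives identical mean squares and serves as a cross-check in
#' the test suite). Unbalanced layouts are reduced to individuals with
#' complete genotype-by-environment cells, with a warning; with a
#' single replicate the error variance is confounded with `V_GE` and
#' reported as zero, with a warning.
#'
#' @param pheno a [PhenotypeTable-class] for one population.
#' @param trait trait to analyse (default: the only trait present).
#' @return One-row data.frame: trait, vG, vGE, vE, e, r, H2 (percent,
#'   from [broadSenseH2()]).
#' @export
estimateComponents <- function(pheno, trait = NULL) {
  d <- phenoData(pheno)
  if (is.null(trait)) {
    trait <- unique(d$trait)
    if (length(trait) > 1L) stop("several traits present; pass `trait`")
  }
  d <- d[d$trait == trait & !is.na(d$value), , drop = FALSE]
  e <- length(unique(d$environment))
  if (e < 2L) stop("variance components need >= 2 environments")
  ## complete-case genotypes across environments
  tab <- table(d$individual, d$environment)
  ok <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(ok) < nrow(tab)) {
    warning(sprintf("%d individual(s) dropped (missing environments)",
                    nrow(tab) - length(ok)))
    d <- d[d$individual %in% ok, , drop = FALSE]
  }
  g <- length(ok)
  if (g < 2L) stop("need >= 2 genotypes")
  reps <- table(d$individual, d$environment)
  r <- min(reps)
  if (length(unique(as.vector(reps))) > 1L) {
    warning("unbalanced replicates; using cell means and the minimum ",
            "replicate count")
  }
  cellMean <- tapply(d$value, list(d$individual, d$environment), mean)
  grand <- mean(cellMean)
  gm <- rowMeans(cellMean)
  em <- colMeans(cellMean)
  ssG <- e * r * sum((gm - grand)^2)
  ssE <- g * r * sum((em - grand)^2)
  ssGE <- r * sum((cellMean - outer(gm, rep(1, e)) -
                     outer(rep(1, g), em) + grand)^2)
  msG <- ssG / (g - 1)
  msGE <- ssGE / ((g - 1) * (e - 1))
  if (r > 1) {
    key <- paste(d$individual, d$environment)
    within <- d$value - cellMean[cbind(d$individual, d$environment)]
    dfErr <- sum(table(key) - 1L)
    msErr <- sum(within^2) / dfErr
  } else {
    warning("single replicate: error variance confounded with V_GE; ",
            "reporting V_e = 0")
    msErr <- 0
  }
  vE <- msErr
  vGE <- max((msGE - msErr) / r, 0)
  vG <- max((msG - msGE) / (r * e), 0)
  data.frame(trait = trait, vG = vG, vGE = vGE, vE = vE,
             e = e, r = as.integer(r),
             H2 = broadSenseH2(vG, vGE, vE, e, r),
             stringsAsFactors = FALSE)
}

#' Broad-sense heritability of line means
#'
#' `H2 = 100 * V_G / (V_G + V_GE / e + V_e / (r e))`: the genetic share
#' of the phenotypic variance of genotype means over `e` environments
#' and `r` replicates. A zero denominator returns `NA` with a warning;
#' `V_G = 0` gives 0.
#'
#' @param vG,vGE,vE genetic, genotype-by-environment and error
#'   variance components (trait-squared units; vectorised).
#' @param e,r numbers of environments and replicates.
#' @return Heritability in percent (unrounded).
#' @examples
#' broadSenseH2(0.287, 0, 1.804, e = 4, r = 2)   # 56.00
#' @export
broadSenseH2 <- function(vG, vGE, vE, e, r) {
  den <- vG + vGE / e + vE / (r * e)
  bad <- !is.na(den) & den <= 0 & !(vG == 0)
  out <- ifelse(den > 0, 100 * vG / den, ifelse(vG == 0, 0, NA_real_))
  if (any(is.na(out) & !is.na(den))) warning("zero denominator: H2 is NA")
  out
}
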