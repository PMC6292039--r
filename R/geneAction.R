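#' Additive / dominance effect estimates from genotype-class means
#'
#' The gene-action calculus on genotype-class means:
#' `a = (P1P1 - P2P2) / 2` from the homozygote classes, `d = P1P2 -
#' (P1P1 + P2P2) / 2` from the heterozygote, the backcross composite
#' `(a + d)` as the heterozygote-minus-recurrent-homozygote contrast,
#' and the MPH-scan `d` as the heterozygote-minus-homozygote contrast
#' on MPH values. When a component is available from several sources
#' the IF2 estimates take precedence (the IF2 `|d/a|` is the
#' criterion); otherwise `a` comes from the RILs and `d` from the MPH
#' dataset.
#'
#' @param if2Means named vector `c(AA=, AB=, BB=)` of IF2 class means,
#'   or NULL.
#' @param rilMeans named vector `c(AA=, BB=)` of RIL class means, or
#'   NULL.
#' @param mphMeans named vector `c(het=, hom=)` of MPH class means
#'   (hom = mean over homozygote classes), or NULL.
#' @param bcMeans named vector `c(het=, hom=)` of backcross F1 class
#'   means (hom = recurrent homozygote), or NULL.
#' @return One-row data.frame: a, d, composite, ratio (|d/a|),
#'   aSource, dSource.
#' @examples
#' estimateEffects(if2Means = c(AA = 4, AB = 7, BB = 2))  # a = 1, d = 4
#' @export
estimateEffects <- function(if2Means = NULL, rilMeans = NULL,
                            mphMeans = NULL, bcMeans = NULL) {
  a <- d <- comp <- NA_real_
  aSrc <- dSrc <- NA_character_
  if (!is.null(rilMeans)) {
    a <- unname((rilMeans["AA"] - rilMeans["BB"]) / 2)
    aSrc <- "RIL"
  }
  if (!is.null(mphMeans)) {
    d <- unname(mphMeans["het"] - mphMeans["hom"])
    dSrc <- "MPH"
  }
  if (!is.null(if2Means)) {
    a <- unname((if2Means["AA"] - if2Means["BB"]) / 2)
    d <- unname(if2Means["AB"] - (if2Means["AA"] + if2Means["BB"]) / 2)
    aSrc <- dSrc <- "IF2"
  }
  if (!is.null(bcMeans)) comp <- unname(bcMeans["het"] - bcMeans["hom"])
  if (all(is.na(c(a, d, comp))))
    return(data.frame(a = NA_real_, d = NA_real_, composite = NA_real_,
                      ratio = NA_real_, aSource = NA_character_,
                      dSource = NA_character_, stringsAsFactors = FALSE))
  data.frame(a = a, d = d, composite = comp,
             ratio = .dominanceRatio(a, d),
             aSource = aSrc, dSource = dSrc, stringsAsFactors = FALSE)
}

## |d/a|; a = 0 with d != 0 is taken as infinite dominance degree.
.dominanceRatio <- function(a, d) {
  ifelse(is.na(a) | is.na(d), NA_real_,
         ifelse(a == 0, ifelse(d == 0, 0, Inf), abs(d / a)))
}

## one per-environment verdict on the |d/a| <= 1 boundary
.ratioClass <- function(ratio) ifelse(ratio <= 1, "PD/D", "OD")

.newCall <- function(locus, population, class, ratio, ruleCase,
                     environments = NA_character_) {
  data.frame(locus = locus, population = population, class = class,
             ratio = ratio, ruleCase = ruleCase,
             environments = environments, stringsAsFactors = FALSE)
}

#' Gene-action classification for an IF2-population locus
#'
#' Dominance-degree rules for the immortalized F2: loci with
#' `|d/a| <= 1` are partially or completely dominant (PD/D), loci with
#' `|d/a| > 1` over-dominant (OD), and a locus detectable only in the
#' MPH dataset is OD. Per-environment verdicts that fall on both sides
#' of the `|d/a| = 1` boundary make the locus "uncertain" (a locus
#' detected in a single environment cannot be uncertain).
#'
#' @param est data.frame with one row per environment in which the
#'   locus was detected, columns `environment`, `a`, `d` (the effect
#'   estimates to judge by; IF2-sourced where available).
#' @param detected named logical `c(ril=, if2=, mph=)` detection flags.
#' @param locus locus id carried through to the call.
#' @return One-row data.frame: locus, population, class, ratio,
#'   ruleCase, environments. The class is "none" when the locus was
#'   not detected in the IF2 or its MPH dataset.
#' @export
classifyIf2 <- function(est, detected, locus = NA_character_) {
  det <- c(ril = FALSE, if2 = FALSE, mph = FALSE)
  det[names(detected)] <- detected
  envs <- paste(unique(est$environment), collapse = ",")
  if (!det[["if2"]] && !det[["mph"]])
    return(.newCall(locus, "IF2", "none", NA_real_, "not-detected"))
  if (!det[["if2"]] && det[["mph"]] && !det[["ril"]])
    return(.newCall(locus, "IF2", "OD", NA_real_, "IF2-MPH-only", envs))
  ratio <- .dominanceRatio(est$a, est$d)
  cls <- .ratioClass(ratio)
  if (length(unique(cls)) > 1L)
    return(.newCall(locus, "IF2", "uncertain", median(ratio),
                    "inconsistent-env", envs))
  .newCall(locus, "IF2", cls[1], median(ratio), "IF2-ratio", envs)
}

#' Gene-action classification for a backcross-population locus
#'
#' The backcross decision rules. A locus is over-dominant (OD) when
#' (case 1) it is detected in the backcross F1 and MPH datasets and
#' twice the MPH dominance effect exceeds the backcross composite,
#' `2|d| > |a + d|`; (case 2) it is detected in the RILs and the MPH
#' dataset with `|d/a| > 1` (`a` from the RILs, `d` from MPH); or
#' (case 3) it is detected only in the MPH dataset. A locus detected
#' only in the backcross F1 dataset is additive (A); a locus detected
#' in the RILs and the backcross but without any MPH signal is treated
#' the same way. Loci present in the backcross, MPH and RIL datasets
#' are judged by the case-1 ratio of effects. Everything else is PD/D,
#' and per-environment verdicts on both sides of a boundary give
#' "uncertain".
#'
#' @param est data.frame with one row per environment, columns
#'   `environment`, `a` (RIL), `d` (MPH), `composite` (backcross F1);
#'   NA where a source did not detect the locus.
#' @param detected named logical `c(ril=, bc=, mph=)`.
#' @param population "HSBCF1" or "MARBCF1".
#' @param locus locus id.
#' @return One-row data.frame as in [classifyIf2()].
#' @export
classifyBcf1 <- function(est, detected, population = "HSBCF1",
                         locus = NA_character_) {
  det <- c(ril = FALSE, bc = FALSE, mph = FALSE)
  det[names(detected)] <- detected
  envs <- paste(unique(est$environment), collapse = ",")
  if (!det[["bc"]] && !det[["mph"]])
    return(.newCall(locus, population, "none", NA_real_, "not-detected"))
  if (det[["mph"]] && !det[["bc"]] && !det[["ril"]])
    return(.newCall(locus, population, "OD", NA_real_, "BC-case3", envs))
  if (det[["bc"]] && !det[["mph"]])
    return(.newCall(locus, population, "A", NA_real_, "BC-additive", envs))
  if (det[["bc"]] && det[["mph"]]) {
    ## case 1 (also the all-three rule): 2|d|(MPH) vs |a+d|(BCF1)
    od <- 2 * abs(est$d) > abs(est$composite)
    rule <- if (det[["ril"]]) "BC-all-three" else "BC-case1"
    ratio <- 2 * abs(est$d) / abs(est$composite)
  } else {
    ## ril & mph: case 2 on |d/a|
    ratio <- .dominanceRatio(est$a, est$d)
    od <- ratio > 1
    rule <- "BC-case2"
  }
  cls <- ifelse(od, "OD", "PD/D")
  if (length(unique(cls)) > 1L)
    return(.newCall(locus, population, "uncertain", median(ratio),
                    "inconsistent-env", envs))
  .newCall(locus, population, cls[1], median(ratio), rule, envs)
}

#' Assemble gene-action calls for a hybrid population
#'
#' Matches single-locus QTL records across the relevant datasets (RILs,
#' the hybrid F1 dataset, and its MPH dataset) by support-interval
#' overlap, assembles per-environment effect estimates per matched
#' locus, and classifies each locus with [classifyIf2()] or
#' [classifyBcf1()].
#'
#' @param records data.frame of QTL records ([callQtls()] rows) from
#'   the datasets relevant to `population` (others are ignored).
#' @param population "IF2", "HSBCF1" or "MARBCF1".
#' @return data.frame of gene-action calls, one row per matched locus.
#' @export
classifyGeneActions <- function(records,
                                population = c("IF2", "HSBCF1",
                                               "MARBCF1")) {
  population <- match.arg(population)
  mphDs <- paste0(population, "MPH")
  use <- c("RIL", population, mphDs)
  records <- records[records$dataset %in% use, , drop = FALSE]
  if (!nrow(records))
    return(.newCall(character(0), character(0), character(0),
                    numeric(0), character(0), character(0)))
  merged <- mergeQtls(records)
  out <- list()
  for (i in seq_len(nrow(merged))) {
    ri <- as.integer(strsplit(merged$memberRows[i], ",", fixed = TRUE)[[1]])
    mem <- records[ri, , drop = FALSE]
    det <- unique(mem$dataset)
    if (population == "IF2") {
      flags <- c(ril = "RIL" %in% det, if2 = "IF2" %in% det,
                 mph = mphDs %in% det)
      envRows <- do.call(rbind, lapply(unique(mem$environment), function(e) {
        me <- mem[mem$environment == e, , drop = FALSE]
        if2r <- me[me$dataset == "IF2", , drop = FALSE]
        rilr <- me[me$dataset == "RIL", , drop = FALSE]
        mphr <- me[me$dataset == mphDs, , drop = FALSE]
        a <- if (nrow(if2r)) if2r$a[1]
             else if (nrow(rilr)) rilr$a[1] else NA_real_
        d <- if (nrow(if2r)) if2r$d[1]
             else if (nrow(mphr)) mphr$d[1] else NA_real_
        data.frame(environment = e, a = a, d = d,
                   stringsAsFactors = FALSE)
      }))
      envRows <- envRows[!is.na(envRows$a) & !is.na(envRows$d), ,
                         drop = FALSE]
      cl <- if (nrow(envRows) || !(flags[["if2"]]))
        classifyIf2(envRows, flags, locus = merged$name[i])
      else .newCall(merged$name[i], "IF2", "none", NA_real_,
                    "not-detected")
    } else {
      flags <- c(ril = "RIL" %in% det, bc = population %in% det,
                 mph = mphDs %in% det)
      envRows <- do.call(rbind, lapply(unique(mem$environment), function(e) {
        me <- mem[mem$environment == e, , drop = FALSE]
        rilr <- me[me$dataset == "RIL", , drop = FALSE]
        bcr <- me[me$dataset == population, , drop = FALSE]
        mphr <- me[me$dataset == mphDs, , drop = FALSE]
        data.frame(environment = e,
                   a = if (nrow(rilr)) rilr$a[1] else NA_real_,
                   d = if (nrow(mphr)) mphr$d[1] else NA_real_,
                   composite = if (nrow(bcr)) bcr$composite[1]
                               else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      need <- if (flags[["bc"]] && flags[["mph"]])
        !is.na(envRows$d) & !is.na(envRows$composite)
      else if (flags[["mph"]] && flags[["ril"]])
        !is.na(envRows$a) & !is.na(envRows$d)
      else rep(TRUE, nrow(envRows))
      sub <- envRows[need, , drop = FALSE]
      if (!nrow(sub)) sub <- envRows
      cl <- classifyBcf1(sub, flags, population = population,
                         locus = merged$name[i])
    }
    out[[length(out) + 1L]] <- cl
  }
  res <- do.call(rbind, out)
  res[res$class != "none", , drop = FALSE]
}

#' Per-population gene-action class counts and percentages
#'
#' Counts and percentages of additive (A), partially/completely
#' dominant (PD/D), over-dominant (OD) and uncertain loci per
#' population; percentages are of all classified loci (uncertain
#' included in the denominator), reported to two decimals. Optional
#' pooled groups (e.g. the two backcross populations together) are
#' appended.
#'
#' @param calls data.frame with columns `population` and `class`
#'   (one row per locus).
#' @param pool optional named list of population groupings, e.g.
#'   `list(BCF1 = c("HSBCF1", "MARBCF1"))`.
#' @return data.frame(population, class, count, percent).
#' @export
summarizeClasses <- function(calls, pool = NULL) {
  if (!nrow(calls)) stop("no gene-action calls to summarize")
  lv <- c("A", "PD/D", "OD", "uncertain")
  onePop <- function(name, rows) {
    counts <- table(factor(rows$class, levels = lv))
    data.frame(population = name, class = lv,
               count = as.integer(counts),
               percent = round(100 * as.integer(counts) /
                                 sum(counts), 2),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(unique(calls$population), function(p)
    onePop(p, calls[calls$population == p, , drop = FALSE])))
  for (nm in names(pool)) {
    res <- rbind(res, onePop(nm, calls[calls$population %in% pool[[nm]], ,
                                       drop = FALSE]))
  }
  rownames(res) <- NULL
  res
}
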