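#' @import methods
#' @importFrom stats aggregate anova as.formula coef complete.cases lm
#'   logLik median pf quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

## Population identifiers used throughout. MPH datasets reuse the genotypes
## of the hybrid population they derive from.
.POPULATIONS <- c("RIL", "IF2", "HSBCF1", "MARBCF1", "P1", "P2")
.DATASETS <- c("RIL", "IF2", "HSBCF1", "MARBCF1",
               "IF2MPH", "HSBCF1MPH", "MARBCF1MPH")
.TRAITS <- c("FB", "BN", "BW", "LP", "SY", "LY")

## Integer genotype codes: number of P2-origin alleles.
## 0 = AA (both alleles from P1), 1 = AB, 2 = BB (both from P2).
.GENO_LEVELS <- c("AA", "AB", "BB")

#' GeneticMap: ordered markers with centimorgan positions
#'
#' The coordinate frame for every genome scan: an ordered set of
#' chromosomes, each carrying an ordered list of named markers at
#' non-decreasing cM positions. Markers co-locating at the same position
#' are jittered apart by `jitter` so that scan grids are well defined.
#'
#' @slot chrom character, chromosome id per marker (e.g. "C01").
#' @slot marker character, globally unique marker names.
#' @slot pos numeric, cM position per marker, strictly increasing within
#'   a chromosome after jittering.
#'
#' @examples
#' gm <- GeneticMap(chrom = rep("C01", 3),
#'                  marker = c("m1", "m2", "m3"),
#'                  pos = c(0, 10, 25))
#' chromosomes(gm)
#' @export
setClass("GeneticMap",
         representation(chrom = "character",
                        marker = "character",
                        pos = "numeric"))

setValidity("GeneticMap", function(object) {
  n <- length(object@marker)
  if (length(object@chrom) != n || length(object@pos) != n)
    return("chrom, marker and pos must have equal length")
  if (anyDuplicated(object@marker))
    return("marker names must be globally unique")
  if (any(object@pos < 0))
    return("positions must be non-negative")
  for (cc in unique(object@chrom)) {
    p <- object@pos[object@chrom == cc]
    if (is.unsorted(p, strictly = TRUE))
      return(sprintf("positions on %s are not strictly increasing", cc))
  }
  TRUE
})

#' Construct a GeneticMap
#'
#' Markers are ordered by chromosome (order of first appearance) and
#' position; exact position ties are separated by adding multiples of
#' `jitter`.
#'
#' @param chrom chromosome id per marker.
#' @param marker marker names (unique).
#' @param pos cM positions (non-negative).
#' @param jitter cM added to break exact position ties (default 1e-6).
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(chrom, marker, pos, jitter = 1e-6) {
  marker <- as.character(marker)
  chrom <- rep_len(as.character(chrom), length(marker))
  pos <- as.numeric(pos)
  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- chrom[ord]; marker <- marker[ord]; pos <- pos[ord]
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    p <- pos[i]
    while (any(dup <- duplicated(p))) p[dup] <- p[dup] + jitter
    pos[i] <- sort(p)
  }
  new("GeneticMap", chrom = chrom, marker = marker, pos = pos)
}

#' GenotypeMatrix: individuals-by-markers parental-origin calls
#'
#' Genotypes are parental-origin codes, not nucleotide alleles: code 0
#' ("AA") means both alleles trace to parent P1, 2 ("BB") both to P2,
#' 1 ("AB") heterozygous, `NA` missing. Marker columns follow the map
#' order exactly.
#'
#' @slot calls integer matrix (individuals x markers) with values
#'   0/1/2/NA and dimnames.
#' @slot population one of RIL, IF2, HSBCF1, MARBCF1, P1, P2.
#' @slot map the [GeneticMap-class] the columns refer to.
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix",
                        population = "character",
                        map = "GeneticMap"))

setValidity("GenotypeMatrix", function(object) {
  if (!object@population %in% .POPULATIONS)
    return(sprintf("population must be one of %s",
                   paste(.POPULATIONS, collapse = ", ")))
  if (ncol(object@calls) != length(object@map@marker))
    return("number of call columns differs from the map")
  if (!identical(colnames(object@calls), object@map@marker))
    return("call columns must be named and ordered as the map markers")
  if (is.null(rownames(object@calls)))
    return("calls must carry individual ids as rownames")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) && !all(v %in% 0:2))
    return("calls must be 0 (AA), 1 (AB), 2 (BB) or NA")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer or character matrix; character entries are
#'   translated from "AA"/"AB"/"BB".
#' @param population population id.
#' @param map a [GeneticMap-class].
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(calls, population, map) {
  if (is.character(calls)) {
    dm <- dimnames(calls)
    calls <- matrix(match(calls, .GENO_LEVELS) - 1L, nrow = nrow(calls),
                    dimnames = dm)
  }
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, population = population, map = map)
}

#' PhenotypeTable: long multi-environment phenotype records
#'
#' One record per individual x trait x environment x replicate. The same
#' container carries raw plot values (`kind = "raw"`), hybrid-breakdown
#' values of RILs (`kind = "HB"`) and mid-parent heterosis of hybrids
#' (`kind = "MPH"`); derived kinds hold exactly one value per individual
#' x trait x environment (replicate 1) and carry the percent variant
#' (value / midparent * 100) in a `percent` column.
#'
#' @slot data data.frame with columns individual, trait, environment,
#'   replicate, value (and percent for derived kinds).
#' @slot kind "raw", "HB" or "MPH".
#' @export
setClass("PhenotypeTable",
         representation(data = "data.frame", kind = "character"))

setValidity("PhenotypeTable", function(object) {
  need <- c("individual", "trait", "environment", "replicate", "value")
  if (!all(need %in% names(object@data)))
    return(paste("data must contain columns",
                 paste(need, collapse = ", ")))
  if (!object@kind %in% c("raw", "HB", "MPH"))
    return("kind must be raw, HB or MPH")
  if (object@kind != "raw" && !"percent" %in% names(object@data))
    return("derived kinds must carry a percent column")
  TRUE
})

#' Construct a PhenotypeTable
#' @param data long-format data.frame (individual, trait, environment,
#'   replicate, value, and percent for derived kinds).
#' @param kind "raw", "HB" or "MPH".
#' @return A [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(data, kind = "raw") {
  data$individual <- as.character(data$individual)
  data$trait <- as.character(data$trait)
  data$environment <- as.character(data$environment)
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  rownames(data) <- NULL
  new("PhenotypeTable", data = data, kind = kind)
}

#' CrossDesign: IF2 pairings and backcross assignments
#'
#' Records how hybrids were made from the RILs: pair crosses for the
#' immortalized F2 (two rounds of random permutation pairing, every RIL
#' used once as female and once as male per round) and the two Design-III
#' backcross series in which every RIL is crossed to each recurrent
#' parent.
#'
#' @slot if2Pairs data.frame(hybrid, female, male).
#' @slot backcrosses data.frame(hybrid, ril, recurrent) with recurrent
#'   in {P1, P2}.
#' @export
setClass("CrossDesign",
         representation(if2Pairs = "data.frame",
                        backcrosses = "data.frame"))

setValidity("CrossDesign", function(object) {
  if (nrow(object@if2Pairs)) {
    if (!all(c("hybrid", "female", "male") %in% names(object@if2Pairs)))
      return("if2Pairs needs columns hybrid, female, male")
    if (any(object@if2Pairs$female == object@if2Pairs$male))
      return("IF2 pairs must have distinct members")
  }
  if (nrow(object@backcrosses)) {
    if (!all(c("hybrid", "ril", "recurrent") %in% names(object@backcrosses)))
      return("backcrosses needs columns hybrid, ril, recurrent")
    if (!all(object@backcrosses$recurrent %in% c("P1", "P2")))
      return("recurrent parent must be P1 or P2")
  }
  TRUE
})

#' Construct a CrossDesign
#' @param if2Pairs data.frame(hybrid, female, male); may be empty.
#' @param backcrosses data.frame(hybrid, ril, recurrent); may be empty.
#' @return A [CrossDesign-class].
#' @export
CrossDesign <- function(if2Pairs = data.frame(), backcrosses = data.frame()) {
  new("CrossDesign", if2Pairs = if2Pairs, backcrosses = backcrosses)
}

#' SimConfig: sizes and seed for the forward simulator
#'
#' Defaults mirror the study design the package emulates: 188 RILs at
#' F8 (seven selfing generations after the F1), 376 IF2 hybrids (two
#' permutation rounds), 188 hybrids per backcross, four environments and
#' two replicates.
#'
#' @slot nRil number of recombinant inbred lines.
#' @slot selfingGenerations selfing generations after the F1.
#' @slot environments number of environments.
#' @slot replicates replicates per environment.
#' @slot seed integer seed; fully determines simulator output.
#' @export
setClass("SimConfig",
         representation(nRil = "integer",
                        selfingGenerations = "integer",
                        environments = "integer",
                        replicates = "integer",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nRil < 1L || object@selfingGenerations < 1L ||
      object@environments < 1L || object@replicates < 1L)
    return("all counts must be >= 1")
  TRUE
})

#' Construct a SimConfig
#' @param nRil,selfingGenerations,environments,replicates study sizes.
#' @param seed integer seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nRil = 188, selfingGenerations = 7,
                      environments = 4, replicates = 2, seed = 1) {
  new("SimConfig", nRil = as.integer(nRil),
      selfingGenerations = as.integer(selfingGenerations),
      environments = as.integer(environments),
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' QTLArchitecture: the simulated truth
#'
#' Causal loci with additive (`a`), dominance (`d`) and per-environment
#' additive deviations (QTL-by-environment), digenic interactions with
#' aa/ad/da/dd components, per-trait environment means, and variance
#' parameters. The phenotype model is
#' `value = mu_e + sum(a x + d z + qe_e x) + sum(aa x1 x2 + ad x1 z2 +
#'  da z1 x2 + dd z1 z2) + GE + residual`
#' with `x` in {-1, 0, +1} counting P1-origin alleles and `z = 1` for
#' heterozygotes.
#'
#' @slot loci data.frame(trait, chrom, pos, a, d).
#' @slot qe numeric matrix, one row per locus, one column per
#'   environment: per-environment additive deviations.
#' @slot epistasis data.frame(trait, chrom1, pos1, chrom2, pos2, aa, ad,
#'   da, dd).
#' @slot envMeans numeric matrix, traits x environments.
#' @slot sigmaGE named numeric, per-trait line-by-environment SD.
#' @slot sigmaE named numeric, per-trait residual SD.
#' @slot clamp data.frame(trait, lo, hi) or empty: optional trait
#'   floor/ceiling (off by default).
#' @export
setClass("QTLArchitecture",
         representation(loci = "data.frame",
                        qe = "matrix",
                        epistasis = "data.frame",
                        envMeans = "matrix",
                        sigmaGE = "numeric",
                        sigmaE = "numeric",
                        clamp = "data.frame"))

setValidity("QTLArchitecture", function(object) {
  if (nrow(object@loci) &&
      !all(c("trait", "chrom", "pos", "a", "d") %in% names(object@loci)))
    return("loci needs columns trait, chrom, pos, a, d")
  if (nrow(object@loci) && nrow(object@qe) != nrow(object@loci))
    return("qe must have one row per locus")
  if (nrow(object@epistasis) &&
      !all(c("trait", "chrom1", "pos1", "chrom2", "pos2",
             "aa", "ad", "da", "dd") %in% names(object@epistasis)))
    return("epistasis needs trait, chrom1, pos1, chrom2, pos2, aa, ad, da, dd")
  if (any(object@sigmaGE < 0) || any(object@sigmaE < 0))
    return("variance parameters must be non-negative")
  TRUE
})

#' Construct a QTLArchitecture
#'
#' @param loci data.frame(trait, chrom, pos, a, d); may be empty.
#' @param envMeans traits-by-environments matrix of environment means
#'   (rownames = traits), or a named vector for a single trait.
#' @param qe optional per-environment additive deviations (rows =
#'   loci, cols = environments); default all zero.
#' @param epistasis optional data.frame of digenic interactions.
#' @param sigmaGE,sigmaE per-trait SDs (recycled from scalars).
#' @param clamp optional data.frame(trait, lo, hi).
#' @return A [QTLArchitecture-class].
#' @export
qtlArchitecture <- function(loci = data.frame(), envMeans,
                            qe = NULL, epistasis = data.frame(),
                            sigmaGE = 0, sigmaE = 1,
                            clamp = data.frame()) {
  if (is.vector(envMeans))
    envMeans <- matrix(envMeans, nrow = 1,
                       dimnames = list(unique(c(loci$trait, "trait1"))[1],
                                       names(envMeans)))
  traits <- rownames(envMeans)
  if (is.null(traits)) stop("envMeans must carry trait rownames")
  if (nrow(loci)) loci$trait <- as.character(loci$trait)
  if (is.null(qe))
    qe <- matrix(0, nrow = nrow(loci), ncol = ncol(envMeans))
  if (length(sigmaGE) == 1L) sigmaGE <- setNames(rep(sigmaGE, length(traits)), traits)
  if (length(sigmaE) == 1L) sigmaE <- setNames(rep(sigmaE, length(traits)), traits)
  new("QTLArchitecture", loci = loci, qe = qe, epistasis = epistasis,
      envMeans = envMeans, sigmaGE = sigmaGE, sigmaE = sigmaE,
      clamp = clamp)
}

#' GenotypeProbabilityGrid: flanking-marker genotype probabilities
#'
#' Expected genotype-class probabilities on a cM grid, conditional on the
#' nearest informative flanking markers under the map function (Haldane
#' by default). At a typed marker the probabilities collapse to an
#' indicator. The class set depends on the population: RIL {AA, BB},
#' IF2 {AA, AB, BB}, backcross {recurrent homozygote, AB}.
#'
#' @slot population population the grid was built for.
#' @slot individuals individual ids (rows of the probability matrices).
#' @slot grid data.frame(chrom, pos) of grid positions.
#' @slot pAA,pAB,pBB probability matrices (individuals x grid).
#' @slot markerScores additive marker scores (individuals x markers,
#'   mean-imputed) used for cofactor regression.
#' @slot map the underlying [GeneticMap-class].
#' @slot step grid step in cM.
#' @export
setClass("GenotypeProbabilityGrid",
         representation(population = "character",
                        individuals = "character",
                        grid = "data.frame",
                        pAA = "matrix", pAB = "matrix", pBB = "matrix",
                        markerScores = "matrix",
                        map = "GeneticMap",
                        step = "numeric"))

#' ScanProfile: a genome scan for one dataset x trait x environment
#'
#' @slot dataset one of the seven dataset ids (RIL, IF2, HSBCF1,
#'   MARBCF1, IF2MPH, HSBCF1MPH, MARBCF1MPH).
#' @slot trait,environment what was scanned.
#' @slot grid data.frame(chrom, pos, lod, a, d, composite, pve); effect
#'   columns are NA where the dataset cannot estimate them.
#' @slot cofactors marker names used as background cofactors.
#' @slot threshold genome-wide LOD threshold (NA until set).
#' @slot nPerm permutations behind the threshold.
#' @slot step scan step in cM.
#' @export
setClass("ScanProfile",
         representation(dataset = "character",
                        trait = "character",
                        environment = "character",
                        grid = "data.frame",
                        cofactors = "character",
                        threshold = "numeric",
                        nPerm = "integer",
                        step = "numeric"))

setValidity("ScanProfile", function(object) {
  if (!all(c("chrom", "pos", "lod") %in% names(object@grid)))
    return("grid needs chrom, pos, lod")
  if (any(object@grid$lod < -1e-8, na.rm = TRUE))
    return("LOD must be non-negative")
  TRUE
})
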