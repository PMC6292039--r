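#' Accessors for the core containers
#'
#' Small accessor generics in place of direct slot access:
#' `chromosomes()`, `markerNames()`, `markerPositions()`, `mapTable()`
#' for maps; `genotypeCalls()`, `population()`, `individuals()` for
#' genotype matrices; `phenoData()`, `phenoKind()` for phenotype tables;
#' `if2Pairs()`, `backcrosses()` for cross designs; `scanGrid()`,
#' `scanThreshold()` for scan profiles.
#'
#' @param x the object.
#' @param ... unused.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x, ...) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("markerNames", function(x, ...) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("markerPositions", function(x, ...) standardGeneric("markerPositions"))
#' @rdname accessors
#' @export
setGeneric("mapTable", function(x, ...) standardGeneric("mapTable"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("population", function(x, ...) standardGeneric("population"))
#' @rdname accessors
#' @export
setGeneric("individuals", function(x, ...) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("phenoData", function(x, ...) standardGeneric("phenoData"))
#' @rdname accessors
#' @export
setGeneric("phenoKind", function(x, ...) standardGeneric("phenoKind"))
#' @rdname accessors
#' @export
setGeneric("if2Pairs", function(x, ...) standardGeneric("if2Pairs"))
#' @rdname accessors
#' @export
setGeneric("backcrosses", function(x, ...) standardGeneric("backcrosses"))
#' @rdname accessors
#' @export
setGeneric("scanGrid", function(x, ...) standardGeneric("scanGrid"))
#' @rdname accessors
#' @export
setGeneric("scanThreshold", function(x, ...) standardGeneric("scanThreshold"))
#' @rdname accessors
#' @export
setGeneric("scanThreshold<-", function(x, value) standardGeneric("scanThreshold<-"))

#' @rdname accessors
#' @export
setMethod("chromosomes", "GeneticMap", function(x, ...) unique(x@chrom))
#' @rdname accessors
#' @export
setMethod("markerNames", "GeneticMap", function(x, ...) x@marker)
#' @rdname accessors
#' @export
setMethod("markerPositions", "GeneticMap", function(x, ...)
  setNames(x@pos, x@marker))
#' @rdname accessors
#' @export
setMethod("mapTable", "GeneticMap", function(x, ...)
  data.frame(chrom = x@chrom, marker = x@marker, pos = x@pos,
             stringsAsFactors = FALSE))

#' @rdname accessors
#' @param as "integer" (0/1/2) or "character" ("AA"/"AB"/"BB").
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x, as = "integer", ...) {
  if (identical(as, "character")) {
    out <- matrix(.GENO_LEVELS[x@calls + 1L], nrow = nrow(x@calls),
                  dimnames = dimnames(x@calls))
    return(out)
  }
  x@calls
})
#' @rdname accessors
#' @export
setMethod("population", "GenotypeMatrix", function(x, ...) x@population)
#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeMatrix", function(x, ...) rownames(x@calls))
#' @rdname accessors
#' @export
setMethod("mapTable", "GenotypeMatrix", function(x, ...) mapTable(x@map))

#' @rdname accessors
#' @export
setMethod("phenoData", "PhenotypeTable", function(x, ...) x@data)
#' @rdname accessors
#' @export
setMethod("phenoKind", "PhenotypeTable", function(x, ...) x@kind)
#' @rdname accessors
#' @export
setMethod("individuals", "PhenotypeTable", function(x, ...)
  unique(x@data$individual))

#' @rdname accessors
#' @export
setMethod("if2Pairs", "CrossDesign", function(x, ...) x@if2Pairs)
#' @rdname accessors
#' @export
setMethod("backcrosses", "CrossDesign", function(x, ...) x@backcrosses)

#' @rdname accessors
#' @export
setMethod("scanGrid", "ScanProfile", function(x, ...) x@grid)
#' @rdname accessors
#' @export
setMethod("scanThreshold", "ScanProfile", function(x, ...) x@threshold)
#' @rdname accessors
#' @param value new threshold.
#' @export
setReplaceMethod("scanThreshold", "ScanProfile", function(x, value) {
  x@threshold <- as.numeric(value)
  x
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d markers on %d chromosomes, %.1f cM total\n",
              length(object@marker), length(unique(object@chrom)),
              sum(tapply(object@pos, object@chrom, function(p) diff(range(p))))))
})

setMethod("show", "GenotypeMatrix", function(object) {
  calls <- object@calls
  het <- mean(calls == 1L, na.rm = TRUE)
  cat(sprintf(
    "GenotypeMatrix [%s]: %d individuals x %d markers (%.2f%% AB, %.2f%% NA)\n",
    object@population, nrow(calls), ncol(calls), 100 * het,
    100 * mean(is.na(calls))))
})

setMethod("show", "PhenotypeTable", function(object) {
  d <- object@data
  cat(sprintf(
    "PhenotypeTable [%s]: %d records, %d individuals, traits: %s, envs: %s\n",
    object@kind, nrow(d), length(unique(d$individual)),
    paste(unique(d$trait), collapse = ","),
    paste(unique(d$environment), collapse = ",")))
})

setMethod("show", "CrossDesign", function(object) {
  cat(sprintf("CrossDesign: %d IF2 pairs, %d backcrosses\n",
              nrow(object@if2Pairs), nrow(object@backcrosses)))
})

setMethod("show", "ScanProfile", function(object) {
  cat(sprintf(
    "ScanProfile [%s/%s/%s]: %d positions, max LOD %.2f, threshold %s\n",
    object@dataset, object@trait, object@environment, nrow(object@grid),
    max(object@grid$lod, na.rm = TRUE),
    ifelse(is.na(object@threshold), "unset",
           sprintf("%.2f", object@threshold))))
})

setMethod("show", "QTLArchitecture", function(object) {
  cat(sprintf(
    "QTLArchitecture: %d loci, %d interactions, traits: %s\n",
    nrow(object@loci), nrow(object@epistasis),
    paste(rownames(object@envMeans), collapse = ",")))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d RILs (F%d), %d environments x %d replicates, seed %d\n",
    object@nRil, object@selfingGenerations + 1L, object@environments,
    object@replicates, object@seed))
})

setMethod("show", "GenotypeProbabilityGrid", function(object) {
  cat(sprintf(
    "GenotypeProbabilityGrid [%s]: %d individuals x %d positions (step %g cM)\n",
    object@population, length(object@individuals), nrow(object@grid),
    object@step))
})
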