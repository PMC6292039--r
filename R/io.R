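#' Genotype token dialect for the cross CSV format
#'
#' @param AA,AB,BB,missing tokens used in files for each call.
#' @return A named list usable as the `dialect` argument of
#'   [readCrossCsv()] / [writeCrossCsv()].
#' @export
crossDialect <- function(AA = "A", AB = "H", BB = "B", missing = "-") {
  list(AA = AA, AB = AB, BB = BB, missing = missing)
}

#' Read / write the qtl-cross CSV format
#'
#' A single CSV holds both the map and the genotypes: row 1 marker
#' names, row 2 chromosome ids, row 3 cM positions, then one row per
#' individual (id in column 1, genotype tokens after). Tokens are mapped
#' through `dialect`; unknown tokens become `NA` (their count is
#' reported via a message). Writing then reading recovers the same map
#' and call matrix.
#'
#' @param path file path.
#' @param population population id stored on the returned matrix.
#' @param dialect token mapping, see [crossDialect()].
#' @return `readCrossCsv()`: a list with elements `map`
#'   ([GeneticMap-class]) and `geno` ([GenotypeMatrix-class]).
#' @export
readCrossCsv <- function(path, population = "RIL",
                         dialect = crossDialect()) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(raw) < 4L)
    stop("cross CSV needs marker, chromosome, position rows plus individuals")
  markers <- as.character(raw[1, -1])
  chrom <- as.character(raw[2, -1])
  pos <- suppressWarnings(as.numeric(raw[3, -1]))
  if (anyNA(pos))
    stop(sprintf("non-numeric position on line 3, column %d",
                 which(is.na(pos))[1] + 1L))
  if (anyDuplicated(markers))
    stop(sprintf("duplicated marker name '%s'",
                 markers[duplicated(markers)][1]))
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (is.unsorted(p))
      stop(sprintf("unsorted positions on chromosome %s", cc))
  }
  body <- raw[-(1:3), , drop = FALSE]
  bad <- which(apply(body, 1, function(x) sum(!is.na(x) & x != "")) !=
                 length(markers) + 1L)
  if (length(bad))
    stop(sprintf("ragged genotype row on line %d", bad[1] + 3L))
  ids <- body[[1]]
  tok <- as.matrix(body[, -1, drop = FALSE])
  code <- match(tok, c(dialect$AA, dialect$AB, dialect$BB)) - 1L
  unknown <- is.na(code) & tok != dialect$missing
  if (any(unknown))
    message(sprintf("%d unknown genotype token(s) set to NA", sum(unknown)))
  calls <- matrix(code, nrow = nrow(tok),
                  dimnames = list(ids, markers))
  map <- GeneticMap(chrom = chrom, marker = markers, pos = pos)
  ## map construction may reorder within chromosome; align columns
  calls <- calls[, markerNames(map), drop = FALSE]
  list(map = map, geno = GenotypeMatrix(calls, population, map))
}

#' @rdname readCrossCsv
#' @param geno a [GenotypeMatrix-class] to write.
#' @export
writeCrossCsv <- function(geno, path, dialect = crossDialect()) {
  map <- geno@map
  tok <- c(dialect$AA, dialect$AB, dialect$BB)[geno@calls + 1L]
  tok[is.na(tok)] <- dialect$missing
  tok <- matrix(tok, nrow = nrow(geno@calls))
  out <- rbind(c("id", map@marker),
               c("", map@chrom),
               c("", format(map@pos, digits = 15, trim = TRUE,
                            scientific = FALSE)),
               cbind(rownames(geno@calls), tok))
  write.table(out, path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read / write the long phenotype CSV
#'
#' Columns: individual, trait, environment, replicate, value (plus
#' percent and kind for derived tables).
#'
#' @param path file path.
#' @param kind phenotype kind to stamp on the table if the file carries
#'   no `kind` column.
#' @return A [PhenotypeTable-class].
#' @export
readPhenotypeCsv <- function(path, kind = "raw") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("kind" %in% names(d)) {
    kind <- unique(d$kind)
    if (length(kind) != 1L) stop("phenotype file mixes kinds")
    d$kind <- NULL
  }
  PhenotypeTable(d, kind = kind)
}

#' @rdname readPhenotypeCsv
#' @param pheno a [PhenotypeTable-class] to write.
#' @export
writePhenotypeCsv <- function(pheno, path) {
  d <- phenoData(pheno)
  d$kind <- phenoKind(pheno)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the cross-design CSV
#'
#' Columns hybrid_id, female_parent, male_parent. Backcross rows carry
#' "P1" or "P2" as the male (recurrent) parent.
#'
#' @param path file path.
#' @return A [CrossDesign-class].
#' @export
readCrossDesignCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid_id", "female_parent", "male_parent")
  if (!all(need %in% names(d)))
    stop("cross-design CSV needs hybrid_id, female_parent, male_parent")
  isBC <- d$male_parent %in% c("P1", "P2")
  CrossDesign(
    if2Pairs = data.frame(hybrid = d$hybrid_id[!isBC],
                          female = d$female_parent[!isBC],
                          male = d$male_parent[!isBC],
                          stringsAsFactors = FALSE),
    backcrosses = data.frame(hybrid = d$hybrid_id[isBC],
                             ril = d$female_parent[isBC],
                             recurrent = d$male_parent[isBC],
                             stringsAsFactors = FALSE))
}

#' @rdname readCrossDesignCsv
#' @param design a [CrossDesign-class] to write.
#' @export
writeCrossDesignCsv <- function(design, path) {
  p <- if2Pairs(design); b <- backcrosses(design)
  d <- rbind(
    if (nrow(p)) data.frame(hybrid_id = p$hybrid, female_parent = p$female,
                            male_parent = p$male, stringsAsFactors = FALSE),
    if (nrow(b)) data.frame(hybrid_id = b$hybrid, female_parent = b$ril,
                            male_parent = b$recurrent,
                            stringsAsFactors = FALSE))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
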