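.DATASET_ABBREV <- c(RIL = "R", IF2 = "I", HSBCF1 = "B1", MARBCF1 = "B2",
                     IF2MPH = "IM", HSBCF1MPH = "B1M", MARBCF1MPH = "B2M")

#' Dataset abbreviations used in multi-environment QTL names
#'
#' "R", "I", "B1", "B2" for the RIL, IF2 and two backcross F1 datasets;
#' "IM", "B1M", "B2M" for their MPH datasets.
#'
#' @param dataset dataset id(s), e.g. "HSBCF1MPH".
#' @return Abbreviation(s).
#' @export
datasetAbbrev <- function(dataset) {
  out <- .DATASET_ABBREV[dataset]
  if (anyNA(out)) stop("unknown dataset id")
  unname(out)
}

#' Format and parse QTL names
#'
#' Three grammars: single-locus QTLs `q<trait>-<chrom>-<number>`
#' (e.g. "qBN-C01-2"); multi-environment main-effect QTLs
#' `<abbrev>maq<trait>-<chrom>-<number>` (e.g. "RmaqLP-C07-1");
#' epistatic pairs `<abbrev>meq<trait>-<number>` (e.g. "B1MmeqSY-3").
#' `parseQtlName(formatQtlName(...))` recovers the components.
#'
#' @param type "single", "mqtl" or "eqtl".
#' @param trait trait abbreviation (e.g. "BN").
#' @param chrom chromosome id (e.g. "C01"); unused for "eqtl".
#' @param number QTL (or pair) number.
#' @param dataset dataset id (for "mqtl"/"eqtl").
#' @return `formatQtlName()`: character vector of names.
#'   `parseQtlName()`: data.frame(type, dataset, trait, chrom, number).
#' @examples
#' formatQtlName("single", trait = "BN", chrom = "C01", number = 2)
#' parseQtlName("B1MmaqSY-C14-1")
#' @export
formatQtlName <- function(type = c("single", "mqtl", "eqtl"), trait,
                          chrom = NULL, number, dataset = NULL) {
  type <- match.arg(type)
  switch(type,
         single = sprintf("q%s-%s-%d", trait, chrom, as.integer(number)),
         mqtl = sprintf("%smaq%s-%s-%d", datasetAbbrev(dataset), trait,
                        chrom, as.integer(number)),
         eqtl = sprintf("%smeq%s-%d", datasetAbbrev(dataset), trait,
                        as.integer(number)))
}

#' @rdname formatQtlName
#' @param name name(s) to parse.
#' @export
parseQtlName <- function(name) {
  one <- function(nm) {
    m <- regmatches(nm, regexec("^q([A-Z]+)-(C\\d+)-(\\d+)$", nm))[[1]]
    if (length(m))
      return(data.frame(type = "single", dataset = NA_character_,
                        trait = m[2], chrom = m[3],
                        number = as.integer(m[4]),
                        stringsAsFactors = FALSE))
    ## longest abbreviations first so B1M is not read as B1
    ab <- "(B1M|B2M|IM|B1|B2|R|I)"
    m <- regmatches(nm, regexec(paste0("^", ab,
                                       "maq([A-Z]+)-(C\\d+)-(\\d+)$"),
                                nm))[[1]]
    if (length(m))
      return(data.frame(type = "mqtl",
                        dataset = names(.DATASET_ABBREV)[
                          match(m[2], .DATASET_ABBREV)],
                        trait = m[3], chrom = m[4],
                        number = as.integer(m[5]),
                        stringsAsFactors = FALSE))
    m <- regmatches(nm, regexec(paste0("^", ab, "meq([A-Z]+)-(\\d+)$"),
                                nm))[[1]]
    if (length(m))
      return(data.frame(type = "eqtl",
                        dataset = names(.DATASET_ABBREV)[
                          match(m[2], .DATASET_ABBREV)],
                        trait = m[3], chrom = NA_character_,
                        number = as.integer(m[4]),
                        stringsAsFactors = FALSE))
    stop(sprintf("'%s' does not match any QTL naming grammar", nm))
  }
  do.call(rbind, lapply(name, one))
}
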