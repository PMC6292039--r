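#' LOD curves of a genome scan
#'
#' One panel per chromosome with the LOD profile and, when available,
#' the genome-wide permutation threshold as a dashed line.
#'
#' @param profile a [ScanProfile-class].
#' @param threshold optional LOD threshold to draw (defaults to the
#'   profile's stored one).
#' @return A ggplot object.
#' @export
plotLodProfile <- function(profile, threshold = scanThreshold(profile)) {
  g <- scanGrid(profile)
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  title = sprintf("%s / %s / %s", profile@dataset,
                                  profile@trait, profile@environment)) +
    ggplot2::theme_bw()
  if (!is.na(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed")
  p
}

#' @importFrom ggplot2 .data
NULL
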