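#' Map functions: distance to recombination fraction
#'
#' `haldaneRecomb()` converts a map distance in centimorgans to a
#' recombination fraction under the Haldane (no-interference) model,
#' `r = (1 - exp(-2 d / 100)) / 2`. `kosambiRecomb()` is the Kosambi
#' alternative, `r = tanh(2 d / 100) / 2`. `mapDistance()` inverts
#' Haldane: `d = -50 log(1 - 2 r)`.
#'
#' @param distance map distance in cM, non-negative (vectorised).
#' @param r recombination fraction in [0, 0.5).
#' @return Recombination fraction in [0, 0.5), or cM for
#'   `mapDistance()`.
#' @examples
#' haldaneRecomb(10)         # 0.0906346
#' mapDistance(haldaneRecomb(10))
#' @export
haldaneRecomb <- function(distance) {
  if (any(distance < 0, na.rm = TRUE))
    stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * distance / 100))
}

#' @rdname haldaneRecomb
#' @export
kosambiRecomb <- function(distance) {
  if (any(distance < 0, na.rm = TRUE))
    stop("map distance must be non-negative")
  0.5 * tanh(2 * distance / 100)
}

#' @rdname haldaneRecomb
#' @export
mapDistance <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

.recombFun <- function(mapFunction = c("haldane", "kosambi")) {
  switch(match.arg(mapFunction),
         haldane = haldaneRecomb,
         kosambi = kosambiRecomb)
}

#' Mid-parent value
#'
#' The arithmetic mean of the two parental values, `MP = (P1 + P2) / 2`.
#' `NA` in either argument propagates.
#'
#' @param p1Value,p2Value parental trait values (vectorised).
#' @return The mid-parent value.
#' @examples
#' midparent(653.07, 500.98)  # 577.025
#' @export
midparent <- function(p1Value, p2Value) (p1Value + p2Value) / 2
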