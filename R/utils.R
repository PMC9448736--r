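#' Round half away from zero
#'
#' Rounds to \code{digits} decimals with exact halves moving away from zero,
#' the convention used for printed percentage breakdowns (base R's
#' \code{round} rounds halves to even).
#'
#' @param x numeric vector
#' @param digits decimal places (default 2)
#' @return rounded numeric vector
#' @examples
#' roundHalfUp(c(0.125, -0.125), 2)  # 0.13, -0.13
#' @export
roundHalfUp <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# quantified = present and strictly positive; explicit zeros are treated as
# not quantified because downstream sums of square roots and intensity
# ratios require positive values
.quantified <- function(mat) {
  !is.na(mat) & mat > 0
}

# p-values are never reported as exactly zero (downstream -log10 transforms)
.pfloor <- function(p) {
  pmin(1, pmax(p, .Machine$double.xmin))
}

# composite site key used for matching sites across tables
.siteKeyString <- function(accession, position) {
  paste(accession, position, sep = "@")
}
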