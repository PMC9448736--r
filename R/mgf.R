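#' Scan MGF spectra for isobaric reporter ions
#'
#' Streams a Mascot generic format (MGF) file and, for each
#' \code{BEGIN IONS}/\code{END IONS} block, checks whether at least one peak
#' m/z lies within the reporter-mass tolerance of any reporter-ion mass.
#' Returns the count \code{L} of spectra with a detected reporter and the
#' total spectrum count \code{T} — the ingredients of the labeling
#' efficiency \eqn{E = L/T}.
#'
#' @param path path to an MGF file (or a character vector of its lines via
#'   \code{lines}).
#' @param spec a \linkS4class{ReporterSpec}; default TMT 6-plex with
#'   0.005 Da tolerance.
#' @param lines optional character vector of MGF lines, used instead of
#'   \code{path}.
#' @return named integer vector c(L, T)
#' @seealso [labelingEfficiency()], [tmt6Reporters()]
#' @examples
#' mgf <- c("BEGIN IONS", "TITLE=s1", "126.1277 1500", "END IONS")
#' scanReporterIons(lines = mgf)
#' @export
scanReporterIons <- function(path = NULL, spec = tmt6Reporters(),
                             lines = NULL) {
  if (is.null(lines)) {
    if (is.null(path)) stop("supply a path or lines")
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
  }
  masses <- spec@masses
  tol <- spec@tolerance
  total <- 0L
  labeled <- 0L
  inBlock <- FALSE
  hit <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (inBlock) stop("unterminated spectrum block ", total)
      inBlock <- TRUE
      hit <- FALSE
      total <- total + 1L
      next
    }
    if (ln == "END IONS") {
      if (!inBlock) stop("END IONS outside a spectrum block")
      if (hit) labeled <- labeled + 1L
      inBlock <- FALSE
      next
    }
    if (!inBlock || hit) next
    if (grepl("=", ln, fixed = TRUE)) next  # header key=value line
    mz <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]][1]))
    if (is.na(mz)) next
    if (any(abs(mz - masses) <= tol)) hit <- TRUE
  }
  if (inBlock) stop("unterminated spectrum block ", total)
  c(L = labeled, T = total)
}

#' Isobaric labeling efficiency
#'
#' \eqn{E = L / T}: the fraction of MS/MS spectra carrying at least one
#' detected reporter ion, per labeling batch.
#'
#' @param L spectra with >= 1 reporter detected; may also be the c(L, T)
#'   vector returned by [scanReporterIons()].
#' @param T total spectra.
#' @return efficiency in [0, 1]
#' @examples
#' labelingEfficiency(95, 100)  # 0.95
#' @export
labelingEfficiency <- function(L, T = NULL) {
  if (is.null(T)) {
    if (length(L) != 2L) stop("supply L and T")
    T <- L[["T"]]; L <- L[["L"]]
  }
  if (T <= 0) stop("labeling efficiency undefined: no spectra (T = 0)")
  unname(L / T)
}
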