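#' Summarize quantified phosphosites
#'
#' Counts sites per acceptor residue (pS/pT/pY), per
#' localization-probability class when the profile carries one, and the
#' number annotated in a caller-supplied known-site table, each with its
#' percentage of the total rounded half away from zero to two decimals.
#'
#' @param profile a non-empty \linkS4class{PhosphoProfile}
#' @param knownSites optional data.frame with columns accession, position
#'   (residue ignored) listing known phosphosites.
#' @return a \linkS4class{PSiteSummary}
#' @export
summarizePsites <- function(profile, knownSites = NULL) {
  if (nrow(profile) == 0L) stop("empty profile")
  sk <- siteKeys(profile)
  resCounts <- vapply(c("S", "T", "Y"),
                      function(r) sum(sk$residue == r), integer(1))
  lp <- lpClass(profile)
  classCounts <- if (is.null(lp)) integer(0) else
    vapply(c("I", "II", "III"), function(k) sum(lp == k), integer(1))
  knownCount <- NA_integer_
  if (!is.null(knownSites)) {
    stopifnot(all(c("accession", "position") %in% colnames(knownSites)))
    knownKeys <- .siteKeyString(knownSites$accession, knownSites$position)
    knownCount <- sum(.siteKeyString(sk$accession, sk$position) %in% knownKeys)
  }
  psiteSummaryFromCounts(resCounts, classCounts = classCounts,
                         knownCount = knownCount)
}

#' Build a phosphosite summary from counts
#'
#' Computes the percentage breakdowns directly from residue/class/known
#' counts, e.g. counts read off a published table.
#'
#' @param residueCounts named integer vector over residues S, T, Y (names
#'   required; missing residues counted as 0).
#' @param classCounts optional named integer vector over LP classes I, II, III.
#' @param knownCount optional count of sites annotated in >= 1 known database.
#' @param total total site count; defaults to \code{sum(residueCounts)}.
#' @return a \linkS4class{PSiteSummary}
#' @examples
#' s <- psiteSummaryFromCounts(c(S = 9478, T = 1251, Y = 89))
#' s@residuePct[["S"]]  # 87.61
#' @export
psiteSummaryFromCounts <- function(residueCounts, classCounts = integer(0),
                                   knownCount = NA_integer_, total = NULL) {
  rc <- stats::setNames(integer(3), c("S", "T", "Y"))
  rc[names(residueCounts)] <- as.integer(residueCounts)
  if (is.null(total)) total <- sum(rc)
  total <- as.integer(total)
  pct <- function(k) roundHalfUp(100 * k / total, 2)
  cc <- as.integer(classCounts)
  names(cc) <- names(classCounts)
  new("PSiteSummary",
      total = total,
      residueCounts = rc, residuePct = pct(rc),
      classCounts = cc,
      classPct = if (length(cc)) pct(cc) else numeric(0),
      knownCount = as.integer(knownCount),
      knownPct = if (is.na(knownCount)) NA_real_ else pct(as.integer(knownCount)))
}
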