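#' Restrict a kinase-substrate network to mutually quantified sites
#'
#' Keeps exactly the kinase -> site edges whose site carries a positive
#' intensity in both compared samples. The network channel is defined only
#' on these edges: intensity ratios need positive values on both sides.
#'
#' @param profile a \linkS4class{PhosphoProfile} containing both samples
#' @param sampleA,sampleB sample labels
#' @param network a \linkS4class{KSRNetwork}
#' @return the edge subset as a data.frame (kinase, accession, position,
#'   residue); possibly zero rows.
#' @export
mutualSites <- function(profile, sampleA, sampleB, network) {
  mat <- intensities(profile)
  if (!all(c(sampleA, sampleB) %in% colnames(mat)))
    stop("samples not found in profile: ",
         paste(setdiff(c(sampleA, sampleB), colnames(mat)), collapse = ", "))
  q <- .quantified(mat[, sampleA]) & .quantified(mat[, sampleB])
  sk <- siteKeys(profile)
  okKeys <- .siteKeyString(sk$accession, sk$position)[q]
  et <- edges(network)
  keep <- .siteKeyString(et$accession, et$position) %in% okKeys
  out <- et[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinase network indices (KNI) for one sample pair
#'
#' For every mutually quantified substrate site, the relative intensity
#' ratio RIR = intensity_A / intensity_B splits each kinase's substrate
#' sub-network into an up-regulated part (RIR > 1) and a down-regulated part
#' (RIR < 1). The kinase's up index is the sum of RIRs over up-regulated
#' sites; its down index is the sum of 1/RIR over down-regulated sites.
#' Sites with RIR exactly 1 belong to neither sub-network and are counted in
#' \code{n_tied}. Totals over all kinases feed the chi-squared contingency
#' table of [networkTest()].
#'
#' @inheritParams mutualSites
#' @return a \linkS4class{KNITable}; kinases with no mutually quantified
#'   substrate site are absent (a message reports the empty case).
#' @examples
#' p <- PhosphoProfile(accession = c("P1","P2","P3"), position = 1:3,
#'                     residue = c("S","S","S"),
#'                     intensity = cbind("a:1" = c(2, 4, 1), "b:1" = c(1, 1, 2)))
#' net <- KSRNetwork(kinase = rep("K1", 3), accession = c("P1","P2","P3"),
#'                   position = 1:3, residue = rep("S", 3))
#' kniRecords(computeKni(p, "a:1", "b:1", net))  # kni_up 6, kni_down 2
#' @export
computeKni <- function(profile, sampleA, sampleB, network) {
  et <- mutualSites(profile, sampleA, sampleB, network)
  if (nrow(et) == 0L) {
    message("no mutually quantified ssKSR edge between ", sampleA, " and ",
            sampleB, "; network channel skipped for this pair")
    rec <- data.frame(kinase = character(0), kni_up = numeric(0),
                      kni_down = numeric(0), n_up = integer(0),
                      n_down = integer(0), n_tied = integer(0))
    return(new("KNITable", records = rec, totals = c(up = 0, down = 0),
               sampleA = sampleA, sampleB = sampleB))
  }
  mat <- intensities(profile)
  sk <- siteKeys(profile)
  idx <- match(.siteKeyString(et$accession, et$position),
               .siteKeyString(sk$accession, sk$position))
  rir <- mat[idx, sampleA] / mat[idx, sampleB]
  up <- rir > 1
  dn <- rir < 1
  kin <- sort(unique(et$kinase))
  f <- factor(et$kinase, levels = kin)
  sumBy <- function(v, sel) {
    out <- stats::setNames(numeric(length(kin)), kin)
    if (any(sel)) {
      s <- tapply(v[sel], f[sel], sum)
      out[names(s)[!is.na(s)]] <- s[!is.na(s)]
    }
    out
  }
  rec <- data.frame(
    kinase = kin,
    kni_up = unname(sumBy(rir, up)),
    kni_down = unname(sumBy(1 / rir, dn)),
    n_up = as.integer(sumBy(rep(1, length(rir)), up)),
    n_down = as.integer(sumBy(rep(1, length(rir)), dn)),
    n_tied = as.integer(sumBy(rep(1, length(rir)), !up & !dn)),
    stringsAsFactors = FALSE
  )
  new("KNITable", records = rec,
      totals = c(up = sum(rec$kni_up), down = sum(rec$kni_down)),
      sampleA = sampleA, sampleB = sampleB)
}

#' Network-channel chi-squared test for one kinase
#'
#' Builds the 2x2 table (kinase vs other kinases) x (up- vs down-regulated
#' sub-network): a = KNI_U(i), b = KNI_D(i), c = KNI_U - KNI_U(i),
#' d = KNI_D - KNI_D(i), and applies the Yates-corrected chi-squared test.
#' Direction is +1 when the kinase's share of the up total exceeds its share
#' of the down total.
#'
#' @param kni a \linkS4class{KNITable}
#' @param kinase kinase symbol
#' @param pThreshold significance threshold; 1e-5 usual, 0.01 for lenient
#'   designs.
#' @return one-row data.frame: kinase, a, b, c, d, chi2, pvalue, direction,
#'   significant
#' @export
networkTest <- function(kni, kinase, pThreshold = 1e-5) {
  out <- networkTests(kni, pThreshold)
  row <- out[out$kinase == kinase, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("kinase '", kinase, "' is degenerate or absent in this comparison")
  rownames(row) <- NULL
  row
}

#' Network-channel tests for all kinases of one sample pair
#'
#' Vectorized [networkTest()]; kinases whose up and down indices are both
#' zero (all substrate RIRs tied) are excluded with a message.
#'
#' @inheritParams networkTest
#' @return data.frame, one row per tested kinase
#' @export
networkTests <- function(kni, pThreshold = 1e-5) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  rec <- kniRecords(kni)
  tot <- kniTotals(kni)
  keep <- rec$kni_up > 0 | rec$kni_down > 0
  if (any(!keep))
    message(sum(!keep), " degenerate kinase(s) (all substrate RIRs tied) excluded")
  rec <- rec[keep, , drop = FALSE]
  a <- rec$kni_up
  b <- rec$kni_down
  cc <- tot[["up"]] - a
  dd <- tot[["down"]] - b
  chi <- .yatesChi2Vec(a, b, cc, dd)
  if (nrow(rec) == 0L)
    chi <- data.frame(chi2 = numeric(0), pvalue = numeric(0),
                      degenerate = logical(0))
  shareU <- if (tot[["up"]] > 0) a / tot[["up"]] else rep(0, length(a))
  shareD <- if (tot[["down"]] > 0) b / tot[["down"]] else rep(0, length(b))
  out <- data.frame(
    kinase = rec$kinase,
    a = a, b = b, c = unname(cc), d = unname(dd),
    kni_up = rec$kni_up, kni_down = rec$kni_down,
    n_up = rec$n_up, n_down = rec$n_down, n_tied = rec$n_tied,
    chi2 = chi$chi2, pvalue = chi$pvalue,
    direction = sign(shareU - shareD),
    significant = chi$pvalue < pThreshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
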