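#' Total substrate intensity (TSI) per kinase and sample
#'
#' For each kinase and sample, sums the square-root values (SRVs) of the
#' reporter intensities of the kinase's substrate phosphosites, over the
#' sites quantified (positive) in that sample. A site targeted by several
#' kinases contributes its SRV to each of them, so the per-sample total over
#' all kinases (the column sum) counts shared sites once per targeting
#' kinase. Kinases with no quantified substrate site in a sample carry
#' TSI 0 there.
#'
#' @param profile a \linkS4class{PhosphoProfile}
#' @param network a \linkS4class{KSRNetwork}; edges to sites absent from the
#'   profile are ignored.
#' @param transform intensity transform: \code{"sqrt"} (canonical SRV),
#'   \code{"identity"} or \code{"log"} (log1p; non-canonical, exploratory).
#' @return a \linkS4class{TSITable}
#' @examples
#' p <- PhosphoProfile(accession = c("P1","P2","P3"), position = c(1L,2L,3L),
#'                     residue = c("S","S","T"),
#'                     intensity = matrix(c(4, 9, 25), 3, 1,
#'                                        dimnames = list(NULL, "ctl:1")))
#' net <- KSRNetwork(kinase = rep("K1", 3), accession = c("P1","P2","P3"),
#'                   position = 1:3, residue = c("S","S","T"))
#' tsiMatrix(computeTsi(p, net))  # 2 + 3 + 5 = 10
#' @export
computeTsi <- function(profile, network,
                       transform = c("sqrt", "identity", "log")) {
  transform <- match.arg(transform)
  if (length(kinases(network)) == 0L) stop("network has no kinases")
  inc <- .incidence(profile, network)     # sites x kinases, 0/1 sparse
  mat <- intensities(profile)
  q <- .quantified(mat)
  v <- ifelse(q, mat, 0)
  v <- switch(transform, sqrt = sqrt(v), identity = v, log = log1p(v))
  tsi <- as.matrix(Matrix::crossprod(inc, v))
  nSites <- as.matrix(Matrix::crossprod(inc, q * 1))
  storage.mode(nSites) <- "integer"
  colnames(tsi) <- colnames(mat)
  colnames(nSites) <- colnames(mat)
  new("TSITable", tsi = tsi, nSites = nSites, transform = transform)
}

# sparse site-by-kinase incidence matrix over the profile's sites
.incidence <- function(profile, network) {
  sk <- siteKeys(profile)
  siteKey <- .siteKeyString(sk$accession, sk$position)
  et <- edges(network)
  kin <- kinases(network)
  edgeSite <- match(.siteKeyString(et$accession, et$position), siteKey)
  keep <- !is.na(edgeSite)
  Matrix::sparseMatrix(
    i = edgeSite[keep],
    j = match(et$kinase[keep], kin),
    x = 1,
    dims = c(nrow(sk), length(kin)),
    dimnames = list(NULL, kin)
  )
}

#' Intensity-channel chi-squared test for one kinase
#'
#' Builds the 2x2 contingency table (kinase vs other kinases) x (sample A vs
#' sample B) from total substrate intensities — a = TSI_A(i), b = TSI_B(i),
#' c = TSI_A - TSI_A(i), d = TSI_B - TSI_B(i) — and applies the
#' Yates-corrected chi-squared test. Direction is +1 when the kinase's share
#' of total substrate intensity is higher in A than in B, -1 when lower,
#' 0 on equality.
#'
#' @param tsi a \linkS4class{TSITable}
#' @param kinase kinase symbol (a row of the table)
#' @param sampleA,sampleB sample labels (columns of the table)
#' @param pThreshold significance threshold; 1e-5 is the usual choice, 0.05
#'   for lenient designs.
#' @return one-row data.frame: kinase, a, b, c, d, chi2, pvalue, direction,
#'   significant
#' @export
intensityTest <- function(tsi, kinase, sampleA, sampleB, pThreshold = 1e-5) {
  out <- intensityTests(tsi, sampleA, sampleB, pThreshold)
  row <- out[out$kinase == kinase, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("kinase '", kinase,
         "' has no quantified substrate site in either sample")
  rownames(row) <- NULL
  row
}

#' Intensity-channel tests for all kinases of one sample pair
#'
#' Vectorized [intensityTest()] over every kinase with at least one
#' quantified substrate site in sample A or B; kinases with none in either
#' sample are excluded with a message.
#'
#' @inheritParams intensityTest
#' @return data.frame, one row per tested kinase
#' @export
intensityTests <- function(tsi, sampleA, sampleB, pThreshold = 1e-5) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  m <- tsiMatrix(tsi)
  if (!all(c(sampleA, sampleB) %in% colnames(m)))
    stop("samples not found in TSI table: ",
         paste(setdiff(c(sampleA, sampleB), colnames(m)), collapse = ", "))
  nA <- tsi@nSites[, sampleA]
  nB <- tsi@nSites[, sampleB]
  tested <- nA > 0L | nB > 0L
  if (any(!tested))
    message(sum(!tested), " kinase(s) with no quantified substrate site in ",
            sampleA, " or ", sampleB, " excluded")
  a <- m[tested, sampleA]
  b <- m[tested, sampleB]
  totA <- sum(m[, sampleA]); totB <- sum(m[, sampleB])
  cc <- totA - a
  dd <- totB - b
  chi <- .yatesChi2Vec(a, b, cc, dd)
  shareA <- if (totA > 0) a / totA else rep(0, length(a))
  shareB <- if (totB > 0) b / totB else rep(0, length(b))
  out <- data.frame(
    kinase = rownames(m)[tested],
    a = unname(a), b = unname(b), c = unname(cc), d = unname(dd),
    chi2 = chi$chi2, pvalue = chi$pvalue,
    direction = sign(shareA - shareB),
    significant = chi$pvalue < pThreshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
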