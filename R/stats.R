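#' Yates-corrected chi-squared test on a 2x2 contingency table
#'
#' Computes the continuity-corrected chi-squared statistic
#' \deqn{\chi^2 = \frac{T\,[\max(0, |ad - bc| - T/2)]^2}{T_i T_o T_A T_B}}
#' where \eqn{T_i = a+b}, \eqn{T_o = c+d}, \eqn{T_A = a+c}, \eqn{T_B = b+d}
#' and \eqn{T} is the grand total, with the upper-tail p-value from the
#' chi-squared distribution on 1 degree of freedom. Cells may be real-valued
#' (the evidence channels fill them with sums of square-rooted intensities or
#' of intensity ratios). A table with any zero margin is degenerate: the
#' statistic is 0 and the p-value 1, never an error, so batch runs over many
#' kinases never abort.
#'
#' @param a,b,c,d nonnegative cells; row 1 = the kinase of interest,
#'   row 2 = all other kinases; columns = the two compared samples (or the
#'   up/down sub-networks). \code{a} may also be a 2x2 matrix.
#' @return list with elements \code{chi2}, \code{pvalue} (floored at the
#'   smallest positive double, and exactly 1 when \code{chi2 == 0}) and
#'   \code{degenerate}.
#' @examples
#' yatesChi2(10, 0, 0, 10)$chi2   # 16.2
#' yatesChi2(5, 5, 5, 5)$pvalue   # 1
#' @export
yatesChi2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  if (any(c(a, b, c, d) < 0)) stop("contingency cells must be nonnegative")
  res <- .yatesChi2Vec(a, b, c, d)
  list(chi2 = res$chi2, pvalue = res$pvalue, degenerate = res$degenerate)
}

# vectorized over kinases; used by the evidence channels
.yatesChi2Vec <- function(a, b, c, d) {
  Ti <- a + b; To <- c + d; TA <- a + c; TB <- b + d
  Tt <- Ti + To
  degenerate <- Ti == 0 | To == 0 | TA == 0 | TB == 0 | Tt == 0
  num <- pmax(0, abs(a * d - b * c) - Tt / 2)^2 * Tt
  den <- Ti * To * TA * TB
  chi2 <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, den))
  pvalue <- ifelse(chi2 == 0, 1,
                   .pfloor(stats::pchisq(chi2, df = 1, lower.tail = FALSE)))
  data.frame(chi2 = chi2, pvalue = pvalue, degenerate = degenerate)
}

#' Hypergeometric over/under-representation test
#'
#' Given a universe of \code{N} annotated genes of which \code{M} carry a
#' term, and a query of \code{n} genes of which \code{m} carry it, computes
#' the enrichment ratio \eqn{E = (m/M) / (n/N)} and a one-sided
#' hypergeometric p-value: the upper tail \eqn{\sum_{m'=m}^{n}} when
#' \eqn{E \ge 1} (over-representation) and the lower tail
#' \eqn{\sum_{m'=0}^{m}} when \eqn{E < 1} (under-representation). Terms of
#' the sum that are combinatorially impossible (\eqn{m' > M} or
#' \eqn{n - m' > N - M}) contribute zero mass.
#'
#' @param N universe size; @param n query size; @param M genes with the term;
#' @param m query genes with the term.
#' @return list with \code{e_ratio}, \code{pvalue}, \code{side}
#'   ("over" or "under") and the four counts.
#' @examples
#' hypergeomEnrichment(N = 10, n = 5, M = 4, m = 4)  # e_ratio 2, p = 6/252
#' @export
hypergeomEnrichment <- function(N, n, M, m) {
  if (M == 0 || n == 0)
    stop("enrichment ratio undefined: M = 0 or n = 0")
  if (m > min(n, M) || n > N || M > N)
    stop("counts violate m <= min(n, M), n <= N, M <= N")
  e_ratio <- (m / M) / (n / N)
  if (e_ratio >= 1) {
    p <- sum(stats::dhyper(m:n, M, N - M, n))
    side <- "over"
  } else {
    p <- sum(stats::dhyper(0:m, M, N - M, n))
    side <- "under"
  }
  list(e_ratio = e_ratio, pvalue = .pfloor(min(1, p)), side = side,
       N = N, n = n, M = M, m = m)
}

#' Term enrichment over an annotation table
#'
#' Runs [hypergeomEnrichment()] for every term of a gene-to-term annotation
#' table against a query gene set. The universe is the set of annotated
#' genes (optionally intersected with a caller-supplied universe); the query
#' is restricted to annotated genes.
#'
#' @param genes character vector of query gene symbols.
#' @param annotations data.frame with columns gene, term_id, term_name.
#' @param universe optional character vector restricting the annotated
#'   universe.
#' @return data.frame, one row per term, with counts, e_ratio, pvalue, side
#'   and a Benjamini-Hochberg adjusted p-value, ordered by pvalue.
#' @export
enrichTerms <- function(genes, annotations, universe = NULL) {
  stopifnot(all(c("gene", "term_id", "term_name") %in% colnames(annotations)))
  ann <- annotations
  ann$gene <- toupper(trimws(ann$gene))
  if (!is.null(universe))
    ann <- ann[ann$gene %in% toupper(trimws(universe)), , drop = FALSE]
  genes <- unique(toupper(trimws(genes)))
  allGenes <- unique(ann$gene)
  N <- length(allGenes)
  query <- intersect(genes, allGenes)
  n <- length(query)
  if (n == 0L) stop("no query gene carries an annotation")
  terms <- unique(ann[, c("term_id", "term_name")])
  out <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- unique(ann$gene[ann$term_id == terms$term_id[i]])
    M <- length(tg)
    m <- length(intersect(query, tg))
    h <- hypergeomEnrichment(N, n, M, m)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               N = N, n = n, M = M, m = m, e_ratio = h$e_ratio,
               pvalue = h$pvalue, side = h$side, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC for a scored binary classification
#'
#' Sweeps the distinct score thresholds (higher score = more confident
#' positive) to build the ROC curve of (1 - specificity, sensitivity)
#' points, and computes the AUC as the tie-corrected rank statistic: the
#' probability that a random positive outscores a random negative, ties
#' counted one half. The two agree (the threshold sweep traces diagonal
#' segments through tied blocks whose trapezoidal area is the tie-corrected
#' probability).
#'
#' @param scores numeric vector.
#' @param labels logical (TRUE = positive) or any 2-level vector coercible
#'   via \code{labels == positive}.
#' @param positive the level regarded as positive when \code{labels} is not
#'   logical.
#' @return a \linkS4class{ROCResult}
#' @examples
#' auc(rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)))  # 0.75
#' @export
rocAuc <- function(scores, labels, positive = TRUE) {
  if (!is.logical(labels)) labels <- labels == positive
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L) stop("no positive items in labels")
  if (nNeg == 0L) stop("no negative items in labels")
  r <- rank(scores)  # average ranks handle ties
  aucVal <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / nNeg, tpr = sum(pred & labels) / nPos)
  }, numeric(2))
  pts <- rbind(c(fpr = 0, tpr = 0), t(pts))
  new("ROCResult", points = pts, auc = aucVal)
}

#' Sensitivity and specificity from confusion counts
#'
#' \eqn{Sn = TP / (TP + FN)} and \eqn{Sp = TN / (TN + FP)}.
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return named numeric c(Sn, Sp)
#' @examples
#' snSp(8, 2, 9, 1)  # Sn 0.8, Sp 0.9
#' @export
snSp <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0) stop("empty positive class: TP + FN = 0")
  if (tn + fp <= 0) stop("empty negative class: TN + FP = 0")
  c(Sn = tp / (tp + fn), Sp = tn / (tn + fp))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant sequence has no
#' defined rank correlation; the result is \code{NA} so callers can exclude
#' such pairs from averages.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return correlation in [-1, 1], or NA for a constant input.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}
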