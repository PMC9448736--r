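#' Benchmark a kinase ranking against known regulators
#'
#' Scores a \linkS4class{CKIResult} (or any kinase -> score table) against a
#' truth set of known regulatory kinases. The evaluation universe defaults
#' to the kinases of the result; pass the kinases carrying at least one
#' predicted substrate relation (e.g. \code{kinases(network)}) to reproduce
#' the standard negative-set definition, where every non-truth kinase with
#' at least one ssKSR is a negative. The confusion matrix is taken at the
#' design's hit-count threshold (kinases flagged \code{passes} are the
#' predicted positives); the ROC uses the hit count as the score, ties
#' handled with the rank-based correction.
#'
#' @param result a \linkS4class{CKIResult}, or a prediction data.frame with
#'   columns kinase, hits, passes (e.g. a re-read predictions.tsv)
#' @param truth character vector of known regulatory kinase symbols
#' @param universe optional kinase universe; defaults to the kinases of the
#'   result table. Universe kinases missing from the table score 0 hits and
#'   are not predicted.
#' @return list with elements \code{universe}, \code{counts} (TP, FP, FN,
#'   TN), \code{fractions} (row-normalized confusion matrix), \code{sn},
#'   \code{sp} and \code{roc} (a \linkS4class{ROCResult})
#' @export
benchmarkRanking <- function(result, truth, universe = NULL) {
  tb <- if (is.data.frame(result)) result else ckiTable(result)
  stopifnot(all(c("kinase", "hits", "passes") %in% colnames(tb)))
  truth <- unique(toupper(truth))
  if (is.null(universe)) universe <- tb$kinase
  universe <- unique(toupper(universe))
  pos <- intersect(truth, universe)
  if (length(pos) == 0L) stop("no truth kinase in the universe")
  if (length(pos) == length(universe)) stop("no negative kinase in the universe")
  idx <- match(universe, tb$kinase)
  hits <- ifelse(is.na(idx), 0L, tb$hits[idx])
  passes <- ifelse(is.na(idx), FALSE, tb$passes[idx])
  isPos <- universe %in% pos
  tp <- sum(passes & isPos); fp <- sum(passes & !isPos)
  fn <- sum(!passes & isPos); tn <- sum(!passes & !isPos)
  ss <- snSp(tp, fn, tn, fp)
  fractions <- matrix(
    c(if (tp + fp > 0) c(tp, fp) / (tp + fp) else c(NA, NA),
      if (fn + tn > 0) c(fn, tn) / (fn + tn) else c(NA, NA)),
    nrow = 2, byrow = TRUE,
    dimnames = list(predicted = c("known", "unknown"),
                    actual = c("known", "unknown")))
  roc <- rocAuc(hits, isPos)
  list(universe = universe,
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       fractions = fractions,
       sn = unname(ss["Sn"]), sp = unname(ss["Sp"]),
       roc = roc)
}

#' Write benchmark tables
#'
#' Writes \code{benchmark.tsv} (confusion counts and fractions, Sn, Sp, AUC)
#' and \code{roc_points.tsv} (Sn and 1-Sp per score threshold) into a
#' directory.
#'
#' @param bench result of [benchmarkRanking()]
#' @param dir output directory (created if needed)
#' @return invisibly, the two file paths
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "benchmark.tsv")
  df <- data.frame(
    TP = bench$counts[["TP"]], FP = bench$counts[["FP"]],
    FN = bench$counts[["FN"]], TN = bench$counts[["TN"]],
    frac_tp = bench$fractions["known", "known"],
    frac_fp = bench$fractions["known", "unknown"],
    frac_fn = bench$fractions["unknown", "known"],
    frac_tn = bench$fractions["unknown", "unknown"],
    Sn = bench$sn, Sp = bench$sp, AUC = auc(bench$roc))
  utils::write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "roc_points.tsv")
  pts <- rocPoints(bench$roc)
  utils::write.table(
    data.frame(one_minus_sp = pts[, "fpr"], sn = pts[, "tpr"]),
    f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Kinase-expression vs substrate-intensity correlation
#'
#' For every kinase -> site edge of the network, the Spearman correlation
#' between the kinase's mRNA expression and the substrate site's intensity
#' across the samples shared by the two data sets (pairwise-complete, at
#' least \code{minShared} pairs). Edges with a constant series are skipped
#' and counted.
#'
#' @param expression numeric matrix, genes x samples (rownames = symbols).
#' @param profile a \linkS4class{PhosphoProfile}
#' @param network a \linkS4class{KSRNetwork}
#' @param minShared minimum complete sample pairs per edge (default 3).
#' @return list with \code{edges} (per-edge data.frame with rho),
#'   \code{average} (mean over defined rho), \code{n_skipped}
#' @export
ksrExpressionCorrelation <- function(expression, profile, network,
                                     minShared = 3) {
  shared <- intersect(colnames(expression), colnames(profile))
  if (length(shared) < minShared)
    stop("fewer than ", minShared, " shared samples between expression and profile")
  mat <- intensities(profile)[, shared, drop = FALSE]
  expr <- expression[, shared, drop = FALSE]
  rownames(expr) <- toupper(rownames(expr))
  sk <- siteKeys(profile)
  skey <- .siteKeyString(sk$accession, sk$position)
  et <- edges(network)
  rho <- rep(NA_real_, nrow(et))
  nShared <- integer(nrow(et))
  skipped <- 0L
  for (i in seq_len(nrow(et))) {
    g <- et$kinase[i]
    s <- match(.siteKeyString(et$accession[i], et$position[i]), skey)
    if (is.na(s) || !g %in% rownames(expr)) next
    x <- expr[g, ]
    y <- mat[s, ]
    ok <- is.finite(x) & is.finite(y)
    nShared[i] <- sum(ok)
    if (nShared[i] < minShared) next
    r <- spearmanRho(x[ok], y[ok])
    if (is.na(r)) skipped <- skipped + 1L else rho[i] <- r
  }
  edgesOut <- cbind(et, rho = rho, n_shared = nShared)
  list(edges = edgesOut,
       average = mean(rho, na.rm = TRUE),
       n_skipped = skipped)
}

#' Sample-by-sample Spearman correlation matrix
#'
#' Pairwise Spearman correlations between the sample columns of a
#' feature x sample matrix, using pairwise-complete features. Pairs with
#' fewer than three complete features get \code{NA} with a warning.
#'
#' @param mat numeric matrix, features x samples.
#' @return symmetric correlation matrix with unit diagonal
#' @export
sampleCorrelation <- function(mat) {
  if (nrow(mat) < 3L) stop("need at least 3 features")
  ns <- ncol(mat)
  out <- diag(1, ns)
  dimnames(out) <- list(colnames(mat), colnames(mat))
  flagged <- FALSE
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      ok <- is.finite(mat[, i]) & is.finite(mat[, j])
      if (sum(ok) < 3L) {
        out[i, j] <- out[j, i] <- NA_real_
        flagged <- TRUE
      } else {
        out[i, j] <- out[j, i] <-
          stats::cor(mat[ok, i], mat[ok, j], method = "spearman")
      }
    }
  }
  if (flagged)
    warning("sample pair(s) with fewer than 3 complete features set to NA")
  out
}
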