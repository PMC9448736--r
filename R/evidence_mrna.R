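#' Identify differentially expressed protein kinases (DEPKs)
#'
#' The transcriptomic evidence channel: rows of a differential-expression
#' table whose gene is in the kinase catalog and whose p-value falls below
#' the threshold become evidence hits, one per (kinase, comparison).
#' Direction is the sign of the log2 fold change (first condition over
#' second); a significant gene with log2fc exactly 0 is still a hit with
#' direction 0, since hits are counted without a direction requirement.
#'
#' @param de data.frame with columns gene, log2fc, pvalue, comparison_id
#'   (see [readDeTable()]).
#' @param catalog a \linkS4class{KinaseCatalog}
#' @param pThreshold significance threshold in (0, 1); 0.01 is the usual
#'   choice, with 0.0001 for designs needing more stringency.
#' @return data.frame of evidence hits: kinase, comparison_id, evidence
#'   ("mrna"), pvalue, direction. May have zero rows.
#' @export
identifyDepks <- function(de, catalog, pThreshold = 0.01) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  stopifnot(all(c("gene", "log2fc", "pvalue", "comparison_id") %in% colnames(de)))
  sel <- de[toupper(de$gene) %in% kinases(catalog) & de$pvalue < pThreshold, ,
            drop = FALSE]
  out <- data.frame(
    kinase = toupper(sel$gene),
    comparison_id = sel$comparison_id,
    evidence = rep("mrna", nrow(sel)),
    pvalue = sel$pvalue,
    direction = sign(sel$log2fc),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# all catalog kinases present in a DE comparison (tested, hit or not),
# with their p-values and directions; used by the hit-count integration
.mrnaTested <- function(de, catalog, comparisonId) {
  sel <- de[de$comparison_id == comparisonId &
              toupper(de$gene) %in% kinases(catalog), , drop = FALSE]
  data.frame(kinase = toupper(sel$gene),
             pvalue = sel$pvalue,
             direction = sign(sel$log2fc),
             stringsAsFactors = FALSE)
}
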