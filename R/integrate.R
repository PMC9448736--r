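#' Enumerate the pairwise-comparison design
#'
#' Builds the evidence units of a run. Each channel runs either at
#' \emph{condition} level (one unit per condition pair) or at
#' \emph{replicate} level (one unit for every cross-condition replicate
#' pair, the full Cartesian product). Condition pairs are oriented
#' later-vs-earlier in the order the conditions are supplied, so with
#' conditions \code{c(control, treated)} the unit compares treated against
#' control. A classic two-condition design with three replicates per
#' condition, condition-level mRNA and replicate-level phospho channels
#' yields 1 + 3x3 + 3x3 = 19 units.
#'
#' @param conditions named list: condition -> character vector of sample
#'   labels (the profile's column names). For condition-level phospho
#'   channels each condition must hold exactly one sample.
#' @param channels named character vector mapping each channel
#'   ("mrna", "intensity", "network") to "condition" or "replicate".
#'   Channels may be omitted to exclude them.
#' @param thresholds named numeric p-value thresholds per channel.
#' @param minHits hit-count threshold for calling a kinase central.
#' @return a \linkS4class{CKIDesign}
#' @examples
#' d <- enumerateUnits(
#'   conditions = list(control = paste0("control:", 1:3),
#'                     treated = paste0("treated:", 1:3)),
#'   channels = c(mrna = "condition", intensity = "replicate",
#'                network = "replicate"),
#'   thresholds = c(mrna = 0.01, intensity = 1e-5, network = 1e-5),
#'   minHits = 14)
#' nrow(designUnits(d))  # 19
#' @export
enumerateUnits <- function(conditions, channels, thresholds, minHits) {
  if (length(conditions) < 2L) stop("need at least two conditions")
  condNames <- names(conditions)
  if (is.null(condNames) || any(!nzchar(condNames)))
    stop("conditions must be a named list")
  badCh <- setdiff(names(channels), c("mrna", "intensity", "network"))
  if (length(badCh)) stop("unknown channel(s): ", paste(badCh, collapse = ", "))
  pairIdx <- utils::combn(length(conditions), 2L)
  units <- list()
  for (ch in names(channels)) {
    level <- channels[[ch]]
    if (!level %in% c("condition", "replicate"))
      stop("channel level must be 'condition' or 'replicate'")
    for (p in seq_len(ncol(pairIdx))) {
      i <- pairIdx[1L, p]; j <- pairIdx[2L, p]
      condA <- condNames[j]; condB <- condNames[i]  # later vs earlier
      if (level == "condition") {
        if (ch == "mrna") {
          sA <- condA; sB <- condB
        } else {
          if (length(conditions[[condA]]) != 1L ||
              length(conditions[[condB]]) != 1L)
            stop("condition-level ", ch, " channel requires one sample per ",
                 "condition; pool or switch to replicate level")
          sA <- conditions[[condA]]; sB <- conditions[[condB]]
        }
        units[[length(units) + 1L]] <- data.frame(
          evidence = ch, sampleA = sA, sampleB = sB,
          stringsAsFactors = FALSE)
      } else {
        grid <- expand.grid(sampleA = conditions[[condA]],
                            sampleB = conditions[[condB]],
                            stringsAsFactors = FALSE)
        grid$evidence <- ch
        units[[length(units) + 1L]] <- grid[, c("evidence", "sampleA", "sampleB")]
      }
    }
  }
  u <- do.call(rbind, units)
  u$comparison_id <- paste0(u$sampleA, "_vs_", u$sampleB)
  u$unit_id <- paste(u$evidence, u$comparison_id, sep = ":")
  u <- u[, c("unit_id", "evidence", "sampleA", "sampleB", "comparison_id")]
  rownames(u) <- NULL
  new("CKIDesign", units = u, thresholds = thresholds,
      minHits = as.integer(minHits))
}

#' Preset design templates
#'
#' Channel levels, thresholds and hit-count cutoffs for the four study
#' archetypes:
#' \describe{
#'   \item{dox}{condition-level mRNA (p < 0.01), replicate-level intensity
#'     and network (both p < 1e-5); 19 units with 3v3 replicates; >= 14 hits.}
#'   \item{genistein}{all replicate-level; stringent mRNA p < 1e-4, lenient
#'     intensity p < 0.05 and network p < 0.01; 12 units with 2v2; >= 6 hits.}
#'   \item{maturation}{all replicate-level; p < 0.01 / 1e-5 / 1e-5;
#'     27 units with 3v3; >= 15 hits.}
#'   \item{reprogramming}{all condition-level over three conditions;
#'     p < 0.01 / 1e-5 / 0.01; 9 units; >= 5 hits.}
#' }
#'
#' @param name preset name
#' @return list with elements channels, thresholds, minHits
#' @export
ckiPreset <- function(name = c("dox", "genistein", "maturation",
                               "reprogramming")) {
  name <- match.arg(name)
  switch(name,
    dox = list(
      channels = c(mrna = "condition", intensity = "replicate",
                   network = "replicate"),
      thresholds = c(mrna = 0.01, intensity = 1e-5, network = 1e-5),
      minHits = 14L),
    genistein = list(
      channels = c(mrna = "replicate", intensity = "replicate",
                   network = "replicate"),
      thresholds = c(mrna = 1e-4, intensity = 0.05, network = 0.01),
      minHits = 6L),
    maturation = list(
      channels = c(mrna = "replicate", intensity = "replicate",
                   network = "replicate"),
      thresholds = c(mrna = 0.01, intensity = 1e-5, network = 1e-5),
      minHits = 15L),
    reprogramming = list(
      channels = c(mrna = "condition", intensity = "condition",
                   network = "condition"),
      thresholds = c(mrna = 0.01, intensity = 1e-5, network = 0.01),
      minHits = 5L)
  )
}

#' Count positive hits per kinase and rank
#'
#' Pools per-unit test results over all evidence channels, counts each
#' kinase's significant units (its positive hits), flags kinases reaching
#' the design's hit-count threshold, and ranks by hit count with the
#' -log10 p sum and the symbol as tie-breaks. A kinase never tested in any
#' unit is absent from the output. Duplicate results for one (kinase, unit)
#' are an error.
#'
#' @param results data.frame with columns kinase, unit_id, evidence, pvalue,
#'   direction, significant — one row per kinase tested in a unit.
#' @param design a \linkS4class{CKIDesign}; unit ids in \code{results} must
#'   belong to it.
#' @return a \linkS4class{CKIResult}
#' @export
countHits <- function(results, design) {
  need <- c("kinase", "unit_id", "evidence", "pvalue", "direction",
            "significant")
  stopifnot(all(need %in% colnames(results)))
  u <- designUnits(design)
  extra <- setdiff(unique(results$unit_id), u$unit_id)
  if (length(extra))
    stop("results contain units not in the design: ",
         paste(utils::head(extra, 3), collapse = ", "))
  if (anyDuplicated(results[, c("kinase", "unit_id")]))
    stop("duplicate result for one (kinase, unit)")
  kin <- sort(unique(results$kinase))
  f <- factor(results$kinase, levels = kin)
  hitsBy <- function(sel) {
    v <- tapply(results$significant[sel], f[sel], sum)
    out <- stats::setNames(integer(length(kin)), kin)
    out[names(v)[!is.na(v)]] <- as.integer(v[!is.na(v)])
    out
  }
  all <- rep(TRUE, nrow(results))
  tb <- data.frame(
    kinase = kin,
    hits = unname(hitsBy(all)),
    hits_mrna = unname(hitsBy(results$evidence == "mrna")),
    hits_intensity = unname(hitsBy(results$evidence == "intensity")),
    hits_network = unname(hitsBy(results$evidence == "network")),
    stringsAsFactors = FALSE
  )
  nl <- tapply(-log10(.pfloor(results$pvalue)), f, sum)
  tb$sum_neglog10_p <- as.numeric(nl[tb$kinase])
  db <- tapply(results$direction[results$significant],
               f[results$significant], sum)
  tb$direction_balance <- as.integer(ifelse(is.na(db[tb$kinase]), 0,
                                            db[tb$kinase]))
  tb$passes <- tb$hits >= minHits(design)
  tb <- rankKinases(tb)
  new("CKIResult", table = tb, design = design)
}

#' Rank kinases by hit count
#'
#' Orders a prediction table by hits (descending), then by the sum of
#' -log10 p (descending), then alphabetically by symbol, and assigns
#' ranks 1..K. Hit count is the primary prioritization measure; the p-sum
#' tie-break only orders kinases with equal hit counts deterministically.
#'
#' @param table data.frame with columns kinase, hits, sum_neglog10_p
#' @return the table in rank order with a \code{rank} column
#' @export
rankKinases <- function(table) {
  stopifnot(all(c("kinase", "hits", "sum_neglog10_p") %in% colnames(table)))
  ord <- order(-table$hits, -table$sum_neglog10_p, table$kinase)
  tb <- table[ord, , drop = FALSE]
  tb$rank <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  tb
}

#' Run central kinase inference end to end
#'
#' Executes the three evidence channels over every unit of the design —
#' differential kinase mRNA expression, substrate-intensity chi-squared
#' tests, and up/down sub-network chi-squared tests — then pools the
#' results, counts positive hits per kinase and ranks the candidates.
#'
#' @param profile a \linkS4class{PhosphoProfile}
#' @param network a \linkS4class{KSRNetwork}; kinases outside the catalog
#'   are dropped.
#' @param de differential-expression data.frame (see [readDeTable()]); its
#'   comparison_id values must match the design's mRNA units.
#' @param catalog a \linkS4class{KinaseCatalog}
#' @param design a \linkS4class{CKIDesign}
#' @param transform intensity transform for the TSI channel (see
#'   [computeTsi()]).
#' @param bhColumn also report Benjamini-Hochberg adjusted p-values per
#'   channel in the returned unit results (informational only; hit calling
#'   always uses the raw thresholds).
#' @param verbose emit per-stage messages.
#' @return a \linkS4class{CKIResult}; the pooled per-unit test results are
#'   attached as \code{metadata} in \code{attr(ckiTable(x), "unit_results")}.
#' @export
runCKI <- function(profile, network, de, catalog, design,
                   transform = "sqrt", bhColumn = FALSE, verbose = FALSE) {
  quiet <- function(expr) if (verbose) expr else suppressMessages(expr)
  et <- edges(network)
  inCat <- et$kinase %in% kinases(catalog)
  if (any(!inCat)) {
    if (verbose)
      message(length(unique(et$kinase[!inCat])),
              " network kinase(s) not in the catalog dropped")
    network <- KSRNetwork(et[inCat, , drop = FALSE])
  }
  thr <- channelThresholds(design)
  u <- designUnits(design)
  tsi <- NULL
  if (any(u$evidence == "intensity"))
    tsi <- computeTsi(profile, network, transform = transform)
  resList <- vector("list", nrow(u))
  for (k in seq_len(nrow(u))) {
    unit <- u[k, ]
    rows <- switch(unit$evidence,
      mrna = {
        tested <- .mrnaTested(de, catalog, unit$comparison_id)
        if (nrow(tested) > 0L) {
          tested$significant <- tested$pvalue < thr[["mrna"]]
          tested
        } else tested
      },
      intensity = quiet(
        intensityTests(tsi, unit$sampleA, unit$sampleB,
                       pThreshold = thr[["intensity"]])),
      network = quiet(
        networkTests(computeKni(profile, unit$sampleA, unit$sampleB, network),
                     pThreshold = thr[["network"]]))
    )
    if (nrow(rows) == 0L) {
      resList[[k]] <- NULL
      next
    }
    keep <- intersect(c("kinase", "pvalue", "direction", "significant",
                        "a", "b", "c", "d", "chi2"), colnames(rows))
    rows <- rows[, keep, drop = FALSE]
    rows$unit_id <- unit$unit_id
    rows$evidence <- unit$evidence
    resList[[k]] <- rows
  }
  resList <- Filter(Negate(is.null), resList)
  if (length(resList) == 0L)
    stop("no kinase was testable in any unit")
  cols <- c("kinase", "unit_id", "evidence", "a", "b", "c", "d", "chi2",
            "pvalue", "direction", "significant")
  results <- do.call(rbind, lapply(resList, function(r) {
    for (col in setdiff(cols, colnames(r))) r[[col]] <- NA_real_
    r[, cols]
  }))
  rownames(results) <- NULL
  if (bhColumn) {
    results$padj <- NA_real_
    for (ch in unique(results$evidence)) {
      sel <- results$evidence == ch
      results$padj[sel] <- stats::p.adjust(results$pvalue[sel], method = "BH")
    }
  }
  out <- countHits(results, design)
  attr(out@table, "unit_results") <- results
  out
}

#' Write a prediction table
#'
#' Writes the per-kinase predictions of a \linkS4class{CKIResult} as TSV
#' with columns kinase, hits, hits_mrna, hits_intensity, hits_network,
#' sum_neglog10_p, passes, rank, direction_balance.
#'
#' @param result a \linkS4class{CKIResult}
#' @param path output path
#' @return invisibly, the path
#' @export
writePredictions <- function(result, path) {
  tb <- ckiTable(result)
  tb <- tb[, c("kinase", "hits", "hits_mrna", "hits_intensity",
               "hits_network", "sum_neglog10_p", "passes", "rank",
               "direction_balance")]
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
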