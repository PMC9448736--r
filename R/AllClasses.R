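#' PhosphoProfile: a quantified phosphosite intensity matrix
#'
#' Container for site-level reporter intensities across samples, built on
#' \linkS4class{SummarizedExperiment}. Rows are phosphosites identified by
#' (accession, position, residue); columns are samples carrying
#' (condition, replicate) metadata. The single assay \code{"intensity"}
#' holds nonnegative reporter intensities; a missing cell (\code{NA}) means
#' the site was not quantified in that sample. An intensity of exactly zero
#' is also treated as "not quantified" by all downstream computations,
#' because substrate-intensity sums and intensity ratios require positive
#' values.
#'
#' @slot lpAvailable logical; whether localization-probability classes are
#'   recorded in \code{rowData(x)$lp_class}.
#'
#' @seealso [readPhosphoTable()], [computeTsi()], [summarizePsites()]
#' @export
setClass("PhosphoProfile",
  contains = "SummarizedExperiment",
  representation(lpAvailable = "logical"),
  prototype(lpAvailable = FALSE)
)

.validPhosphoProfile <- function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("accession", "position", "residue") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain accession, position, residue")
  else {
    if (any(rd$position < 1L))
      msg <- c(msg, "site positions must be >= 1")
    if (!all(rd$residue %in% c("S", "T", "Y")))
      msg <- c(msg, "residues must be one of S, T, Y")
    key <- paste(rd$accession, rd$position)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (accession, position) site keys")
    if (object@lpAvailable) {
      if (!"lp_class" %in% colnames(rd))
        msg <- c(msg, "lpAvailable is TRUE but rowData lacks lp_class")
      else if (anyNA(rd$lp_class) || !all(rd$lp_class %in% c("I", "II", "III")))
        msg <- c(msg, "lp_class must cover all sites with values I, II, III")
    }
  }
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain condition and replicate")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample labels must be unique")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be nonnegative")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhosphoProfile", .validPhosphoProfile)

#' Construct a PhosphoProfile
#'
#' @param accession character vector of protein accessions (one per site).
#' @param position integer vector of 1-based positions in the protein.
#' @param residue character vector of phospho-acceptor residues ("S", "T", "Y").
#' @param intensity numeric matrix, sites x samples; \code{NA} = not quantified.
#'   Column names are the sample labels.
#' @param condition,replicate per-sample metadata; if \code{NULL}, parsed from
#'   sample labels of the form \code{"condition:replicate"}.
#' @param lpClass optional per-site localization-probability class
#'   ("I", "II", "III"); class I is LP > 0.75, class II 0.5 < LP <= 0.75,
#'   class III 0.25 <= LP <= 0.5.
#'
#' @return a \linkS4class{PhosphoProfile}
#' @examples
#' p <- PhosphoProfile(
#'   accession = c("P1", "P1", "P2"), position = c(10L, 25L, 7L),
#'   residue = c("S", "T", "Y"),
#'   intensity = matrix(c(4, 9, NA, 16, 25, 36), nrow = 3,
#'                      dimnames = list(NULL, c("ctl:1", "trt:1")))
#' )
#' dim(p)
#' @export
PhosphoProfile <- function(accession, position, residue, intensity,
                           condition = NULL, replicate = NULL,
                           lpClass = NULL) {
  if (is.null(dim(intensity)))
    intensity <- matrix(intensity, nrow = length(accession))
  storage.mode(intensity) <- "double"
  labels <- colnames(intensity)
  if (is.null(labels))
    stop("intensity matrix must carry sample labels as column names")
  if (is.null(condition) || is.null(replicate)) {
    parsed <- .parseSampleLabels(labels)
    if (is.null(condition)) condition <- parsed$condition
    if (is.null(replicate)) replicate <- parsed$replicate
  }
  rd <- S4Vectors::DataFrame(
    accession = as.character(accession),
    position = as.integer(position),
    residue = as.character(residue)
  )
  lpAvailable <- !is.null(lpClass)
  if (lpAvailable) rd$lp_class <- as.character(lpClass)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = rd,
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.character(replicate),
                                   row.names = labels)
  )
  new("PhosphoProfile", se, lpAvailable = lpAvailable)
}

# "condition:replicate" labels; a label with no colon becomes replicate 1
.parseSampleLabels <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  list(
    condition = vapply(parts, `[`, character(1), 1L),
    replicate = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "1",
                       character(1))
  )
}

#' @describeIn PhosphoProfile site identity table (accession, position, residue)
#' @param x a PhosphoProfile
#' @export
setMethod("siteKeys", "PhosphoProfile", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x)[, c("accession", "position", "residue")])
})

#' @describeIn PhosphoProfile the intensity assay matrix
#' @export
setMethod("intensities", "PhosphoProfile", function(x) {
  SummarizedExperiment::assay(x, "intensity")
})

#' @describeIn PhosphoProfile per-sample condition labels
#' @export
setMethod("conditions", "PhosphoProfile", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$condition, colnames(x))
})

#' @describeIn PhosphoProfile per-sample replicate labels
#' @export
setMethod("replicates", "PhosphoProfile", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$replicate, colnames(x))
})

#' @describeIn PhosphoProfile localization-probability classes, or NULL
#' @export
setMethod("lpClass", "PhosphoProfile", function(x) {
  if (!x@lpAvailable) return(NULL)
  SummarizedExperiment::rowData(x)$lp_class
})

setMethod("show", "PhosphoProfile", function(object) {
  cat(sprintf("PhosphoProfile: %d p-sites x %d samples\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  tab <- table(cd$condition)
  cat("conditions:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "intensity")))
  cat(sprintf("missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / prod(dim(object))))
  if (object@lpAvailable) cat("LP classes: available\n")
})


#' KSRNetwork: directed kinase -> phosphosite edges
#'
#' The set of site-specific kinase-substrate relations (ssKSRs), e.g. the
#' exported predictions of a site-specific kinase-substrate predictor. Each
#' edge points from a kinase gene symbol to one phosphosite
#' (accession, position, residue). Edges are unique; every kinase carries at
#' least one edge.
#'
#' @slot edgeTable data.frame with columns kinase, accession, position, residue
#' @export
setClass("KSRNetwork", representation(edgeTable = "data.frame"))

.validKSRNetwork <- function(object) {
  et <- object@edgeTable
  msg <- character()
  need <- c("kinase", "accession", "position", "residue")
  if (!all(need %in% colnames(et)))
    return(paste("edge table needs columns:", paste(need, collapse = ", ")))
  if (nrow(et) == 0L) msg <- c(msg, "network has no edges")
  if (anyDuplicated(et[, need])) msg <- c(msg, "duplicate edges")
  if (any(et$position < 1L)) msg <- c(msg, "positions must be >= 1")
  if (!all(et$residue %in% c("S", "T", "Y")))
    msg <- c(msg, "residues must be one of S, T, Y")
  if (any(!nzchar(et$kinase))) msg <- c(msg, "empty kinase symbol")
  if (length(msg)) msg else TRUE
}
setValidity("KSRNetwork", .validKSRNetwork)

#' Construct a KSRNetwork
#'
#' @param kinase kinase gene symbols (case-normalized to upper case), or a
#'   data.frame with columns kinase, accession, position, residue.
#' @param accession,position,residue substrate site coordinates.
#' @return a \linkS4class{KSRNetwork}; duplicate edges are dropped with a message.
#' @examples
#' net <- KSRNetwork(kinase = c("PIM1", "PIM1", "PLK1"),
#'                   accession = c("P1", "P2", "P1"),
#'                   position = c(10L, 7L, 10L), residue = c("S", "Y", "S"))
#' kinases(net)
#' @export
KSRNetwork <- function(kinase, accession = NULL, position = NULL, residue = NULL) {
  if (is.data.frame(kinase)) {
    et <- kinase
  } else {
    et <- data.frame(kinase = kinase, accession = accession,
                     position = position, residue = residue,
                     stringsAsFactors = FALSE)
  }
  et$kinase <- toupper(trimws(as.character(et$kinase)))
  et$accession <- as.character(et$accession)
  et$position <- as.integer(et$position)
  et$residue <- as.character(et$residue)
  dup <- duplicated(et[, c("kinase", "accession", "position", "residue")])
  if (any(dup)) {
    message(sum(dup), " duplicate ssKSR edge(s) removed")
    et <- et[!dup, , drop = FALSE]
  }
  rownames(et) <- NULL
  new("KSRNetwork", edgeTable = et)
}

#' @describeIn KSRNetwork the edge table
#' @param x a KSRNetwork
#' @export
setMethod("edges", "KSRNetwork", function(x) x@edgeTable)

#' @describeIn KSRNetwork sorted unique kinase symbols
#' @export
setMethod("kinases", "KSRNetwork", function(x) sort(unique(x@edgeTable$kinase)))

#' @describeIn KSRNetwork unique substrate sites covered by the network
#' @export
setMethod("siteKeys", "KSRNetwork", function(x) {
  s <- unique(x@edgeTable[, c("accession", "position", "residue")])
  rownames(s) <- NULL
  s
})

setMethod("show", "KSRNetwork", function(object) {
  cat(sprintf("KSRNetwork: %d edges, %d kinases, %d substrate p-sites\n",
              nrow(object@edgeTable),
              length(unique(object@edgeTable$kinase)),
              nrow(unique(object@edgeTable[, c("accession", "position")]))))
})


#' KinaseCatalog: the protein-kinase gene universe
#'
#' The set of kinase gene symbols of a species (e.g. the 524 human or 539
#' mouse protein kinases of a curated kinase database). Differentially
#' expressed mRNAs are mapped onto this catalog to call differentially
#' expressed protein kinases.
#'
#' @slot symbols character vector of unique, upper-cased gene symbols
#' @slot species free-text species label
#' @export
setClass("KinaseCatalog",
         representation(symbols = "character", species = "character"))

setValidity("KinaseCatalog", function(object) {
  if (length(object@symbols) == 0L) return("catalog is empty")
  if (anyDuplicated(toupper(object@symbols)))
    return("duplicate symbols after case normalization")
  TRUE
})

#' Construct a KinaseCatalog
#' @param symbols kinase gene symbols; trimmed, upper-cased, de-duplicated.
#' @param species free-text label.
#' @return a \linkS4class{KinaseCatalog}
#' @export
KinaseCatalog <- function(symbols, species = "unspecified") {
  symbols <- unique(toupper(trimws(symbols)))
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) == 0L) stop("kinase catalog is empty")
  new("KinaseCatalog", symbols = sort(symbols), species = species)
}

#' @describeIn KinaseCatalog the catalog symbols
#' @param x a KinaseCatalog
#' @export
setMethod("kinases", "KinaseCatalog", function(x) x@symbols)

setMethod("show", "KinaseCatalog", function(object) {
  cat(sprintf("KinaseCatalog: %d kinases (%s)\n",
              length(object@symbols), object@species))
})


#' ReporterSpec: isobaric reporter-ion masses and tolerance
#'
#' Monoisotopic reporter masses for an isobaric labeling kit plus the m/z
#' tolerance used when scanning MS/MS peak lists for reporter ions.
#'
#' @slot masses named numeric vector of monoisotopic masses (Da)
#' @slot tolerance m/z matching tolerance (Da)
#' @seealso [tmt6Reporters()], [scanReporterIons()]
#' @export
setClass("ReporterSpec",
         representation(masses = "numeric", tolerance = "numeric"))

setValidity("ReporterSpec", function(object) {
  msg <- character()
  if (length(object@masses) == 0L || any(object@masses <= 0))
    msg <- c(msg, "masses must be positive")
  if (anyDuplicated(object@masses)) msg <- c(msg, "masses must be distinct")
  if (length(object@tolerance) != 1L || object@tolerance <= 0)
    msg <- c(msg, "tolerance must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ReporterSpec
#' @param masses named numeric vector of monoisotopic reporter masses in Da.
#' @param tolerance matching tolerance in Da (default 0.005).
#' @return a \linkS4class{ReporterSpec}
#' @export
ReporterSpec <- function(masses, tolerance = 0.005) {
  new("ReporterSpec", masses = masses, tolerance = tolerance)
}

#' TMT 6-plex reporter specification
#'
#' The six monoisotopic TMT 6-plex reporter-ion masses (126-131) with the
#' default 0.005 Da matching tolerance.
#' @return a \linkS4class{ReporterSpec}
#' @examples
#' tmt6Reporters()
#' @export
tmt6Reporters <- function() {
  ReporterSpec(
    masses = c(`126` = 126.127726, `127` = 127.124761, `128` = 128.134436,
               `129` = 129.131471, `130` = 130.141145, `131` = 131.138180),
    tolerance = 0.005
  )
}

setMethod("show", "ReporterSpec", function(object) {
  cat(sprintf("ReporterSpec: %d reporters, tolerance %g Da\n",
              length(object@masses), object@tolerance))
})


#' CKIDesign: the pairwise-comparison design
#'
#' Enumerates the evidence units of a central-kinase-inference run: one unit
#' per (evidence channel, sample pair). Replicate-level channels contribute
#' the full Cartesian product of cross-condition replicate pairs; a
#' condition-level channel contributes one unit per condition pair. The
#' design also fixes the per-channel significance thresholds and the minimum
#' number of positive hits a kinase needs to be called central.
#'
#' @slot units data.frame with columns unit_id, evidence
#'   ("mrna", "intensity", "network"), sampleA, sampleB, comparison_id
#' @slot thresholds named numeric, p-value threshold per channel
#' @slot minHits integer hit-count threshold
#' @seealso [enumerateUnits()], [ckiPreset()]
#' @export
setClass("CKIDesign",
         representation(units = "data.frame", thresholds = "numeric",
                        minHits = "integer"))

setValidity("CKIDesign", function(object) {
  msg <- character()
  u <- object@units
  need <- c("unit_id", "evidence", "sampleA", "sampleB", "comparison_id")
  if (!all(need %in% colnames(u)))
    return(paste("units needs columns:", paste(need, collapse = ", ")))
  if (nrow(u) == 0L) msg <- c(msg, "design has no units")
  if (anyDuplicated(u$unit_id)) msg <- c(msg, "duplicate unit ids")
  if (!all(u$evidence %in% c("mrna", "intensity", "network")))
    msg <- c(msg, "evidence must be mrna, intensity or network")
  if (!all(c("mrna", "intensity", "network") %in% names(object@thresholds)))
    msg <- c(msg, "thresholds must name mrna, intensity, network")
  else if (any(object@thresholds <= 0 | object@thresholds >= 1))
    msg <- c(msg, "thresholds must lie in (0, 1)")
  if (object@minHits < 1L || object@minHits > nrow(u))
    msg <- c(msg, "minHits must lie in 1..number of units")
  if (length(msg)) msg else TRUE
})

#' @describeIn CKIDesign the unit table
#' @param x a CKIDesign
#' @export
setMethod("designUnits", "CKIDesign", function(x) x@units)

#' @describeIn CKIDesign the hit-count threshold
#' @export
setMethod("minHits", "CKIDesign", function(x) x@minHits)

#' @describeIn CKIDesign per-channel p-value thresholds
#' @export
setMethod("channelThresholds", "CKIDesign", function(x) x@thresholds)

setMethod("show", "CKIDesign", function(object) {
  tab <- table(object@units$evidence)
  cat(sprintf("CKIDesign: %d units (%s); min hits %d\n",
              nrow(object@units),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", "),
              object@minHits))
  thr <- object@thresholds
  cat("thresholds:",
      paste(sprintf("%s p<%g", names(thr), thr), collapse = ", "), "\n")
})


#' CKIResult: ranked central-kinase predictions
#'
#' Per-kinase positive-hit counts pooled over all evidence units, with the
#' per-channel breakdown, the sum of -log10 p over all tested units, the
#' pass flag (hits >= minHits of the design) and the final rank. Kinases are
#' ranked by hit count (descending), ties broken by the -log10 p sum, then
#' alphabetically.
#'
#' @slot table the per-kinase prediction data.frame
#' @slot design the \linkS4class{CKIDesign} the hits were counted against
#' @seealso [countHits()], [runCKI()], [rankKinases()]
#' @export
setClass("CKIResult",
         representation(table = "data.frame", design = "CKIDesign"))

setValidity("CKIResult", function(object) {
  tb <- object@table
  need <- c("kinase", "hits", "hits_mrna", "hits_intensity", "hits_network",
            "sum_neglog10_p", "passes", "rank", "direction_balance")
  if (!all(need %in% colnames(tb)))
    return(paste("table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb) > 0L) {
    if (any(tb$hits < 0L) || any(tb$hits > nrow(object@design@units)))
      return("hits must lie in 0..number of units")
    if (!identical(sort(tb$rank), seq_len(nrow(tb))))
      return("rank must be a permutation of 1..nrow")
  }
  TRUE
})

#' @describeIn CKIResult the per-kinase prediction table, rank order
#' @param x a CKIResult
#' @export
setMethod("ckiTable", "CKIResult", function(x) x@table)

#' @describeIn CKIResult kinases in rank order
#' @export
setMethod("kinases", "CKIResult", function(x) x@table$kinase)

setMethod("show", "CKIResult", function(object) {
  tb <- object@table
  cat(sprintf("CKIResult: %d kinases tested, %d pass (hits >= %d of %d units)\n",
              nrow(tb), sum(tb$passes), object@design@minHits,
              nrow(object@design@units)))
  if (nrow(tb) > 0L) {
    top <- utils::head(tb[, c("kinase", "hits", "hits_mrna", "hits_intensity",
                              "hits_network", "rank")], 5L)
    print(top, row.names = FALSE)
  }
})


#' TSITable: per-kinase total substrate intensity
#'
#' The total substrate intensity (TSI) of each kinase in each sample: the sum
#' of square-root-transformed reporter intensities over the kinase's
#' quantified substrate phosphosites. Per-sample totals over all kinases are
#' the column sums; a site targeted by several kinases contributes to each.
#'
#' @slot tsi numeric matrix, kinases x samples
#' @slot nSites integer matrix of contributing quantified sites
#' @slot transform the intensity transform used ("sqrt" is canonical)
#' @seealso [computeTsi()], [intensityTest()]
#' @export
setClass("TSITable",
         representation(tsi = "matrix", nSites = "matrix", transform = "character"))

setValidity("TSITable", function(object) {
  if (!identical(dim(object@tsi), dim(object@nSites)))
    return("tsi and nSites must have identical dimensions")
  if (any(object@tsi < 0)) return("TSI values must be nonnegative")
  TRUE
})

#' @describeIn TSITable the kinase x sample TSI matrix
#' @param x a TSITable
#' @export
setMethod("tsiMatrix", "TSITable", function(x) x@tsi)

#' @describeIn TSITable per-sample totals over all kinases
#' @export
setMethod("tsiTotals", "TSITable", function(x) colSums(x@tsi))

#' @describeIn TSITable the kinases of the table
#' @export
setMethod("kinases", "TSITable", function(x) rownames(x@tsi))

setMethod("show", "TSITable", function(object) {
  cat(sprintf("TSITable (%s transform): %d kinases x %d samples\n",
              object@transform, nrow(object@tsi), ncol(object@tsi)))
})


#' KNITable: per-kinase up/down network indices for one sample pair
#'
#' For one pairwise comparison A vs B, each kinase's up-regulated network
#' index (sum of relative intensity ratios RIR over mutually quantified
#' substrate sites with RIR > 1) and down-regulated index (sum of 1/RIR over
#' sites with RIR < 1), with the site counts. Totals over all kinases are
#' carried for the chi-squared contingency test.
#'
#' @slot records data.frame: kinase, kni_up, kni_down, n_up, n_down, n_tied
#' @slot totals named numeric c(up, down)
#' @slot sampleA,sampleB the compared sample labels
#' @seealso [computeKni()], [networkTest()]
#' @export
setClass("KNITable",
         representation(records = "data.frame", totals = "numeric",
                        sampleA = "character", sampleB = "character"))

setValidity("KNITable", function(object) {
  r <- object@records
  need <- c("kinase", "kni_up", "kni_down", "n_up", "n_down", "n_tied")
  if (!all(need %in% colnames(r)))
    return(paste("records needs columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0L) {
    if (any(r$kni_up < r$n_up - 1e-9) || any(r$kni_down < r$n_down - 1e-9))
      return("each up RIR exceeds 1 and each down 1/RIR exceeds 1, so kni >= n")
  }
  if (!all(c("up", "down") %in% names(object@totals)))
    return("totals must name up and down")
  TRUE
})

#' @describeIn KNITable the per-kinase record table
#' @param x a KNITable
#' @export
setMethod("kniRecords", "KNITable", function(x) x@records)

#' @describeIn KNITable totals over all kinases (up, down)
#' @export
setMethod("kniTotals", "KNITable", function(x) x@totals)

setMethod("show", "KNITable", function(object) {
  cat(sprintf("KNITable %s vs %s: %d kinases; totals up %.3g, down %.3g\n",
              object@sampleA, object@sampleB, nrow(object@records),
              object@totals["up"], object@totals["down"]))
})


#' ROCResult: a receiver operating characteristic curve
#'
#' ROC points (1 - specificity, sensitivity) swept over the distinct score
#' thresholds (higher score = more confident positive call), plus the area
#' under the curve. The AUC equals the probability that a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @slot points numeric matrix with columns fpr (= 1 - Sp) and tpr (= Sn)
#' @slot auc area under the curve in [0, 1]
#' @seealso [rocAuc()]
#' @export
setClass("ROCResult", representation(points = "matrix", auc = "numeric"))

setValidity("ROCResult", function(object) {
  p <- object@points
  msg <- character()
  if (!all(c("fpr", "tpr") %in% colnames(p)))
    return("points must have columns fpr, tpr")
  if (any(diff(p[, "fpr"]) < -1e-12) || any(diff(p[, "tpr"]) < -1e-12))
    msg <- c(msg, "ROC points must be monotone nondecreasing")
  if (any(abs(p[1, ] - 0) > 1e-12) || any(abs(p[nrow(p), ] - 1) > 1e-12))
    msg <- c(msg, "ROC must run from (0,0) to (1,1)")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ROCResult the (fpr, tpr) point matrix
#' @param x a ROCResult
#' @export
setMethod("rocPoints", "ROCResult", function(x) x@points)

#' @describeIn ROCResult the area under the curve
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f over %d points\n",
              object@auc, nrow(object@points)))
})


#' PSiteSummary: phosphosite summary statistics
#'
#' Counts and printed-style percentages of quantified phosphosites per
#' acceptor residue (pS/pT/pY), per localization-probability class
#' (I/II/III) when available, and the fraction annotated in at least one
#' known phosphosite database. Percentages are rounded half away from zero
#' to two decimals.
#'
#' @slot total total number of sites
#' @slot residueCounts,residuePct named by residue (S, T, Y)
#' @slot classCounts,classPct named by LP class, or empty when unavailable
#' @slot knownCount,knownPct sites annotated in a known-site set (NA if no
#'   known-site table was supplied)
#' @seealso [summarizePsites()], [psiteSummaryFromCounts()]
#' @export
setClass("PSiteSummary",
         representation(total = "integer",
                        residueCounts = "integer", residuePct = "numeric",
                        classCounts = "integer", classPct = "numeric",
                        knownCount = "integer", knownPct = "numeric"))

setValidity("PSiteSummary", function(object) {
  msg <- character()
  if (sum(object@residueCounts) != object@total)
    msg <- c(msg, "residue counts must sum to total")
  if (length(object@classCounts) && sum(object@classCounts) != object@total)
    msg <- c(msg, "class counts must sum to total")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSiteSummary", function(object) {
  cat(sprintf("PSiteSummary: %d p-sites\n", object@total))
  r <- object@residueCounts
  cat(" residues:",
      paste(sprintf("p%s %d (%.2f%%)", names(r), r,
                    object@residuePct[names(r)]), collapse = ", "), "\n")
  if (length(object@classCounts)) {
    k <- object@classCounts
    cat(" LP classes:",
        paste(sprintf("%s %d (%.2f%%)", names(k), k,
                      object@classPct[names(k)]), collapse = ", "), "\n")
  }
  if (!is.na(object@knownCount))
    cat(sprintf(" known sites: %d (%.2f%%)\n",
                object@knownCount, object@knownPct))
})
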