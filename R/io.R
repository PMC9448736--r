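#' Read a phosphosite intensity table
#'
#' Parses a tab-separated table with site identity columns followed by one
#' intensity column per sample. Sample labels of the form
#' \code{"condition:replicate"} carry the design; a label without a colon is
#' taken as a single-replicate condition. Blank/NA cells are recorded as
#' missing; explicit zeros are converted to missing as well (and counted
#' separately in the message), because downstream substrate-intensity sums
#' and intensity ratios are defined only for positive values.
#'
#' @param path file path.
#' @param dialect named list mapping the roles \code{accession},
#'   \code{position}, \code{residue} (and optionally \code{lp_class}) to the
#'   header names used in the file; an lp_class column is picked up when the
#'   file has one.
#' @return a \linkS4class{PhosphoProfile}
#' @seealso [writePhosphoTable()]
#' @export
readPhosphoTable <- function(path,
                             dialect = list(accession = "accession",
                                            position = "position",
                                            residue = "residue",
                                            lp_class = "lp_class")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  for (role in c("accession", "position", "residue")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% colnames(df))
      stop("malformed header: missing ", role, " column",
           if (!is.null(col)) paste0(" ('", col, "')"))
  }
  lpCol <- dialect[["lp_class"]]
  idCols <- c(dialect$accession, dialect$position, dialect$residue,
              if (!is.null(lpCol) && lpCol %in% colnames(df)) lpCol)
  sampleCols <- setdiff(colnames(df), idCols)
  if (length(sampleCols) == 0L)
    stop("malformed header: no sample columns")
  intensity <- as.matrix(df[, sampleCols, drop = FALSE])
  storage.mode(intensity) <- "double"
  neg <- which(intensity < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative intensity at row ", neg[1, 1], ", sample '",
         sampleCols[neg[1, 2]], "'")
  res <- as.character(df[[dialect$residue]])
  bad <- which(!res %in% c("S", "T", "Y"))
  if (length(bad) > 0L)
    stop("invalid residue '", res[bad[1]], "' at row ", bad[1],
         " (must be S, T or Y)")
  nZero <- sum(intensity == 0, na.rm = TRUE)
  if (nZero > 0L) {
    message(nZero, " zero-intensity cell(s) treated as not quantified")
    intensity[intensity == 0] <- NA_real_
  }
  nMissing <- sum(is.na(intensity)) - nZero
  if (nMissing > 0L)
    message(nMissing, " blank cell(s) recorded as not quantified")
  PhosphoProfile(
    accession = as.character(df[[dialect$accession]]),
    position = as.integer(df[[dialect$position]]),
    residue = res,
    intensity = intensity,
    lpClass = if (!is.null(lpCol) && lpCol %in% colnames(df))
      as.character(df[[lpCol]]) else NULL
  )
}

#' Write a phosphosite intensity table
#'
#' Inverse of [readPhosphoTable()]: missing cells are written as empty
#' fields, so write-then-read reproduces the profile.
#'
#' @param profile a \linkS4class{PhosphoProfile}
#' @param path output file path
#' @return invisibly, the path
#' @export
writePhosphoTable <- function(profile, path) {
  sk <- siteKeys(profile)
  lp <- lpClass(profile)
  df <- if (is.null(lp)) sk else cbind(sk, lp_class = lp)
  df <- cbind(df, as.data.frame(intensities(profile), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a site-specific kinase-substrate relation table
#'
#' Tab-separated columns: kinase, accession, position, residue. Duplicate
#' edges are dropped with a message; kinase symbols are upper-cased.
#'
#' @param path file path
#' @return a \linkS4class{KSRNetwork}
#' @export
readSsksrTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("kinase", "accession", "position", "residue")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("malformed header: missing column(s) ",
                         paste(miss, collapse = ", "))
  KSRNetwork(df[, need])
}

#' Write a kinase-substrate relation table
#' @param network a \linkS4class{KSRNetwork}
#' @param path output path
#' @return invisibly, the path
#' @export
writeSsksrTable <- function(network, path) {
  utils::write.table(edges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated columns: gene, log2fc, pvalue, comparison_id. Gene symbols
#' are upper-cased; exact duplicate rows are dropped with a message; a
#' duplicated (gene, comparison_id) pair with conflicting values is an error.
#'
#' @param path file path
#' @return data.frame with columns gene, log2fc, pvalue, comparison_id
#' @export
readDeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "comparison_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("malformed header: missing column(s) ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$gene <- toupper(trimws(df$gene))
  df$comparison_id <- as.character(df$comparison_id)
  bad <- which(is.na(df$pvalue) | df$pvalue < 0 | df$pvalue > 1)
  if (length(bad)) stop("p-value out of [0,1] at row ", bad[1])
  dup <- duplicated(df)
  if (any(dup)) {
    message(sum(dup), " duplicate DE row(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  key <- paste(df$gene, df$comparison_id)
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("conflicting duplicate rows for (gene, comparison_id): ", k)
  }
  rownames(df) <- NULL
  df
}

#' Write a differential-expression table
#' @param de data.frame with columns gene, log2fc, pvalue, comparison_id
#' @param path output path
#' @return invisibly, the path
#' @export
writeDeTable <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase catalog (one gene symbol per line)
#' @param path file path
#' @param species free-text species label
#' @return a \linkS4class{KinaseCatalog}
#' @export
readKinaseCatalog <- function(path, species = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("kinase catalog is empty: ", path)
  KinaseCatalog(lines, species = species)
}

#' Write a kinase catalog
#' @param catalog a \linkS4class{KinaseCatalog}
#' @param path output path
#' @return invisibly, the path
#' @export
writeKinaseCatalog <- function(catalog, path) {
  writeLines(kinases(catalog), path)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Tab-separated columns: gene, term_id, term_name (GO/KEGG style).
#' @param path file path
#' @return data.frame with upper-cased gene symbols, de-duplicated
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "term_id", "term_name")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("malformed header: missing column(s) ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$gene <- toupper(trimws(df$gene))
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Read a truth list of known regulatory kinases (one symbol per line)
#' @param path file path
#' @return character vector of unique upper-cased symbols
#' @export
readTruthList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  unique(toupper(lines[nzchar(lines)]))
}

#' Write a truth list
#' @param truth character vector of kinase symbols
#' @param path output path
#' @return invisibly, the path
#' @export
writeTruthList <- function(truth, path) {
  writeLines(toupper(truth), path)
  invisible(path)
}
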