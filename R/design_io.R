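#' Read a run design file
#'
#' A YAML document declaring the comparison design:
#' \preformatted{
#' conditions:
#'   control: ["control:1", "control:2", "control:3"]
#'   treated: ["treated:1", "treated:2", "treated:3"]
#' channels: {mrna: condition, intensity: replicate, network: replicate}
#' thresholds: {mrna: 0.01, intensity: 1.0e-5, network: 1.0e-5}
#' min_hits: 14
#' }
#'
#' @param path path to the YAML design file
#' @return a \linkS4class{CKIDesign}
#' @seealso [enumerateUnits()], [writeDesignFile()]
#' @export
readDesignFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("conditions", "channels", "thresholds", "min_hits")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("design file missing field(s): ",
                         paste(miss, collapse = ", "))
  enumerateUnits(
    conditions = lapply(y$conditions, as.character),
    channels = unlist(y$channels),
    thresholds = unlist(y$thresholds),
    minHits = y$min_hits
  )
}

#' Write a run design file
#' @param conditions named list of sample labels per condition
#' @param channels,thresholds,minHits as for [enumerateUnits()]
#' @param path output path
#' @return invisibly, the path
#' @export
writeDesignFile <- function(conditions, channels, thresholds, minHits, path) {
  yaml::write_yaml(list(
    conditions = lapply(conditions, as.character),
    channels = as.list(channels),
    thresholds = as.list(thresholds),
    min_hits = as.integer(minHits)
  ), path)
  invisible(path)
}

# design from a profile's colData plus a preset or explicit settings
.designFromProfile <- function(profile, channels, thresholds, minHits) {
  cond <- conditions(profile)
  lv <- unique(cond)
  enumerateUnits(
    conditions = stats::setNames(
      lapply(lv, function(cn) names(cond)[cond == cn]), lv),
    channels = channels, thresholds = thresholds, minHits = minHits
  )
}
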