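#' Synthetic-data generator configuration
#'
#' Parameters of the paired transcriptome/phosphoproteome simulator. The
#' generator emulates the statistical structure the central-kinase method
#' assumes: a kinase with elevated activity phosphorylates its substrate
#' sites at higher levels, so a planted "central" kinase multiplies the
#' reporter intensities of all its substrate sites by an activity effect
#' \code{kappa} in every non-reference condition. Reporter intensities are
#' log-normal (right-skewed, as TMT reporter intensities are); missingness
#' is completely at random; differential-expression p-values are uniform
#' nulls with planted kinase genes drawn from a Beta concentrated near zero.
#'
#' @param seed integer; fully determines the output.
#' @param nKinases number of kinases in the catalog and network.
#' @param nSites number of phosphosites.
#' @param edgesPerKinase mean substrate-site count per kinase
#'   (Poisson-distributed, at least 1).
#' @param sharedSubstrateProb probability that an edge reuses a site already
#'   targeted by another kinase.
#' @param conditions named integer vector: replicates per condition, in
#'   order; the first condition is the reference, planted effects apply to
#'   the others.
#' @param baselineLogMean,baselineLogSd per-site baseline log-intensity
#'   distribution (natural log; defaults centred on a 1e6 reporter scale).
#' @param noiseSd per-cell measurement noise sd on the log scale.
#' @param missingProb completely-at-random cell dropout probability.
#' @param nPlanted number of planted central kinases.
#' @param kappa activity effect multiplier (> 0) applied to planted kinases'
#'   substrate sites in non-reference conditions; 1 = null (no effect, and
#'   the matching DE rows are nulls too).
#' @param nNullGenes additional non-kinase genes in the DE table.
#' @return a validated config list of class \code{cki_synth_config}
#' @seealso [simulateCKIData()]
#' @export
syntheticConfig <- function(seed = 1L, nKinases = 100L, nSites = 2000L,
                            edgesPerKinase = 20, sharedSubstrateProb = 0.2,
                            conditions = c(control = 3L, treated = 3L),
                            baselineLogMean = log(1e6), baselineLogSd = 1,
                            noiseSd = 0.25, missingProb = 0.1,
                            nPlanted = 5L, kappa = 8,
                            nNullGenes = 500L) {
  stopifnot(kappa > 0,
            missingProb >= 0, missingProb <= 1,
            sharedSubstrateProb >= 0, sharedSubstrateProb <= 1,
            nPlanted <= nKinases, length(conditions) >= 2,
            !is.null(names(conditions)))
  if (nSites < edgesPerKinase)
    stop("config error: nSites must cover the per-kinase edge demand")
  structure(list(
    seed = as.integer(seed), nKinases = as.integer(nKinases),
    nSites = as.integer(nSites), edgesPerKinase = edgesPerKinase,
    sharedSubstrateProb = sharedSubstrateProb,
    conditions = conditions,
    baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
    noiseSd = noiseSd, missingProb = missingProb,
    nPlanted = as.integer(nPlanted), kappa = kappa,
    nNullGenes = as.integer(nNullGenes)
  ), class = "cki_synth_config")
}

#' Simulate a paired transcriptome/phosphoproteome dataset
#'
#' Generates a phosphosite intensity profile, a random kinase-substrate
#' bipartite network, a matched differential-expression table (one
#' condition-level comparison per condition pair, later vs earlier), the
#' kinase catalog, and the planted truth. Identical configs (including the
#' seed) give identical output.
#'
#' @param config a [syntheticConfig()]
#' @return list with elements \code{profile} (\linkS4class{PhosphoProfile}),
#'   \code{network} (\linkS4class{KSRNetwork}), \code{de} (data.frame),
#'   \code{catalog} (\linkS4class{KinaseCatalog}), \code{truth} (list with
#'   the planted kinase symbols and effect), \code{config}
#' @examples
#' d <- simulateCKIData(syntheticConfig(seed = 7, nKinases = 10,
#'                                      nSites = 100, nPlanted = 2))
#' d$truth$kinases
#' @export
simulateCKIData <- function(config) {
  stopifnot(inherits(config, "cki_synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  kin <- sprintf("KIN%03d", seq_len(config$nKinases))
  planted <- if (config$nPlanted > 0)
    sample(kin, config$nPlanted) else character(0)

  # sites: one accession per site keeps (accession, position) trivially unique
  nS <- config$nSites
  sites <- data.frame(
    accession = sprintf("PROT%05d", seq_len(nS)),
    position = sample(5:995, nS, replace = TRUE),
    residue = sample(c("S", "T", "Y"), nS, replace = TRUE,
                     prob = c(0.86, 0.12, 0.02)),
    stringsAsFactors = FALSE
  )
  lp <- sample(c("I", "II", "III"), nS, replace = TRUE,
               prob = c(0.84, 0.13, 0.03))

  # bipartite network: per-kinase Poisson edge counts; an edge reuses an
  # already-targeted site with probability sharedSubstrateProb
  used <- integer(0)
  edgeK <- character(0); edgeS <- integer(0)
  for (k in kin) {
    nk <- max(1L, stats::rpois(1, config$edgesPerKinase))
    nk <- min(nk, nS)
    s <- integer(nk)
    for (e in seq_len(nk)) {
      if (length(used) > 0 && stats::runif(1) < config$sharedSubstrateProb)
        s[e] <- sample(used, 1L)
      else
        s[e] <- sample.int(nS, 1L)
    }
    s <- unique(s)
    used <- unique(c(used, s))
    edgeK <- c(edgeK, rep(k, length(s)))
    edgeS <- c(edgeS, s)
  }
  net <- KSRNetwork(data.frame(
    kinase = edgeK,
    accession = sites$accession[edgeS],
    position = sites$position[edgeS],
    residue = sites$residue[edgeS],
    stringsAsFactors = FALSE
  ))

  # intensities: lognormal baseline x planted effect x lognormal noise
  condNames <- names(config$conditions)
  labels <- unlist(lapply(condNames, function(cn)
    paste(cn, seq_len(config$conditions[[cn]]), sep = ":")))
  condOf <- rep(condNames, times = config$conditions)
  baseline <- stats::rnorm(nS, config$baselineLogMean, config$baselineLogSd)
  et <- edges(net)
  plantedSites <- unique(match(
    .siteKeyString(et$accession[et$kinase %in% planted],
                   et$position[et$kinase %in% planted]),
    .siteKeyString(sites$accession, sites$position)))
  intensity <- matrix(NA_real_, nS, length(labels),
                      dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    lmu <- baseline
    if (condOf[j] != condNames[1] && length(plantedSites) > 0)
      lmu[plantedSites] <- lmu[plantedSites] + log(config$kappa)
    intensity[, j] <- exp(lmu + stats::rnorm(nS, 0, config$noiseSd))
  }
  drop <- matrix(stats::runif(length(intensity)) < config$missingProb,
                 nrow = nS)
  intensity[drop] <- NA_real_
  profile <- PhosphoProfile(
    accession = sites$accession, position = sites$position,
    residue = sites$residue, intensity = intensity, lpClass = lp
  )

  # DE table: one condition-level comparison per condition pair
  nullGenes <- if (config$nNullGenes > 0)
    sprintf("GENE%04d", seq_len(config$nNullGenes)) else character(0)
  genes <- c(kin, nullGenes)
  pairIdx <- utils::combn(length(condNames), 2L)
  deList <- lapply(seq_len(ncol(pairIdx)), function(p) {
    cid <- paste0(condNames[pairIdx[2, p]], "_vs_", condNames[pairIdx[1, p]])
    isPlanted <- genes %in% planted & config$kappa != 1
    data.frame(
      gene = genes,
      log2fc = ifelse(isPlanted,
                      log2(config$kappa) + stats::rnorm(length(genes), 0, 0.2),
                      stats::rnorm(length(genes), 0, 0.3)),
      pvalue = ifelse(isPlanted,
                      stats::rbeta(length(genes), 1, 200),
                      stats::runif(length(genes))),
      comparison_id = cid,
      stringsAsFactors = FALSE
    )
  })
  de <- do.call(rbind, deList)
  rownames(de) <- NULL

  list(profile = profile, network = net, de = de,
       catalog = KinaseCatalog(kin, species = "synthetic"),
       truth = list(kinases = sort(planted), kappa = config$kappa),
       config = config)
}

#' Write a simulated dataset as a fixture directory
#'
#' Writes psites.tsv, ssksr.tsv, de.tsv, kinases.txt, truth.txt and
#' config.yaml in the package's exchange schemas, so that the readers
#' round-trip the dataset and [simulateCKIData()] on the recorded config
#' regenerates it exactly.
#'
#' @param dataset result of [simulateCKIData()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeFixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePhosphoTable(dataset$profile, file.path(dir, "psites.tsv"))
  writeSsksrTable(dataset$network, file.path(dir, "ssksr.tsv"))
  writeDeTable(dataset$de, file.path(dir, "de.tsv"))
  writeKinaseCatalog(dataset$catalog, file.path(dir, "kinases.txt"))
  writeTruthList(dataset$truth$kinases, file.path(dir, "truth.txt"))
  cfg <- unclass(dataset$config)
  cfg$conditions <- as.list(cfg$conditions)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 15L)
  invisible(dir)
}

#' Reload a fixture's generator configuration
#' @param path path to a config.yaml written by [writeFixture()]
#' @return a [syntheticConfig()]
#' @export
readFixtureConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$conditions <- unlist(cfg$conditions)
  do.call(syntheticConfig, cfg)
}
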