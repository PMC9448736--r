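# small in-code fixtures shared across test files

# 3 sites x 2 samples with one missing cell
tinyProfile <- function() {
  PhosphoProfile(
    accession = c("P1", "P1", "P2"),
    position = c(10L, 25L, 7L),
    residue = c("S", "T", "Y"),
    intensity = matrix(c(4, 9, NA, 16, 25, 36), nrow = 3,
                       dimnames = list(NULL, c("ctl:1", "trt:1")))
  )
}

# one kinase with three substrate sites, one site shared with a second kinase
tinyNetwork <- function() {
  KSRNetwork(kinase = c("K1", "K1", "K1", "K2"),
             accession = c("P1", "P1", "P2", "P1"),
             position = c(10L, 25L, 7L, 10L),
             residue = c("S", "T", "Y", "S"))
}

# profile built from an explicit intensity matrix; rows auto-named sites
profileFromMatrix <- function(mat) {
  n <- nrow(mat)
  PhosphoProfile(accession = sprintf("P%03d", seq_len(n)),
                 position = seq_len(n) + 4L,
                 residue = rep("S", n),
                 intensity = mat)
}

# complete network: every kinase targets every site of a profile
fullNetwork <- function(profile, kinases) {
  sk <- siteKeys(profile)
  KSRNetwork(do.call(rbind, lapply(kinases, function(k)
    data.frame(kinase = k, sk, stringsAsFactors = FALSE))))
}

# the standard two-condition 3v3 design used by the recovery experiments
doxDesign <- function(reps = 3L) {
  p <- ckiPreset("dox")
  enumerateUnits(
    conditions = list(control = paste0("control:", seq_len(reps)),
                      treated = paste0("treated:", seq_len(reps))),
    channels = p$channels, thresholds = p$thresholds, minHits = p$minHits)
}

mgfFixturePath <- function() {
  system.file("extdata", "tiny.mgf", package = "cki", mustWork = TRUE)
}

tinyFixtureDir <- function() {
  system.file("extdata", "tiny_fixture", package = "cki", mustWork = TRUE)
}

# independent Yates chi-squared oracle (integer tables): stats::chisq.test
yatesOracle <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2)
  out <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(chi2 = unname(out$statistic), pvalue = unname(out$p.value))
}

# brute-force pairwise-concordance AUC
aucOracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  grid <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(grid)
}

# uncorrected 2x2 chi-squared: exactly homogeneous of degree 1 in the cells
chiUncorrected <- function(a, b, c, d) {
  Tt <- a + b + c + d
  Tt * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exhaustive hypergeometric tail via binomial coefficients
hyperOracle <- function(N, n, M, m, upper) {
  ms <- if (upper) m:n else 0:m
  sum(vapply(ms, function(mp) {
    if (mp > M || (n - mp) > (N - M)) return(0)
    choose(M, mp) * choose(N - M, n - mp) / choose(N, n)
  }, numeric(1)))
}
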