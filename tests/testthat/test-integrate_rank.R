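test_that("unit enumeration reproduces the four standard design sizes", {
  thr <- c(mrna = 0.01, intensity = 1e-5, network = 1e-5)
  # 3 conditions, 1 profile each, all condition level -> 9
  d9 <- enumerateUnits(
    conditions = list(g = "g:1", f2 = "f2:1", f5 = "f5:1"),
    channels = c(mrna = "condition", intensity = "condition",
                 network = "condition"),
    thresholds = thr, minHits = 5)
  expect_equal(nrow(designUnits(d9)), 9L)
  # 2 conditions, condition-level mRNA, 3v3 phospho -> 1 + 9 + 9 = 19
  d19 <- doxDesign()
  expect_equal(nrow(designUnits(d19)), 19L)
  expect_equal(as.integer(table(designUnits(d19)$evidence)[c("mrna", "intensity", "network")]),
               c(1L, 9L, 9L))
  # 2 conditions, 2v2 everywhere -> 12
  d12 <- enumerateUnits(
    conditions = list(control = paste0("control:", 1:2),
                      treated = paste0("treated:", 1:2)),
    channels = c(mrna = "replicate", intensity = "replicate",
                 network = "replicate"),
    thresholds = thr, minHits = 6)
  expect_equal(nrow(designUnits(d12)), 12L)
  # 2 conditions, 3v3 everywhere -> 27
  d27 <- enumerateUnits(
    conditions = list(control = paste0("control:", 1:3),
                      treated = paste0("treated:", 1:3)),
    channels = c(mrna = "replicate", intensity = "replicate",
                 network = "replicate"),
    thresholds = thr, minHits = 15)
  expect_equal(nrow(designUnits(d27)), 27L)
})

test_that("condition pairs are oriented later vs earlier", {
  d <- enumerateUnits(
    conditions = list(GFP = "GFP:1", FHH2 = "FHH2:1", FHH5 = "FHH5:1"),
    channels = c(mrna = "condition"),
    thresholds = c(mrna = 0.01, intensity = 1e-5, network = 1e-5),
    minHits = 1)
  expect_setequal(designUnits(d)$comparison_id,
                  c("FHH2_vs_GFP", "FHH5_vs_GFP", "FHH5_vs_FHH2"))
})

test_that("design validation catches bad inputs", {
  thr <- c(mrna = 0.01, intensity = 1e-5, network = 1e-5)
  expect_error(enumerateUnits(list(a = "a:1"), c(mrna = "condition"),
                              thr, 1), "two conditions")
  expect_error(enumerateUnits(list(a = paste0("a:", 1:2), b = "b:1"),
                              c(intensity = "condition"), thr, 1),
               "one sample per")
  expect_error(enumerateUnits(list(a = "a:1", b = "b:1"),
                              c(mrna = "condition"), thr, minHits = 5),
               "minHits")
})

mkResults <- function(df) {
  df$evidence <- sub(":.*$", "", df$unit_id)
  df$pvalue <- ifelse(df$significant, 1e-8, 0.5)
  df$direction <- 1
  df
}

test_that("hit counting applies the min-hits threshold at the boundary", {
  d9 <- enumerateUnits(
    conditions = list(g = "g:1", f2 = "f2:1", f5 = "f5:1"),
    channels = c(mrna = "condition", intensity = "condition",
                 network = "condition"),
    thresholds = c(mrna = 0.01, intensity = 1e-5, network = 1e-5),
    minHits = 5)
  uid <- designUnits(d9)$unit_id
  res <- mkResults(rbind(
    data.frame(kinase = "K5", unit_id = uid, significant = seq_along(uid) <= 5),
    data.frame(kinase = "K4", unit_id = uid, significant = seq_along(uid) <= 4)))
  out <- ckiTable(countHits(res, d9))
  expect_true(out$passes[out$kinase == "K5"])
  expect_false(out$passes[out$kinase == "K4"])
  expect_equal(out$hits[out$kinase == "K5"], 5L)
})

test_that("all-null p-values give zero hits everywhere", {
  d <- doxDesign()
  uid <- designUnits(d)$unit_id
  res <- mkResults(data.frame(kinase = "K1", unit_id = uid,
                              significant = FALSE))
  out <- ckiTable(countHits(res, d))
  expect_equal(out$hits, 0L)
  expect_false(any(out$passes))
})

test_that("duplicate (kinase, unit) results and foreign units are rejected", {
  d <- doxDesign()
  uid <- designUnits(d)$unit_id[1]
  res <- mkResults(data.frame(kinase = c("K1", "K1"), unit_id = uid,
                              significant = TRUE))
  expect_error(countHits(res, d), "duplicate result")
  res2 <- mkResults(data.frame(kinase = "K1", unit_id = "intensity:x_vs_y",
                               significant = TRUE))
  expect_error(countHits(res2, d), "not in the design")
})

test_that("ranking is by hits, then -log10 p sum, then symbol", {
  tb <- data.frame(kinase = c("K1", "K2", "K3"),
                   hits = c(7L, 5L, 7L),
                   sum_neglog10_p = c(40, 10, 55))
  ranked <- rankKinases(tb)
  expect_equal(ranked$kinase, c("K3", "K1", "K2"))
  expect_equal(ranked$rank, 1:3)
  tb2 <- data.frame(kinase = c("KB", "KA"), hits = c(3L, 3L),
                    sum_neglog10_p = c(5, 5))
  expect_equal(rankKinases(tb2)$kinase, c("KA", "KB"))
  expect_equal(rankKinases(tb2[1, , drop = FALSE])$rank, 1L)
})

test_that("the output ordering is invariant to input row order", {
  d <- doxDesign()
  uid <- designUnits(d)$unit_id
  set.seed(51)
  res <- expand.grid(kinase = sprintf("K%02d", 1:20),
                     unit_id = uid, stringsAsFactors = FALSE)
  res$significant <- runif(nrow(res)) < 0.3
  res <- mkResults(res)
  res$pvalue <- ifelse(res$significant, 10^-runif(nrow(res), 6, 12), 0.5)
  a <- ckiTable(countHits(res, d))
  b <- ckiTable(countHits(res[sample(nrow(res)), ], d))
  expect_equal(a, b)
})

test_that("relaxing a channel threshold never lowers any hit count", {
  d <- simulateCKIData(syntheticConfig(seed = 18, nKinases = 30, nSites = 400,
                                       edgesPerKinase = 10, nPlanted = 3,
                                       kappa = 3))
  p <- ckiPreset("dox")
  mk <- function(thr) {
    des <- enumerateUnits(
      conditions = list(control = paste0("control:", 1:3),
                        treated = paste0("treated:", 1:3)),
      channels = p$channels, thresholds = thr, minHits = 14)
    ckiTable(runCKI(d$profile, d$network, d$de, d$catalog, des))
  }
  strict <- mk(c(mrna = 0.001, intensity = 1e-7, network = 1e-7))
  loose <- mk(c(mrna = 0.05, intensity = 1e-3, network = 1e-3))
  m <- match(strict$kinase, loose$kinase)
  expect_true(all(loose$hits[m] >= strict$hits))
})

test_that("presets carry the printed thresholds and hit cutoffs", {
  expect_equal(ckiPreset("dox")$minHits, 14L)
  expect_equal(ckiPreset("genistein")$thresholds,
               c(mrna = 1e-4, intensity = 0.05, network = 0.01))
  expect_equal(ckiPreset("maturation")$minHits, 15L)
  expect_equal(ckiPreset("reprogramming")$minHits, 5L)
})

test_that("a null dataset passes almost no kinase at default thresholds", {
  passed <- integer(20)
  tested <- integer(20)
  for (s in 1:20) {
    d <- simulateCKIData(syntheticConfig(seed = 900 + s, nKinases = 40,
                                         nSites = 600, edgesPerKinase = 10,
                                         nPlanted = 0, kappa = 1))
    res <- runCKI(d$profile, d$network, d$de, d$catalog, doxDesign())
    tb <- ckiTable(res)
    passed[s] <- sum(tb$passes)
    tested[s] <- nrow(tb)
  }
  expect_lt(sum(passed) / sum(tested), 0.01)
})
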