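# a prediction table where the top `nPred` kinases pass
mkPredictions <- function(universe, predicted) {
  data.frame(kinase = universe,
             hits = ifelse(universe %in% predicted, 15L, 3L),
             sum_neglog10_p = 1,
             passes = universe %in% predicted)
}

test_that("benchmark counts the confusion matrix and Sn/Sp as defined", {
  universe <- sprintf("K%03d", 1:100)
  truth <- universe[1:10]
  predicted <- c(universe[1:8], universe[11:12])  # 8 true + 2 false
  bench <- benchmarkRanking(mkPredictions(universe, predicted), truth)
  expect_equal(bench$counts, c(TP = 8L, FP = 2L, FN = 2L, TN = 88L))
  expect_equal(bench$sn, 0.8)
  expect_equal(bench$sp, 88 / 90)
  expect_equal(unname(bench$fractions["known", ]), c(0.8, 0.2))
  expect_equal(unname(rowSums(bench$fractions)), c(1, 1))
})

test_that("predicting exactly the truth gives Sn = Sp = AUC = 1", {
  universe <- sprintf("K%03d", 1:30)
  truth <- universe[1:5]
  bench <- benchmarkRanking(mkPredictions(universe, truth), truth)
  expect_equal(bench$sn, 1)
  expect_equal(bench$sp, 1)
  expect_equal(auc(bench$roc), 1)
})

test_that("all-equal scores give AUC 0.5", {
  universe <- sprintf("K%03d", 1:30)
  tb <- data.frame(kinase = universe, hits = 5L, sum_neglog10_p = 1,
                   passes = FALSE)
  bench <- benchmarkRanking(tb, universe[1:5])
  expect_equal(auc(bench$roc), 0.5)
})

test_that("benchmark AUC equals brute-force concordance; relabeling is neutral", {
  set.seed(61)
  universe <- sprintf("K%03d", 1:60)
  tb <- data.frame(kinase = universe,
                   hits = sample(0:19, 60, replace = TRUE),
                   sum_neglog10_p = 1, passes = FALSE)
  tb$passes <- tb$hits >= 14
  truth <- sample(universe, 12)
  bench <- benchmarkRanking(tb, truth)
  expect_equal(auc(bench$roc),
               aucOracle(tb$hits, universe %in% truth), tolerance = 1e-12)
  # confusion counts sum to the universe size
  expect_equal(sum(bench$counts), 60)
  # permuting the table rows changes nothing
  perm <- sample(nrow(tb))
  bench2 <- benchmarkRanking(tb[perm, ], truth)
  expect_equal(bench2$counts, bench$counts)
  expect_equal(auc(bench2$roc), auc(bench$roc))
})

test_that("universe kinases absent from the result score zero hits", {
  tb <- mkPredictions(c("K1", "K2"), "K1")
  bench <- benchmarkRanking(tb, "K1", universe = c("K1", "K2", "K3"))
  expect_equal(sum(bench$counts), 3)
  expect_error(benchmarkRanking(tb, "KX"), "no truth kinase")
  expect_error(benchmarkRanking(tb, c("K1", "K2")), "no negative")
})

test_that("kinase expression vs substrate intensity correlation per edge", {
  p <- profileFromMatrix(matrix(c(10, 5, 20, 6, 30, 7, 40, 8), 2, 4,
                                dimnames = list(NULL, paste0("s:", 1:4))))
  net <- KSRNetwork(kinase = c("KUP", "KDN"),
                    accession = c("P001", "P002"),
                    position = c(5L, 6L), residue = c("S", "S"))
  expr <- matrix(c(1, 8, 2, 7, 3, 6, 4, 5), 2, 4,
                 dimnames = list(c("KUP", "KDN"), paste0("s:", 1:4)))
  out <- ksrExpressionCorrelation(expr, p, net)
  rho <- out$edges$rho[match(c("KUP", "KDN"), out$edges$kinase)]
  expect_equal(rho, c(1, -1))   # monotone up, anti-ranked down
  expect_equal(out$average, 0)
})

test_that("null expression/intensity data averages near zero correlation", {
  set.seed(62)
  n <- 100
  p <- profileFromMatrix(matrix(runif(n * 6, 1, 100), n, 6,
                                dimnames = list(NULL, paste0("s:", 1:6))))
  sk <- siteKeys(p)
  net <- KSRNetwork(data.frame(kinase = sprintf("K%03d", 1:n), sk))
  expr <- matrix(runif(n * 6), n, 6,
                 dimnames = list(sprintf("K%03d", 1:n), paste0("s:", 1:6)))
  out <- ksrExpressionCorrelation(expr, p, net)
  expect_lt(abs(out$average), 0.1)
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  set.seed(63)
  mat <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  mat[, 4] <- mat[, 3]                      # duplicated sample
  cc <- sampleCorrelation(mat)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(cc["s3", "s4"], 1)
  expect_equal(sampleCorrelation(cbind(a = 1:5, b = 5:1))["a", "b"], -1)
  # matches per-pair Spearman
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(cc[i, j], cor(mat[, i], mat[, j], method = "spearman"))
})

test_that("sample pairs with under 3 complete features are flagged NA", {
  mat <- matrix(c(1, 2, 3, 4, 5, NA, NA, 2, NA, NA, 7, 1), 6, 2)
  expect_warning(cc <- sampleCorrelation(mat), "fewer than 3")
  expect_true(is.na(cc[1, 2]))
})
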