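test_that("Yates chi-squared matches hand-evaluated tables", {
  expect_equal(yatesChi2(10, 0, 0, 10)$chi2, 16.2)
  r <- yatesChi2(5, 5, 5, 5)
  expect_equal(r$chi2, 0)
  expect_equal(r$pvalue, 1)
  # continuity correction floors |ad - bc| - T/2 at zero
  expect_equal(yatesChi2(2, 1, 1, 2)$chi2, 0)
})

test_that("degenerate margins give chi2 0, p 1, never an error", {
  for (tab in list(c(0, 0, 5, 5), c(5, 0, 5, 0), c(0, 0, 0, 0))) {
    r <- yatesChi2(tab[1], tab[2], tab[3], tab[4])
    expect_true(r$degenerate)
    expect_equal(r$chi2, 0)
    expect_equal(r$pvalue, 1)
  }
})

test_that("chi-squared is invariant under column swap and transposition", {
  set.seed(31)
  for (i in 1:50) {
    t <- runif(4, 0, 50)
    r0 <- yatesChi2(t[1], t[2], t[3], t[4])
    expect_equal(yatesChi2(t[2], t[1], t[4], t[3])$chi2, r0$chi2)
    expect_equal(yatesChi2(t[1], t[3], t[2], t[4])$chi2, r0$chi2)
  }
})

test_that("chi-squared agrees with the chisq.test oracle on 1000 random tables", {
  set.seed(32)
  for (i in 1:1000) {
    t <- sample(0:40, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
        t[1] + t[3] == 0 || t[2] + t[4] == 0) next
    mine <- yatesChi2(t[1], t[2], t[3], t[4])
    orac <- yatesOracle(t[1], t[2], t[3], t[4])
    expect_equal(mine$chi2, orac$chi2, tolerance = 1e-9)
    expect_equal(mine$pvalue, orac$pvalue, tolerance = 1e-9)
  }
})

test_that("chi-squared accepts real-valued cells", {
  r <- yatesChi2(50.25, 10.5, 949.75, 989.5)
  expect_gt(r$chi2, 0)
  expect_lt(r$pvalue, 1)
})

test_that("hypergeometric enrichment matches the worked examples", {
  h <- hypergeomEnrichment(N = 10, n = 5, M = 4, m = 4)
  expect_equal(h$e_ratio, 2)
  expect_equal(h$pvalue, 6 / 252)
  expect_equal(h$side, "over")
  h <- hypergeomEnrichment(N = 100, n = 10, M = 50, m = 5)
  expect_equal(h$e_ratio, 1)
  h <- hypergeomEnrichment(N = 10, n = 5, M = 5, m = 0)
  expect_equal(h$e_ratio, 0)
  expect_equal(h$pvalue, 1 / 252)
  expect_equal(h$side, "under")
  expect_error(hypergeomEnrichment(10, 0, 5, 0), "undefined")
})

test_that("hypergeometric p equals exhaustive enumeration for N <= 60", {
  set.seed(33)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    n <- sample(1:N, 1)
    M <- sample(1:N, 1)
    m <- sample(0:min(n, M), 1)
    h <- hypergeomEnrichment(N, n, M, m)
    expect_equal(h$pvalue,
                 min(1, max(hyperOracle(N, n, M, m, h$side == "over"),
                            .Machine$double.xmin)),
                 tolerance = 1e-12)
  }
})

test_that("upper summation terms beyond M contribute zero mass", {
  # n > M: impossible m' values in the upper tail are silently zero
  h <- hypergeomEnrichment(N = 20, n = 10, M = 3, m = 3)
  expect_equal(h$pvalue, hyperOracle(20, 10, 3, 3, TRUE), tolerance = 1e-12)
})

test_that("ROC/AUC matches the worked examples", {
  expect_equal(auc(rocAuc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_equal(auc(rocAuc(c(1, 1), c(TRUE, FALSE))), 0.5)
  expect_equal(auc(rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))), 0.75)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "negative")
  expect_error(rocAuc(1:3, c(FALSE, FALSE, FALSE)), "positive")
})

test_that("AUC equals brute-force pairwise concordance and trapezoid area", {
  set.seed(34)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    scores <- sample(0:15, n, replace = TRUE)  # heavy ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- rocAuc(scores, labels)
    expect_equal(auc(r), aucOracle(scores, labels), tolerance = 1e-12)
    pts <- rocPoints(r)
    trap <- sum(diff(pts[, "fpr"]) *
                  (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
    expect_equal(auc(r), trap, tolerance = 1e-12)
  }
})

test_that("ROC endpoints are (0,0) and (1,1); label shuffles average to 0.5", {
  set.seed(35)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), each = 20)
  pts <- rocPoints(rocAuc(scores, labels))
  expect_equal(unname(pts[1, ]), c(0, 0))
  expect_equal(unname(pts[nrow(pts), ]), c(1, 1))
  shuffled <- replicate(100, auc(rocAuc(scores, sample(labels))))
  expect_lt(abs(mean(shuffled) - 0.5), 0.05)
})

test_that("sensitivity and specificity follow their definitions", {
  expect_equal(unname(snSp(8, 2, 9, 1)), c(0.8, 0.9))
  expect_equal(unname(snSp(0, 5, 5, 0)), c(0, 1))
  expect_equal(unname(snSp(10, 0, 0, 10)), c(1, 0))
  expect_error(snSp(0, 0, 5, 5), "positive")
  expect_error(snSp(5, 5, 0, 0), "negative")
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearmanRho(1:4, c(40, 30, 20, 10)), -1)
  expect_true(is.na(spearmanRho(c(1, 1, 1), c(1, 2, 3))))
  set.seed(36)
  for (i in 1:20) {
    x <- sample(1:8, 10, replace = TRUE)  # ties exercised
    y <- sample(1:8, 10, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearmanRho(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("term enrichment composes the hypergeometric test over terms", {
  ann <- data.frame(
    gene = c("A", "B", "C", "D", "E", "F", "A", "B"),
    term_id = c(rep("T1", 6), "T2", "T2"),
    term_name = c(rep("term one", 6), "term two", "term two"))
  out <- enrichTerms(c("A", "B"), ann)
  t2 <- out[out$term_id == "T2", ]
  expect_equal(t2$m, 2L)
  expect_equal(t2$e_ratio, (2 / 2) / (2 / 6))
  expect_equal(t2$pvalue, hyperOracle(6, 2, 2, 2, TRUE), tolerance = 1e-12)
  expect_true(all(out$padj >= out$pvalue - 1e-15))
})
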