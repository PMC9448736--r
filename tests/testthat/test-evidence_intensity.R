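test_that("TSI sums square roots over quantified substrate sites", {
  p <- profileFromMatrix(matrix(c(4, 9, 25), 3, 1,
                                dimnames = list(NULL, "a:1")))
  net <- fullNetwork(p, "K1")
  tsi <- computeTsi(p, net)
  expect_equal(unname(tsiMatrix(tsi)["K1", "a:1"]), 2 + 3 + 5)
})

test_that("missing and zero cells are excluded from TSI", {
  p <- profileFromMatrix(matrix(c(4, NA), 2, 1, dimnames = list(NULL, "a:1")))
  net <- fullNetwork(p, "K1")
  expect_equal(unname(tsiMatrix(computeTsi(p, net))["K1", "a:1"]), 2)
  expect_equal(unname(computeTsi(p, net)@nSites["K1", "a:1"]), 1L)
})

test_that("a shared site contributes to every targeting kinase and the totals", {
  p <- profileFromMatrix(matrix(16, 1, 1, dimnames = list(NULL, "a:1")))
  net <- fullNetwork(p, c("K1", "K2"))
  tsi <- computeTsi(p, net)
  expect_equal(unname(tsiMatrix(tsi)[, "a:1"]), c(4, 4))
  expect_equal(unname(tsiTotals(tsi)["a:1"]), 8)
})

test_that("per-sample totals equal the sum of per-kinase TSI values", {
  d <- simulateCKIData(syntheticConfig(seed = 13, nKinases = 12, nSites = 150,
                                       edgesPerKinase = 8, nPlanted = 2))
  tsi <- computeTsi(d$profile, d$network)
  expect_equal(tsiTotals(tsi), colSums(tsiMatrix(tsi)))
})

test_that("the intensity test reproduces the hand-evaluated contingency table", {
  # TSI_A(i)=50, TSI_B(i)=10, totals 1000/1000 -> chi2 ~ 26.13, direction +1
  p <- profileFromMatrix(matrix(c(2500, 950^2, 100, 990^2), 2, 2,
                                dimnames = list(NULL, c("a:1", "b:1"))))
  net <- KSRNetwork(kinase = c("KI", "KO"), accession = c("P001", "P002"),
                    position = c(5L, 6L), residue = c("S", "S"))
  tsi <- computeTsi(p, net)
  r <- intensityTest(tsi, "KI", "a:1", "b:1")
  expect_equal(unlist(r[, c("a", "b", "c", "d")]),
               c(a = 50, b = 10, c = 950, d = 990))
  expect_equal(r$chi2, yatesChi2(50, 10, 950, 990)$chi2, tolerance = 1e-12)
  expect_equal(round(r$chi2, 2), 26.13)
  expect_equal(r$direction, 1)
})

test_that("equal TSI shares give chi2 0, p 1, not significant", {
  p <- profileFromMatrix(matrix(c(4, 100, 4, 100), 2, 2,
                                dimnames = list(NULL, c("a:1", "b:1"))))
  net <- KSRNetwork(kinase = c("KI", "KO"), accession = c("P001", "P002"),
                    position = c(5L, 6L), residue = c("S", "S"))
  r <- intensityTest(computeTsi(p, net), "KI", "a:1", "b:1")
  expect_equal(r$chi2, 0)
  expect_equal(r$pvalue, 1)
  expect_false(r$significant)
})

test_that("swapping the samples preserves chi2 and p and negates direction", {
  d <- simulateCKIData(syntheticConfig(seed = 14, nKinases = 10, nSites = 120,
                                       edgesPerKinase = 6, nPlanted = 2))
  tsi <- computeTsi(d$profile, d$network)
  ab <- suppressMessages(intensityTests(tsi, "control:1", "treated:1"))
  ba <- suppressMessages(intensityTests(tsi, "treated:1", "control:1"))
  m <- match(ab$kinase, ba$kinase)
  expect_equal(ab$chi2, ba$chi2[m], tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue[m], tolerance = 1e-12)
  expect_equal(ab$direction, -ba$direction[m])
})

test_that("cell scaling: exact degree-1 homogeneity without correction, asymptotic with", {
  set.seed(42)
  for (i in 1:30) {
    cells <- runif(4, 1, 100)
    k <- runif(1, 0.1, 20)
    # the uncorrected statistic scales exactly
    expect_equal(chiUncorrected(k * cells[1], k * cells[2], k * cells[3],
                                k * cells[4]),
                 k * chiUncorrected(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  # the continuity-corrected statistic scales to within the correction's
  # share, which vanishes as the cells grow
  for (i in 1:20) {
    cells <- runif(4, 5e3, 5e4)
    k <- runif(1, 0.5, 10)
    base <- yatesChi2(cells[1], cells[2], cells[3], cells[4])$chi2
    scaled <- yatesChi2(k * cells[1], k * cells[2], k * cells[3],
                        k * cells[4])$chi2
    if (base > 10) expect_equal(scaled / (k * base), 1, tolerance = 0.02)
  }
})

test_that("raising a kinase's substrate intensity in A never lowers its chi2 while up", {
  set.seed(43)
  for (i in 1:20) {
    mat <- matrix(runif(20, 100, 1e4), 10, 2,
                  dimnames = list(NULL, c("a:1", "b:1")))
    p <- profileFromMatrix(mat)
    sk <- siteKeys(p)
    net <- KSRNetwork(rbind(
      data.frame(kinase = "KI", sk[1:3, ]),
      data.frame(kinase = "KO", sk[4:10, ])))
    chi <- numeric(0)
    for (mult in c(1, 2, 4, 8, 16)) {
      m2 <- mat
      m2[1:3, "a:1"] <- mat[1:3, "a:1"] * mult
      r <- intensityTest(computeTsi(profileFromMatrix(m2), net),
                         "KI", "a:1", "b:1")
      if (r$direction >= 0) chi <- c(chi, r$chi2)
    }
    expect_true(all(diff(chi) >= -1e-9))
  }
})

test_that("kinases with no quantified substrate site in either sample are excluded", {
  mat <- matrix(c(4, NA, 9, NA), 2, 2, dimnames = list(NULL, c("a:1", "b:1")))
  p <- profileFromMatrix(mat)
  sk <- siteKeys(p)
  net <- KSRNetwork(rbind(data.frame(kinase = "K1", sk[1, ]),
                          data.frame(kinase = "K2", sk[2, ])))
  tsi <- computeTsi(p, net)
  expect_message(out <- intensityTests(tsi, "a:1", "b:1"), "excluded")
  expect_equal(out$kinase, "K1")
  expect_error(suppressMessages(intensityTest(tsi, "K2", "a:1", "b:1")),
               "no quantified substrate site")
})
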