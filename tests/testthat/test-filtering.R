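test_that("fold changes are means of log2 ratios against baseline", {
  shifts <- matrix(c(0, 0, 0, 0,
                     0, 0, 1, 0,
                     0, -2, -2, -2), 3, byrow = TRUE,
                   dimnames = list(c("flat", "up7", "down"), NULL))
  qt <- makeShiftedQuant(shifts, noise = 0)
  fc <- computeFoldChanges(qt)
  get <- function(p, t) fc$log2FoldChange[fc$proteinId == p & fc$timePoint == t]
  expect_equal(get("flat", 7), 0)
  expect_equal(get("up7", 7), 1)    # abundance doubled at 7 min
  expect_equal(get("up7", 15), 0)
  expect_equal(get("down", 2), -2)
  expect_true(all(fc$evaluable))
})

test_that("missing baseline replicates flag cells as not-evaluable", {
  qt <- makeShiftedQuant(matrix(0, 1, 4, dimnames = list("p", NULL)),
                         noise = 0)
  ab <- SummarizedExperiment::assay(qt, "abundance")
  ab[1, 1:2] <- NA   # leaves a single baseline replicate
  SummarizedExperiment::assay(qt, "abundance") <- ab
  fc <- computeFoldChanges(qt)
  expect_true(all(!fc$evaluable))
  expect_true(all(is.na(fc$log2FoldChange)))

  # baseline time point entirely absent -> error
  qt2 <- qt[, SummarizedExperiment::colData(qt)$timePoint != 0]
  expect_error(computeFoldChanges(qt2), "baseline")
})

test_that("ANOVA p matches an independent hand computation", {
  vals <- anovaFixtureValues()
  shifts <- matrix(0, 1, 4, dimnames = list("p", NULL))
  qt <- makeShiftedQuant(shifts, noise = 0)
  ab <- SummarizedExperiment::assay(qt, "abundance")
  ab[1, ] <- 2^vals
  SummarizedExperiment::assay(qt, "abundance") <- ab

  sig <- computeSignificance(qt)
  # hand-computed F statistic from sums of squares, then the F tail
  g <- rep(1:4, each = 3)
  m <- tapply(vals, g, mean); gm <- mean(vals)
  ssb <- sum(3 * (m - gm)^2)
  ssw <- sum((vals - m[g])^2)
  Fhand <- (ssb / 3) / (ssw / 8)
  expect_equal(Fhand, 8.833903, tolerance = 1e-6)
  expect_equal(unique(sig$pAnova), 1 - stats::pf(Fhand, 3, 8),
               tolerance = 1e-12)
})

test_that("identical groups give p = 1 and degenerate groups never give 0", {
  qt <- makeShiftedQuant(matrix(0, 1, 4, dimnames = list("p", NULL)),
                         noise = 0)
  ab <- SummarizedExperiment::assay(qt, "abundance")
  ab[1, ] <- 2^rep(c(19, 20, 21), 4)   # every group identical -> F = 0
  SummarizedExperiment::assay(qt, "abundance") <- ab
  sig <- computeSignificance(qt)
  expect_equal(unique(sig$pAnova), 1)

  # all values identical: zero variance everywhere -> not-evaluable, never 0
  ab[1, ] <- 2^20
  SummarizedExperiment::assay(qt, "abundance") <- ab
  sig2 <- computeSignificance(qt)
  expect_true(all(is.na(sig2$pAnova)))
  expect_true(all(is.na(sig2$pT)))
})

test_that("Welch t-test p matches the t CDF by hand", {
  set.seed(31)
  qt <- makeShiftedQuant(matrix(c(0, 1, 1, 1), 1,
                                dimnames = list("p", NULL)),
                         noise = 0.4, seed = 31)
  la <- log2(SummarizedExperiment::assay(qt, "abundance"))
  tp <- SummarizedExperiment::colData(qt)$timePoint
  x <- la[1, tp == 0]; y <- la[1, tp == 7]
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tstat <- (mean(y) - mean(x)) / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  pHand <- 2 * stats::pt(-abs(tstat), df)
  sig <- computeSignificance(qt)
  expect_equal(sig$pT[sig$timePoint == 7], pHand, tolerance = 1e-12)
})

test_that("the filter cascade keeps exactly the planted candidates", {
  set.seed(32)
  n <- 20
  shifts <- matrix(0, n, 4,
                   dimnames = list(sprintf("prot%02d", 1:n), NULL))
  planted <- c("prot03", "prot07", "prot11", "prot19")
  shifts["prot03", ] <- c(0, 2.5, 0, 0)       # early
  shifts["prot07", ] <- c(0, 0.8, 1.6, 2.4)   # progressive
  shifts["prot11", ] <- c(0, -2, -2, -2)      # dissociating
  shifts["prot19", ] <- c(0, 0, 2.2, 0)       # intermediate
  qt <- makeShiftedQuant(shifts, noise = 0.2, seed = 32)
  diffs <- computeDifferentials(qt)
  cand <- applyFilters(diffs, qt, contaminants = NULL,
                       spec = filterSpec(maxContaminantCategory = NA))
  expect_setequal(cand$proteinId, planted)

  # vacuous thresholds admit every quantified protein
  allIn <- applyFilters(diffs, qt, contaminants = NULL,
                        spec = filterSpec(minAbsLog2Fc = 0, maxP = 1,
                                          maxContaminantCategory = NA))
  expect_setequal(allIn$proteinId, rownames(qt))
})

test_that("exclusion reasons name the failed criterion", {
  shifts <- matrix(c(0, 2, 2, 2), 1, byrow = TRUE,
                   dimnames = list("hit", NULL))
  qt <- makeShiftedQuant(shifts, noise = 0.1, seed = 33)
  diffs <- computeDifferentials(qt)
  contam <- data.frame(proteinId = "hit", count = 100L,
                       percent = 100 * 100 / 411,
                       category = factor("<=100%",
                                         levels = c("<=1%", "<=10%", "<=100%"),
                                         ordered = TRUE),
                       absent = FALSE)
  cand <- applyFilters(diffs, qt, contam, filterSpec())
  expect_equal(nrow(cand), 0L)
  excl <- attr(cand, "excluded")
  expect_equal(excl$reason[excl$proteinId == "hit"], "contaminant")
})

test_that("tightening any threshold never adds candidates", {
  set.seed(34)
  sim <- simulateTimecourse(simulationConfig(nProteins = 100, seed = 34))
  qt <- normalizeAbundances(sim$quant)
  diffs <- computeDifferentials(qt)
  repo <- simulateContaminantRepository(sim$truth, 411L)
  ann <- annotateContaminants(sim$truth$proteinId, repo)
  loose <- applyFilters(diffs, qt, ann,
                        filterSpec(minAbsLog2Fc = 0.5, maxP = 0.2,
                                   maxContaminantCategory = "<=100%"))
  for (sp in list(filterSpec(minAbsLog2Fc = 1.5, maxP = 0.2,
                             maxContaminantCategory = "<=100%"),
                  filterSpec(minAbsLog2Fc = 0.5, maxP = 0.01,
                             maxContaminantCategory = "<=100%"),
                  filterSpec(minAbsLog2Fc = 0.5, maxP = 0.2,
                             maxContaminantCategory = "<=1%"),
                  filterSpec(minUniquePeptides = 3L, minAbsLog2Fc = 0.5,
                             maxP = 0.2,
                             maxContaminantCategory = "<=100%"))) {
    tight <- applyFilters(diffs, qt, ann, sp)
    expect_true(all(tight$proteinId %in% loose$proteinId))
  }
})

test_that("temporal patterns classify by passing points and monotonicity", {
  tps <- c(2, 7, 15)
  expect_equal(classifyTemporalPattern(tps, c(TRUE, FALSE, FALSE),
                                       c(2, 0.3, 0.1)), "early")
  expect_equal(classifyTemporalPattern(tps, c(FALSE, TRUE, FALSE),
                                       c(0.3, 2, 0.4)), "intermediate")
  expect_equal(classifyTemporalPattern(tps, c(FALSE, FALSE, TRUE),
                                       c(0.1, 0.5, 2)), "late")
  # monotone increasing, passing at 7 and 15 -> latest passing point
  expect_equal(classifyTemporalPattern(tps, c(FALSE, TRUE, TRUE),
                                       c(0.5, 1.4, 2.1)), "late")
  # non-monotone multi-pass -> mixed
  expect_equal(classifyTemporalPattern(tps, c(TRUE, FALSE, TRUE),
                                       c(2, 0.2, 1.8)), "mixed")
  expect_equal(classifyTemporalPattern(tps, c(TRUE, TRUE, TRUE),
                                       c(-2, -1.5, -1.2)), "dissociating")
  expect_true(is.na(classifyTemporalPattern(tps, c(FALSE, FALSE, FALSE),
                                            c(0, 0, 0))))
})

test_that("volcano table transforms coordinates and drops unevaluable rows", {
  diffs <- data.frame(
    proteinId = c("a", "b", "c"), timePoint = 7,
    log2FoldChange = c(1, 0.5, NA), evaluable = c(TRUE, TRUE, FALSE),
    pT = c(0.01, 1, NA), pAnova = c(0.02, 0.9, NA))
  vt <- volcanoTable(diffs)
  expect_equal(nrow(vt), 2L)
  expect_equal(vt$negLog10P[vt$proteinId == "a"], 2)
  expect_equal(vt$log2FoldChange[vt$proteinId == "a"], 1)
  expect_equal(vt$negLog10P[vt$proteinId == "b"], 0)
  expect_equal(attr(vt, "omitted"), 1L)

  empty <- volcanoTable(diffs[0, ])
  expect_equal(nrow(empty), 0L)
})
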