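test_that("quant CSV parsing decodes the run-header grammar", {
  set.seed(1)
  qt <- makeQuantFixture()
  path <- tempfile(fileext = ".csv")
  writeQuantCSV(qt, path)
  back <- readQuantCSV(path)
  expect_equal(dim(back), c(5L, 12L))
  cd <- as.data.frame(SummarizedExperiment::colData(back))
  expect_equal(cd$timePoint[cd$runId == "t7_rep2"], 7L)
  expect_equal(cd$replicate[cd$runId == "t7_rep2"], 2L)
  expect_equal(sort(unique(cd$timePoint)), c(0L, 2L, 7L, 15L))
})

test_that("quant parsing rejects invariant violations", {
  base <- data.frame(accession = c("P1", "P2"), gene_symbol = c("A", "B"),
                     unique_peptides = 2L, quantified_peptides = 3L)

  bad1 <- cbind(base, `run-one` = c(1, 2)); names(bad1)[5] <- "run-one"
  f1 <- tempfile(fileext = ".csv")
  utils::write.table(bad1, f1, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(readQuantCSV(f1), "run-one")

  bad2 <- cbind(base, t0_rep1 = c(-5, 2), t0_rep2 = c(1, 1))
  f2 <- tempfile(fileext = ".csv")
  utils::write.table(bad2, f2, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(readQuantCSV(f2), "negative")

  bad3 <- cbind(base, t0_rep1 = c(1, 2))
  bad3$accession <- c("P1", "P1")
  f3 <- tempfile(fileext = ".csv")
  utils::write.table(bad3, f3, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(readQuantCSV(f3), "duplicate accession")
})

test_that("write(read(x)) is bit-identical for the canonical dialect", {
  set.seed(2)
  qt <- makeQuantFixture()
  p1 <- tempfile(fileext = ".csv")
  writeQuantCSV(qt, p1)
  p2 <- tempfile(fileext = ".csv")
  writeQuantCSV(readQuantCSV(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("identification filter applies the probability rule at the boundary", {
  set.seed(3)
  qt <- makeQuantFixture()
  kept <- rownames(applyIdentificationFilter(qt))
  # P1: 12 peptides all 0.99, prob 1 -> kept
  # P2: peptides (0.95, 0.91, 0.40): two validated >= 0.90, protein 0.995 -> kept
  # P3: 1 unique peptide -> removed
  # P4: probabilities exactly at 0.90/0.99 boundaries -> kept (inclusive)
  # P5: only one peptide >= 0.90, protein 0.95 -> removed
  expect_setequal(kept, c("P1", "P2", "P4"))

  # without probability columns only the peptide-count rule applies
  rd <- SummarizedExperiment::rowData(qt)
  rd$proteinProbability <- NULL
  rd$peptideProbabilities <- NULL
  SummarizedExperiment::rowData(qt) <- rd
  expect_warning(kept2 <- rownames(applyIdentificationFilter(qt)),
                 "unique-peptide rule only")
  expect_setequal(kept2, c("P1", "P2", "P4", "P5"))

  empty <- makeQuantFixture()[0, ]
  expect_equal(nrow(applyIdentificationFilter(empty)), 0L)
})

test_that("quantification filter is boundary-inclusive and idempotent", {
  set.seed(4)
  qt <- makeQuantFixture()
  kept <- rownames(applyQuantificationFilter(qt))
  # quantified peptides (15, 3, 2, 4, 3): the count-2 protein drops
  expect_setequal(kept, c("P1", "P2", "P4", "P5"))
  once <- applyQuantificationFilter(qt)
  twice <- applyQuantificationFilter(once)
  expect_equal(rownames(twice), rownames(once))
})

test_that("identification and quantification filters commute", {
  set.seed(5)
  qt <- makeQuantFixture()
  ab <- suppressWarnings(
    applyQuantificationFilter(applyIdentificationFilter(qt)))
  ba <- suppressWarnings(
    applyIdentificationFilter(applyQuantificationFilter(qt)))
  expect_equal(rownames(ab), rownames(ba))
})

test_that("normalisation removes per-run scaling and is a fixed point", {
  set.seed(6)
  qt <- makeShiftedQuant(matrix(0, 6, 4,
                                dimnames = list(paste0("P", 1:6), NULL)),
                         noise = 0.3, seed = 6)
  ab <- SummarizedExperiment::assay(qt, "abundance")

  # doubling one run is undone exactly
  doubled <- ab; doubled[, 3] <- doubled[, 3] * 2
  qt2 <- qt; SummarizedExperiment::assay(qt2, "abundance") <- doubled
  n1 <- SummarizedExperiment::assay(normalizeAbundances(qt), "abundance")
  n2 <- SummarizedExperiment::assay(normalizeAbundances(qt2), "abundance")
  expect_equal(n1, n2, tolerance = 1e-9)

  # per-run median log-ratio to the stored pseudo-reference is zero
  qn <- normalizeAbundances(qt)
  la <- log2(SummarizedExperiment::assay(qn, "abundance"))
  ref <- S4Vectors::metadata(qn)$pseudoReference
  f <- apply(la, 2, function(col) stats::median(col - ref))
  expect_true(all(abs(f) < 1e-9))

  # already-normalised input is unchanged
  n3 <- SummarizedExperiment::assay(
    normalizeAbundances(normalizeAbundances(qt)), "abundance")
  expect_equal(n3, n1, tolerance = 1e-9)
})

test_that("normalisation flags degenerate runs", {
  set.seed(7)
  qt <- makeQuantFixture()
  ab <- SummarizedExperiment::assay(qt, "abundance")
  ab[, 2] <- NA
  SummarizedExperiment::assay(qt, "abundance") <- ab
  expect_error(normalizeAbundances(qt), "t0_rep2")

  single <- qt[, 1]
  expect_equal(normalizeAbundances(single), single)
})

test_that("spectral-count tables read as integer matrices", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(protein = c("P1", "P2"), t0_rep1 = c(10L, 0L),
               t0_rep2 = c(8L, 1L)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- readSpectralCounts(path)
  expect_true(is.integer(m))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["P1", "t0_rep1"], 10L)
})
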