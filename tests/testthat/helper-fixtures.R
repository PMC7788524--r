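## Fixture builders shared across the suite. Everything is generated in code;
## nothing is read from disk except files these helpers write to tempdirs.

writeBiogridFixture <- function(path = tempfile(fileext = ".tsv")) {
  ## 10 rows, exactly 3 involving the bait INSR
  tab <- data.frame(
    `Official Symbol Interactor A` = c("INSR", "IRS1", "GRB2", "INSR", "SHC1",
                                       "Insr", "GRB10", "SOS1", "PIK3R1", "CBL"),
    `Official Symbol Interactor B` = c("IRS1", "PIK3R1", "SOS1", "SHC1", "GRB7",
                                       "Grb10", "RAF1", "HRAS", "PTEN", "EGFR"),
    `Experimental System` = c("Two-hybrid", "Affinity Capture-MS",
                              "Affinity Capture-MS", "Affinity Capture-Western",
                              "Two-hybrid", "Reconstituted Complex",
                              "Two-hybrid", "Two-hybrid",
                              "Affinity Capture-MS", "Affinity Capture-MS"),
    Throughput = c("Low Throughput", "High Throughput", "High Throughput",
                   "Low Throughput", "Low Throughput", "Low Throughput",
                   "High Throughput", "Low Throughput", "High Throughput",
                   "High Throughput"),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeStringFixture <- function(path = tempfile(fileext = ".tsv")) {
  ## duplicate (INSR, CAV1) rows exercise the keep-max dedup rule
  tab <- data.frame(
    protein1 = c("9606.INSR", "9606.INSR", "9606.INSR", "9606.IGF1R",
                 "9606.INSR"),
    protein2 = c("9606.IGF1R", "9606.CAV1", "9606.CAV1", "9606.IRS2",
                 "9606.IRS1"),
    combined_score = c(999, 420, 615, 800, 950),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## 5 proteins x 12 runs (4 time points x 3 replicates), with probability
## columns spanning the identification-filter boundaries.
makeQuantFixture <- function() {
  samples <- data.frame(
    runId = sprintf("t%d_rep%d", rep(c(0, 2, 7, 15), each = 3), rep(1:3, 4)),
    timePoint = rep(c(0L, 2L, 7L, 15L), each = 3),
    replicate = rep(1:3, 4), stringsAsFactors = FALSE)
  proteins <- data.frame(
    accession = paste0("P", 1:5),
    geneSymbol = c("INSR", "IRS1", "ACTB", "HSPA8", "GRB10"),
    uniquePeptides = c(12L, 3L, 1L, 2L, 2L),
    quantifiedPeptides = c(15L, 3L, 2L, 4L, 3L),
    proteinProbability = c(1, 0.995, 0.999, 0.99, 0.95),
    stringsAsFactors = FALSE)
  ab <- matrix(signif(2^stats::rnorm(60, 20, 1), 6), nrow = 5,
               dimnames = list(proteins$accession, samples$runId))
  qt <- QuantTable(ab, proteins, samples)
  SummarizedExperiment::rowData(qt)$peptideProbabilities <-
    IRanges::NumericList(list(
      rep(0.99, 12),
      c(0.95, 0.91, 0.40),
      c(0.99),
      c(0.90, 0.90),
      c(0.95, 0.89)))
  qt
}

## deterministic quant table with planted per-time mean shifts and no noise
makeShiftedQuant <- function(shifts, nReplicates = 3, noise = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tps <- c(0L, 2L, 7L, 15L)
  n <- nrow(shifts)
  samples <- data.frame(
    runId = sprintf("t%d_rep%d", rep(tps, each = nReplicates),
                    rep(seq_len(nReplicates), length(tps))),
    timePoint = rep(tps, each = nReplicates),
    replicate = rep(seq_len(nReplicates), length(tps)),
    stringsAsFactors = FALSE)
  la <- matrix(20, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    k <- match(samples$timePoint[j], tps)
    la[, j] <- 20 + shifts[, k] +
      (if (noise > 0) stats::rnorm(n, 0, noise) else 0)
  }
  proteins <- data.frame(
    accession = rownames(shifts), geneSymbol = rownames(shifts),
    uniquePeptides = 5L, quantifiedPeptides = 6L, stringsAsFactors = FALSE)
  QuantTable(2^la, proteins, samples)
}

## frozen 3-replicate x 4-group fixture for the ANOVA oracle checks
anovaFixtureValues <- function() {
  c(20.685, 19.718, 20.182, 20.716, 20.602, 20.347,
    21.656, 20.853, 21.909, 21.369, 22.052, 22.543)
}

## Build a complete set of pipeline input files from the simulators:
## the literature interactome's partners include known binders that are
## also present in the simulated dataset, so every stage has work to do.
makePipelineInputs <- function(dir, seed = 1L, nProteins = 120L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateTimecourse(simulationConfig(nProteins = nProteins,
                                             seed = seed))
  quantPath <- file.path(dir, "quant.csv")
  writeQuantCSV(sim$quant, quantPath)

  known <- sim$truth$proteinId[
    sim$truth$class == "progressive_association"][1:10]
  fix <- simulateInteractomeFixture(15, seed = seed,
                                    dir = file.path(dir, "interactome"),
                                    partnerIds = c(known,
                                                   sprintf("LIT%02d", 1:5)))
  repoPath <- file.path(dir, "repo.tsv")
  simulateContaminantRepository(sim$truth, 411L, repoPath)

  set.seed(seed + 1000L)
  ids <- sim$truth$proteinId
  edges <- unique(data.frame(
    protein_a = c(sample(known, 60, replace = TRUE)),
    protein_b = c(sample(ids, 60, replace = TRUE)),
    weight = round(runif(60, 0.2, 1), 3), stringsAsFactors = FALSE))
  edges <- edges[edges$protein_a != edges$protein_b, ]
  edgePath <- file.path(dir, "edges.tsv")
  utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(sim = sim, quantPath = quantPath, biogridPath = fix$biogridPath,
       stringPath = fix$stringPath, repoPath = repoPath,
       edgePath = edgePath, known = known)
}

runQuiet <- function(config) {
  suppressWarnings(suppressMessages(runAll(config)))
}
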