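#' @include AllClasses.R
NULL

.SIM_CLASSES <- c("progressive_association", "early_transient",
                  "dissociating", "flat_specific", "contaminant")

#' Simulation configuration for the synthetic AP-MS time course
#'
#' Defines the study conditions the generator emulates: a bait pulled down
#' over an insulin-stimulation time course of 0/2/7/15 minutes with
#' replicated label-free MS1 quantification. Prey classes follow the
#' qualitative recruitment patterns seen in bait time-course AP-MS:
#' progressive association (abundance rising to the full effect by 15 min),
#' early transient association (peak at 2 min, back to baseline by 15 min),
#' dissociation (drop immediately after stimulation), flat specific binders,
#' and high-frequency contaminants.
#'
#' @param nProteins number of simulated proteins.
#' @param classProportions named proportions over the five classes
#'   (must sum to 1); converted to integer counts by largest-remainder
#'   rounding.
#' @param nReplicates replicates per time point (>= 2).
#' @param timePoints minutes, strictly increasing from 0.
#' @param log2NoiseSd replicate noise standard deviation on the log2 scale
#'   (multiplicative on the raw scale).
#' @param effectLog2fc planted effect size e (log2 fold change at the full
#'   effect).
#' @param contaminantFrequencyRange integer range of repository counts for
#'   contaminant-class proteins.
#' @param repoTotal total control experiments in the simulated repository.
#' @param lowPeptideFrac fraction of flat/contaminant proteins planted below
#'   the 2-/3-peptide identification and quantification thresholds.
#' @param dropoutProb per-cell missingness probability (default 0).
#' @param seed RNG seed.
#' @return object of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nProteins = 200L,
                             classProportions = c(
                               progressive_association = 0.10,
                               early_transient = 0.05,
                               dissociating = 0.05,
                               flat_specific = 0.40,
                               contaminant = 0.40),
                             nReplicates = 3L,
                             timePoints = c(0L, 2L, 7L, 15L),
                             log2NoiseSd = 0.5,
                             effectLog2fc = 2,
                             contaminantFrequencyRange = c(42L, 411L),
                             repoTotal = 411L,
                             lowPeptideFrac = 0.1,
                             dropoutProb = 0,
                             seed = 1L) {
  stopifnot(nProteins >= 1L, nReplicates >= 2L,
            log2NoiseSd > 0, repoTotal >= 1L,
            lowPeptideFrac >= 0, lowPeptideFrac <= 1,
            dropoutProb >= 0, dropoutProb < 1)
  if (!setequal(names(classProportions), .SIM_CLASSES))
    stop("classProportions must be named over: ",
         paste(.SIM_CLASSES, collapse = ", "), call. = FALSE)
  if (abs(sum(classProportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (timePoints[1] != 0 || any(diff(timePoints) <= 0))
    stop("time points must be strictly increasing from 0", call. = FALSE)
  if (contaminantFrequencyRange[1] < floor(0.10 * repoTotal) + 1 ||
      contaminantFrequencyRange[2] > repoTotal)
    stop("contaminant frequency range must lie in the highest category",
         call. = FALSE)
  structure(list(
    nProteins = as.integer(nProteins),
    classProportions = classProportions[.SIM_CLASSES],
    nReplicates = as.integer(nReplicates),
    timePoints = as.integer(timePoints),
    log2NoiseSd = log2NoiseSd,
    effectLog2fc = effectLog2fc,
    contaminantFrequencyRange = as.integer(contaminantFrequencyRange),
    repoTotal = as.integer(repoTotal),
    lowPeptideFrac = lowPeptideFrac,
    dropoutProb = dropoutProb,
    seed = as.integer(seed)), class = "SimulationConfig")
}

## Class mean-shift templates over (0, 2, 7, 15) min, as multiples of the
## effect size e.
.classTemplate <- function(cls, e, nT) {
  tmpl <- switch(cls,
    progressive_association = c(0, e / 3, 2 * e / 3, e),
    early_transient = c(0, e, e / 3, 0),
    dissociating = c(0, -e, -e, -e),
    flat_specific = ,
    contaminant = rep(0, 4))
  if (nT != 4L) tmpl <- tmpl[seq_len(nT)]   # degenerate configs in tests
  tmpl
}

#' Simulate a label-free AP-MS time course with ground truth
#'
#' Per-protein baseline log2 abundance is drawn from Normal(20, 2); the class
#' template shifts the mean at each time point by multiples of the effect
#' size; replicate noise is i.i.d. Normal(0, \code{log2NoiseSd}) on the log2
#' scale. Unique peptide counts are 3 + Poisson(3) (quantified counts add
#' Poisson(2)); a planted fraction of the flat-specific and contaminant
#' classes falls below the 2-/3-peptide acceptance thresholds so the
#' identification and quantification filters are exercised. Contaminant-class
#' proteins receive repository counts inside
#' \code{contaminantFrequencyRange}; all others in [0, 4]. The same seed
#' yields byte-identical output.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return list with elements \code{quant}
#'   (\code{\linkS4class{QuantTable}}), \code{truth} (data.frame:
#'   \code{proteinId}, \code{class}, one \code{trueLog2Fc.t<min>} column per
#'   stimulated time point, \code{repoCount}, \code{lowPeptide}) and
#'   \code{config}.
#' @export
simulateTimecourse <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nProteins
  tps <- config$timePoints
  nT <- length(tps)
  reps <- config$nReplicates

  counts <- largestRemainder(config$classProportions, n)
  cls <- rep(names(counts), counts)
  ids <- sprintf("PROT%04d", seq_len(n))

  baseline <- stats::rnorm(n, mean = 20, sd = 2)
  shift <- t(vapply(cls, .classTemplate, numeric(nT),
                    e = config$effectLog2fc, nT = nT))

  runGrid <- expand.grid(replicate = seq_len(reps), timePoint = tps,
                         KEEP.OUT.ATTRS = FALSE)
  runGrid <- runGrid[order(runGrid$timePoint, runGrid$replicate), ]
  samples <- data.frame(
    runId = sprintf("t%d_rep%d", runGrid$timePoint, runGrid$replicate),
    timePoint = runGrid$timePoint,
    replicate = runGrid$replicate,
    stringsAsFactors = FALSE)

  la <- matrix(NA_real_, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    tIdx <- match(samples$timePoint[j], tps)
    la[, j] <- baseline + shift[, tIdx] +
      stats::rnorm(n, 0, config$log2NoiseSd)
  }
  ab <- 2^la
  if (config$dropoutProb > 0) {
    drop <- matrix(stats::runif(length(ab)) < config$dropoutProb,
                   nrow = n)
    ab[drop] <- NA
  }

  uniquePep <- 3L + stats::rpois(n, 3)
  quantPep <- uniquePep + stats::rpois(n, 2)
  lowPeptide <- rep(FALSE, n)
  eligible <- which(cls %in% c("flat_specific", "contaminant"))
  nLow <- round(config$lowPeptideFrac * length(eligible))
  if (nLow > 0) {
    lowIdx <- sample(eligible, nLow)
    lowPeptide[lowIdx] <- TRUE
    uniquePep[lowIdx] <- 1L
    quantPep[lowIdx] <- 2L
  }

  repoCount <- integer(n)
  isContam <- cls == "contaminant"
  rng <- config$contaminantFrequencyRange
  repoCount[isContam] <- sample(seq(rng[1], rng[2]), sum(isContam),
                                replace = TRUE)
  repoCount[!isContam] <- sample(0:4, sum(!isContam), replace = TRUE)

  proteins <- data.frame(
    accession = ids, geneSymbol = ids,
    uniquePeptides = uniquePep, quantifiedPeptides = quantPep,
    stringsAsFactors = FALSE)
  qt <- QuantTable(ab, proteins, samples)

  truth <- data.frame(proteinId = ids, class = cls,
                      stringsAsFactors = FALSE)
  for (k in seq_along(tps)[-1])
    truth[[sprintf("trueLog2Fc.t%d", tps[k])]] <- shift[, k]
  truth$repoCount <- repoCount
  truth$lowPeptide <- lowPeptide
  rownames(truth) <- NULL

  list(quant = qt, truth = truth, config = config)
}

#' Simulate BioGRID- and STRING-style interactome exports with known bands
#'
#' Writes a pair of database-export fixtures whose partners carry evidence
#' lists that deterministically imply a confidence band (1 record: low; 2-3:
#' medium; >3: high; links-table-only partners: low with the band floor
#' score). A fraction of partners appears in only one export to exercise the
#' union semantics of the merge.
#'
#' @param nPartners number of partner proteins (>= 1).
#' @param seed RNG seed.
#' @param dir output directory.
#' @param bait bait identifier.
#' @param partnerIds optional character vector of partner identifiers to use
#'   (length \code{nPartners}); defaults to generated \code{PART...} names.
#'   Useful for linking the fixture to a simulated quantification dataset.
#' @return list with \code{biogridPath}, \code{stringPath} and \code{truth}
#'   (data.frame: \code{partnerId}, \code{nEvidence}, \code{expectedBand},
#'   \code{source}).
#' @export
simulateInteractomeFixture <- function(nPartners, seed = 1L,
                                       dir = tempfile("interactome"),
                                       bait = "INSR", partnerIds = NULL) {
  if (nPartners < 1L) stop("nPartners must be >= 1", call. = FALSE)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  partners <- if (is.null(partnerIds)) {
    sprintf("PART%03d", seq_len(nPartners))
  } else {
    stopifnot(length(partnerIds) == nPartners)
    harmonizeId(partnerIds)
  }
  source <- sample(c("both", "biogrid-only", "string-only"), nPartners,
                   replace = TRUE, prob = c(0.5, 0.25, 0.25))
  if (all(source == "string-only")) source[1] <- "both"
  nEvidence <- ifelse(source == "string-only", 0L,
                      sample(1:12, nPartners, replace = TRUE))

  sysPool <- c("Affinity Capture-MS", "Two-hybrid", "Affinity Capture-Western",
               "FRET", "Kinase Activity", "Phosphatase Activity",
               "Reconstituted Complex")
  rows <- list()
  for (i in seq_len(nPartners)) {
    if (nEvidence[i] == 0L) next
    systems <- sample(sysPool, nEvidence[i], replace = TRUE)
    rows[[i]] <- data.frame(
      `Official Symbol Interactor A` = bait,
      `Official Symbol Interactor B` = partners[i],
      `Experimental System` = systems,
      Throughput = sample(c("Low Throughput", "High Throughput"),
                          nEvidence[i], replace = TRUE),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, rows)
  ## decoy row not involving the bait, to exercise the drop rule
  bg <- rbind(bg, data.frame(
    `Official Symbol Interactor A` = "GRB2",
    `Official Symbol Interactor B` = "SOS1",
    `Experimental System` = "Two-hybrid", Throughput = "Low Throughput",
    check.names = FALSE, stringsAsFactors = FALSE))
  biogridPath <- file.path(dir, "biogrid_export.tsv")
  utils::write.table(bg, biogridPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  inString <- source %in% c("both", "string-only")
  st <- data.frame(protein1 = bait, protein2 = partners[inString],
                   combined_score = sample(150:999, sum(inString),
                                           replace = TRUE))
  stringPath <- file.path(dir, "string_links.tsv")
  utils::write.table(st, stringPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expectedBand <- ifelse(nEvidence == 0L, "low",
                  ifelse(nEvidence == 1L, "low",
                  ifelse(nEvidence <= 3L, "medium", "high")))
  list(biogridPath = biogridPath, stringPath = stringPath,
       truth = data.frame(partnerId = partners, nEvidence = nEvidence,
                          expectedBand = expectedBand, source = source,
                          stringsAsFactors = FALSE))
}

#' Write the contaminant repository matching a simulated time course
#'
#' @param truth ground-truth data.frame from \code{\link{simulateTimecourse}}.
#' @param repoTotal total control experiments (header value).
#' @param path output path.
#' @return Invisibly, the \code{\linkS4class{ContaminantRepository}} written.
#' @export
simulateContaminantRepository <- function(truth, repoTotal = 411L,
                                          path = tempfile(fileext = ".tsv")) {
  repo <- ContaminantRepository(
    stats::setNames(truth$repoCount, truth$proteinId), repoTotal)
  writeContaminantRepository(repo, path)
  invisible(repo)
}
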