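#' @include AllClasses.R
NULL

## Run-header grammar: t<minutes>_rep<replicate>, e.g. "t7_rep2".
.parseRunHeader <- function(h) {
  m <- regmatches(h, regexec("^t([0-9]+)_rep([0-9]+)$", h))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable run header(s): ", paste(h[bad], collapse = ", "),
         " (expected t<minutes>_rep<k>)", call. = FALSE)
  data.frame(
    runId = h,
    timePoint = as.integer(vapply(m, `[`, "", 2L)),
    replicate = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Read a protein-level quantification table
#'
#' The canonical dialect mirrors a Progenesis-style protein-measurement
#' export: one protein per row with columns \code{accession},
#' \code{gene_symbol}, \code{unique_peptides}, \code{quantified_peptides},
#' optional \code{protein_probability} and \code{peptide_probabilities}
#' (semicolon-separated), followed by one abundance column per run named
#' \code{t<minutes>_rep<k>}. Empty abundance cells are missing values, never
#' zeros. The parse is loss-free: \code{\link{writeQuantCSV}} reproduces the
#' file.
#'
#' @param path CSV (or TSV, by extension) quantification table.
#' @return A \code{\linkS4class{QuantTable}}.
#' @export
readQuantCSV <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  metaCols <- c("accession", "gene_symbol", "unique_peptides",
                "quantified_peptides", "protein_probability",
                "peptide_probabilities")
  need <- setdiff(metaCols[1:4], colnames(tab))
  if (length(need))
    stop("missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  runCols <- setdiff(colnames(tab), metaCols)
  samples <- .parseRunHeader(runCols)
  if (anyDuplicated(tab$accession))
    stop("duplicate accession(s): ",
         paste(unique(tab$accession[duplicated(tab$accession)]), collapse = ", "),
         call. = FALSE)
  ab <- as.matrix(tab[, runCols, drop = FALSE])
  storage.mode(ab) <- "double"
  if (any(ab < 0, na.rm = TRUE))
    stop("negative abundance values are not permitted", call. = FALSE)
  proteins <- data.frame(
    accession = tab$accession,
    geneSymbol = harmonizeId(tab$gene_symbol),
    uniquePeptides = as.integer(tab$unique_peptides),
    quantifiedPeptides = as.integer(tab$quantified_peptides),
    stringsAsFactors = FALSE
  )
  if ("protein_probability" %in% colnames(tab))
    proteins$proteinProbability <- as.numeric(tab$protein_probability)
  qt <- QuantTable(ab, proteins, samples)
  if ("peptide_probabilities" %in% colnames(tab)) {
    pp <- strsplit(ifelse(is.na(tab$peptide_probabilities), "",
                          tab$peptide_probabilities), ";")
    rowData(qt)$peptideProbabilities <- IRanges::NumericList(
      lapply(pp, as.numeric))
  }
  qt
}

#' Write a quantification table in the canonical dialect
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @param path output CSV/TSV path (delimiter chosen by extension).
#' @return Invisibly, \code{path}.
#' @export
writeQuantCSV <- function(qt, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  rd <- rowData(qt)
  out <- data.frame(
    accession = rd$accession,
    gene_symbol = rd$geneSymbol,
    unique_peptides = rd$uniquePeptides,
    quantified_peptides = rd$quantifiedPeptides,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if ("proteinProbability" %in% colnames(rd))
    out$protein_probability <- rd$proteinProbability
  if ("peptideProbabilities" %in% colnames(rd))
    out$peptide_probabilities <- vapply(
      rd$peptideProbabilities,
      function(v) paste(format(v, trim = TRUE), collapse = ";"), "")
  ab <- assay(qt, "abundance")
  out <- cbind(out, as.data.frame(ab, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Identification acceptance filter
#'
#' Retains proteins with at least \code{minUniquePeptides} unique validated
#' peptides; when Scaffold-style probabilities are available the validated
#' count requires peptide probability >= 0.90 and the protein probability
#' must reach >= 0.99 (both boundaries inclusive). Tables without probability
#' columns pass through the peptide-count rule only, with a logged warning.
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @param minUniquePeptides 2 (default) or 3 for the strict setting.
#' @param minPeptideProb minimum per-peptide probability, default 0.90.
#' @param minProteinProb minimum protein-level probability, default 0.99.
#' @return The filtered \code{QuantTable} (a row subset of the input).
#' @export
applyIdentificationFilter <- function(qt, minUniquePeptides = 2L,
                                      minPeptideProb = 0.90,
                                      minProteinProb = 0.99) {
  rd <- rowData(qt)
  keep <- rd$uniquePeptides >= minUniquePeptides
  hasProb <- all(c("proteinProbability", "peptideProbabilities") %in%
                 colnames(rd))
  if (hasProb) {
    nValidated <- vapply(rd$peptideProbabilities,
                         function(v) sum(v >= minPeptideProb), 1L)
    keep <- keep & nValidated >= minUniquePeptides &
      !is.na(rd$proteinProbability) & rd$proteinProbability >= minProteinProb
  } else {
    warning("no probability columns: identification filter enforces the ",
            "unique-peptide rule only")
  }
  qt[which(keep), ]
}

#' Quantification acceptance filter
#'
#' Retains proteins quantified on at least \code{minQuantifiedPeptides}
#' peptides (boundary inclusive). Idempotent.
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @param minQuantifiedPeptides default 3.
#' @return The filtered \code{QuantTable}.
#' @export
applyQuantificationFilter <- function(qt, minQuantifiedPeptides = 3L) {
  keep <- rowData(qt)$quantifiedPeptides >= minQuantifiedPeptides
  qt[which(keep), ]
}

#' Median log-ratio normalisation of run abundances
#'
#' Median-of-ratios scaling: the pseudo-reference is the per-protein
#' geometric mean across runs (computed over anchor proteins with no missing
#' values), each run's log2 scaling factor is its median log-ratio to that
#' reference, and factors are re-anchored so the first run's factor is zero.
#' After normalisation the per-run median log2 ratio to the stored
#' pseudo-reference is exactly zero, within-protein patterns are preserved up
#' to a per-run scalar, the transform is idempotent, and the result is
#' invariant to multiplying any run by a positive constant.
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @return The \code{QuantTable} with the \code{"abundance"} assay rescaled.
#'   \code{metadata(qt)} gains \code{normalized = TRUE},
#'   \code{normFactors} (per-run log2 factors removed) and
#'   \code{pseudoReference} (named log2 reference over the anchor proteins,
#'   on the normalised scale).
#' @export
normalizeAbundances <- function(qt) {
  ab <- assay(qt, "abundance")
  if (ncol(ab) < 2L) return(qt)
  allMissing <- colSums(!is.na(ab) & ab > 0) == 0L
  if (any(allMissing))
    stop("run(s) with no usable abundances: ",
         paste(colnames(ab)[allMissing], collapse = ", "), call. = FALSE)
  anchor <- rowSums(is.na(ab) | ab <= 0) == 0L
  if (!any(anchor))
    stop("no protein with complete positive abundances to anchor normalisation",
         call. = FALSE)
  la <- log2(ab)
  la[!is.finite(la)] <- NA
  ref <- rowMeans(la[anchor, , drop = FALSE])
  f0 <- apply(la[anchor, , drop = FALSE], 2, function(col)
    stats::median(col - ref))
  f <- f0 - f0[1]                     # re-anchor on the first run
  norm <- 2^sweep(la, 2, f)
  norm[is.na(ab)] <- NA
  assay(qt, "abundance") <- norm
  metadata(qt)$normalized <- TRUE
  metadata(qt)$normFactors <- f
  metadata(qt)$pseudoReference <- ref + f0[1]
  qt
}

#' Read a spectral-count table
#'
#' @param path TSV with a \code{protein} identifier column followed by one
#'   integer total-spectral-count column per run.
#' @return integer matrix (proteins x runs).
#' @export
readSpectralCounts <- function(path) {
  tab <- .readDelim(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  if (any(m < 0, na.rm = TRUE))
    stop("spectral counts must be non-negative integers", call. = FALSE)
  m
}
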