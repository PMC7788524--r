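#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData rowData<- colData
NULL

## Controlled vocabulary for interaction evidence. Unmapped source terms
## collapse to "other", which counts toward evidence amount but never toward
## category-specific band promotion.
.EXPERIMENT_TYPES <- c(
  "affinity-capture-MS",
  "yeast-two-hybrid",
  "affinity-capture-immunoblot",
  "resonance-energy-transfer",
  "kinase-activity",
  "phosphatase-activity",
  "crystal-structure-reconstituted-complex",
  "other"
)

.LOW_TYPES <- c("affinity-capture-MS", "yeast-two-hybrid")
.MEDIUM_EXTRA_TYPES <- c(
  "affinity-capture-immunoblot", "resonance-energy-transfer",
  "kinase-activity", "phosphatase-activity"
)

.BANDS <- c("low", "medium", "high")
.BAND_RANGES <- list(low = c(0.1, 0.3), medium = c(0.4, 0.6), high = c(0.7, 0.9))
.BAND_RING <- c(high = 1L, medium = 2L, low = 3L)

.CONTAM_CATEGORIES <- c("<=1%", "<=10%", "<=100%")

#' Bait-centred literature interactome with confidence-scored partners
#'
#' An \code{Interactome} holds the spoke network around a single bait protein:
#' one node per partner, each carrying a confidence score in [0.1, 0.9], a
#' confidence band (low/medium/high), the ring index used for radial layout
#' (high-confidence partners innermost), the evidence count (drawn as node
#' size) and a throughput flag (drawn as node border). Every edge connects the
#' bait to one partner; there are no partner-partner edges.
#'
#' @slot bait character(1), harmonised bait identifier.
#' @slot nodes \code{DataFrame} with columns \code{partnerId}, \code{score},
#'   \code{band}, \code{ring}, \code{nodeSize}, \code{throughputBorder}.
#' @slot evidence \code{DataFrame} of the underlying evidence records with
#'   columns \code{partnerId}, \code{experimentType}, \code{throughput},
#'   \code{sourceDb}.
#'
#' @exportClass Interactome
setClass("Interactome",
  slots = c(bait = "character", nodes = "DataFrame", evidence = "DataFrame")
)

setValidity("Interactome", function(object) {
  msgs <- character()
  if (length(object@bait) != 1L || !nzchar(object@bait))
    msgs <- c(msgs, "bait must be a single non-empty identifier")
  nd <- object@nodes
  need <- c("partnerId", "score", "band", "ring", "nodeSize", "throughputBorder")
  if (!all(need %in% colnames(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$partnerId))
    msgs <- c(msgs, "partner identifiers must be unique")
  if (any(nd$partnerId == object@bait))
    msgs <- c(msgs, "bait must not appear among partners (spoke topology)")
  if (nrow(nd) > 0) {
    if (!all(nd$band %in% .BANDS))
      msgs <- c(msgs, "band must be one of low/medium/high")
    for (b in .BANDS) {
      i <- nd$band == b
      if (any(i)) {
        rng <- .BAND_RANGES[[b]]
        if (any(nd$score[i] < rng[1] - 1e-9 | nd$score[i] > rng[2] + 1e-9))
          msgs <- c(msgs, sprintf("scores outside the %s band range [%.1f, %.1f]",
                                  b, rng[1], rng[2]))
      }
    }
    if (!all(nd$ring == .BAND_RING[nd$band]))
      msgs <- c(msgs, "ring must map from band as high->1, medium->2, low->3")
    if (any(nd$nodeSize < 1L))
      msgs <- c(msgs, "nodeSize (evidence count) must be positive")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn Interactome Number of partner nodes.
#' @param x,object An \code{Interactome}.
#' @export
setMethod("length", "Interactome", function(x) nrow(x@nodes))

setMethod("show", "Interactome", function(object) {
  cat(sprintf("Interactome around bait %s\n", object@bait))
  cat(sprintf("  %d partners: %d high / %d medium / %d low confidence\n",
              nrow(object@nodes),
              sum(object@nodes$band == "high"),
              sum(object@nodes$band == "medium"),
              sum(object@nodes$band == "low")))
  cat(sprintf("  %d evidence records\n", nrow(object@evidence)))
})

#' @rdname Interactome
#' @export
baitId <- function(object) object@bait

#' @rdname Interactome
#' @export
interactomeNodes <- function(object) object@nodes

#' @rdname Interactome
#' @export
interactomeEvidence <- function(object) object@evidence

#' @rdname Interactome
#' @export
partnerIds <- function(object) as.character(object@nodes$partnerId)

#' Protein-level label-free quantification table
#'
#' A \code{QuantTable} extends \code{SummarizedExperiment}: the
#' \code{"abundance"} assay holds non-negative MS1 precursor intensities
#' (missing values are \code{NA}, never silent zeros), \code{rowData}
#' carries identification metadata (accession, gene symbol, unique and
#' quantified peptide counts, optional Scaffold-style peptide/protein
#' probabilities), and \code{colData} maps each run to its time point
#' (minutes) and replicate index.
#'
#' @exportClass QuantTable
setClass("QuantTable", contains = "SummarizedExperiment")

setValidity("QuantTable", function(object) {
  msgs <- character()
  if (!"abundance" %in% names(assays(object)))
    return("QuantTable requires an 'abundance' assay")
  ab <- assay(object, "abundance")
  if (any(ab < 0, na.rm = TRUE))
    msgs <- c(msgs, "abundances must be non-negative")
  needRow <- c("accession", "geneSymbol", "uniquePeptides", "quantifiedPeptides")
  if (!all(needRow %in% colnames(rowData(object))))
    msgs <- c(msgs, paste("rowData must have columns:", paste(needRow, collapse = ", ")))
  needCol <- c("runId", "timePoint", "replicate")
  if (!all(needCol %in% colnames(colData(object))))
    msgs <- c(msgs, paste("colData must have columns:", paste(needCol, collapse = ", ")))
  else {
    if (anyDuplicated(colData(object)$runId))
      msgs <- c(msgs, "run identifiers must be unique")
    if (any(is.na(colData(object)$timePoint)))
      msgs <- c(msgs, "every sample needs a time point")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a QuantTable
#'
#' @param abundance numeric matrix (proteins x runs) of MS1 intensities;
#'   \code{NA} marks missing values.
#' @param proteins data.frame with columns \code{accession},
#'   \code{geneSymbol}, \code{uniquePeptides}, \code{quantifiedPeptides} and
#'   optionally \code{proteinProbability} plus a \code{peptideProbabilities}
#'   list column.
#' @param samples data.frame with columns \code{runId}, \code{timePoint}
#'   (minutes), \code{replicate}.
#' @return A \code{QuantTable}.
#' @export
QuantTable <- function(abundance, proteins, samples) {
  abundance <- as.matrix(abundance)
  rownames(abundance) <- proteins$accession
  colnames(abundance) <- samples$runId
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(proteins, row.names = proteins$accession),
    colData = DataFrame(samples, row.names = samples$runId)
  )
  new("QuantTable", se)
}

setMethod("show", "QuantTable", function(object) {
  cd <- colData(object)
  tps <- sort(unique(cd$timePoint))
  cat(sprintf("QuantTable: %d proteins x %d runs\n", nrow(object), ncol(object)))
  cat(sprintf("  time points (min): %s; replicates per point: %s\n",
              paste(tps, collapse = ", "),
              paste(vapply(tps, function(t) sum(cd$timePoint == t), 1L),
                    collapse = ", ")))
  nmiss <- sum(is.na(assay(object, "abundance")))
  cat(sprintf("  %d missing abundance cells\n", nmiss))
})

#' Contaminant repository of negative-control AP-MS experiments
#'
#' Stores, for each protein, the number of control experiments (out of
#' \code{totalExperiments}) in which it was detected. Detection frequency
#' estimates the chance a protein is non-specific background.
#'
#' @slot totalExperiments integer(1), total control experiments (411 in the
#'   reference repository snapshot).
#' @slot counts named integer vector, detections per protein.
#' @exportClass ContaminantRepository
setClass("ContaminantRepository",
  slots = c(totalExperiments = "integer", counts = "integer")
)

setValidity("ContaminantRepository", function(object) {
  msgs <- character()
  if (length(object@totalExperiments) != 1L || object@totalExperiments < 1L)
    msgs <- c(msgs, "totalExperiments must be a single positive integer")
  if (length(object@counts) && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by protein identifier")
  if (any(object@counts < 0L) || any(object@counts > object@totalExperiments))
    msgs <- c(msgs, "counts must lie in [0, totalExperiments]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname ContaminantRepository
#' @param counts named integer vector of per-protein detection counts.
#' @param totalExperiments total number of control experiments.
#' @export
ContaminantRepository <- function(counts, totalExperiments = 411L) {
  cn <- as.integer(counts)
  names(cn) <- toupper(names(counts))
  new("ContaminantRepository",
      totalExperiments = as.integer(totalExperiments), counts = cn)
}

setMethod("show", "ContaminantRepository", function(object) {
  cat(sprintf("ContaminantRepository: %d proteins over %d control experiments\n",
              length(object@counts), object@totalExperiments))
})

#' @rdname ContaminantRepository
#' @param object A \code{ContaminantRepository}.
#' @export
repositoryTotal <- function(object) object@totalExperiments

#' @rdname ContaminantRepository
#' @export
repositoryCounts <- function(object) object@counts

#' One-hop expansion network around detected known interactors
#'
#' Seed nodes are known bait interactors detected in the dataset; expansion
#' nodes are other dataset proteins adjacent to at least one seed in a local
#' interaction edge table. Total node count never exceeds \code{cap}.
#'
#' @slot seeds character vector of seed protein identifiers.
#' @slot expansion character vector of expansion protein identifiers.
#' @slot edges data.frame with columns \code{proteinA}, \code{proteinB},
#'   \code{weight}, restricted to the retained nodes.
#' @slot category named character vector of contaminant categories (may be
#'   empty before \code{\link{overlayContaminants}}).
#' @slot cap integer(1), the node cap applied at expansion time.
#' @exportClass OneHopNetwork
setClass("OneHopNetwork",
  slots = c(seeds = "character", expansion = "character",
            edges = "data.frame", category = "character", cap = "integer")
)

setValidity("OneHopNetwork", function(object) {
  msgs <- character()
  nodes <- c(object@seeds, object@expansion)
  if (anyDuplicated(nodes))
    msgs <- c(msgs, "seed and expansion node sets must be disjoint and unique")
  if (length(nodes) > object@cap)
    msgs <- c(msgs, sprintf("node count %d exceeds cap %d", length(nodes), object@cap))
  if (length(object@expansion)) {
    e <- object@edges
    adj <- vapply(object@expansion, function(p) {
      any((e$proteinA == p & e$proteinB %in% object@seeds) |
          (e$proteinB == p & e$proteinA %in% object@seeds))
    }, logical(1))
    if (!all(adj))
      msgs <- c(msgs, "every expansion node must be adjacent to at least one seed")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "OneHopNetwork", function(object) {
  cat(sprintf("OneHopNetwork: %d seeds + %d expansion nodes (cap %d), %d edges\n",
              length(object@seeds), length(object@expansion),
              object@cap, nrow(object@edges)))
  if (length(object@category)) {
    tab <- table(factor(object@category, levels = .CONTAM_CATEGORIES))
    cat("  contaminant categories:",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @rdname OneHopNetwork
#' @param object A \code{OneHopNetwork}.
#' @export
seedNodes <- function(object) object@seeds

#' @rdname OneHopNetwork
#' @export
expansionNodes <- function(object) object@expansion

#' @rdname OneHopNetwork
#' @export
networkEdges <- function(object) object@edges

#' @rdname OneHopNetwork
#' @export
nodeCategories <- function(object) object@category
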