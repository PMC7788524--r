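#' @include AllClasses.R
NULL

#' Map dataset proteins onto known interactome partners
#'
#' The seeds of the one-hop expansion: detected proteins that are also
#' partners in the literature interactome (identifiers harmonised on both
#' sides).
#'
#' @param datasetProteins character vector of detected protein identifiers.
#' @param interactome An \code{\linkS4class{Interactome}}.
#' @return character vector of seed identifiers (sorted).
#' @export
mapKnownInteractors <- function(datasetProteins, interactome) {
  seeds <- sort(intersect(harmonizeId(datasetProteins),
                          partnerIds(interactome)))
  message(sprintf("mapKnownInteractors: %d of %d dataset proteins are known partners",
                  length(seeds), length(unique(datasetProteins))))
  if (!length(seeds)) warning("no known interactor detected in the dataset")
  seeds
}

#' Read a local interaction edge table
#'
#' @param path three-column TSV: \code{protein_a}, \code{protein_b},
#'   \code{weight} in [0, 1].
#' @return data.frame with columns \code{proteinA}, \code{proteinB},
#'   \code{weight}.
#' @export
readEdgeTable <- function(path) {
  tab <- .readDelim(path)
  if (ncol(tab) < 3L)
    stop("edge table needs columns protein_a, protein_b, weight",
         call. = FALSE)
  out <- data.frame(proteinA = harmonizeId(tab[[1]]),
                    proteinB = harmonizeId(tab[[2]]),
                    weight = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$weight < 0 | out$weight > 1, na.rm = TRUE))
    stop("edge weights must lie in [0, 1]", call. = FALSE)
  out
}

#' One-hop expansion from seed interactors
#'
#' Adds every non-seed dataset protein adjacent to at least one seed in the
#' edge table. When the resulting node count would exceed \code{cap},
#' expansion nodes are dropped in ascending order of (number of seed
#' neighbours, then total edge weight to seeds), lexicographically larger
#' identifiers dropped first on ties, so the best-connected expansion nodes
#' are retained, and the truncation is logged. The retained edge set is the edge table restricted
#' to retained nodes.
#'
#' @param seeds character vector of seed identifiers.
#' @param edgeTable data.frame from \code{\link{readEdgeTable}}.
#' @param datasetProteins character vector of all detected proteins.
#' @param cap maximum node count, default 500.
#' @return A \code{\linkS4class{OneHopNetwork}}.
#' @export
oneHopExpand <- function(seeds, edgeTable, datasetProteins, cap = 500L) {
  seeds <- unique(harmonizeId(seeds))
  datasetProteins <- unique(harmonizeId(datasetProteins))
  if (cap < length(seeds))
    stop(sprintf("cap (%d) smaller than the seed set (%d)", cap,
                 length(seeds)), call. = FALSE)
  e <- edgeTable
  seedEdge <- (e$proteinA %in% seeds) | (e$proteinB %in% seeds)
  other <- ifelse(e$proteinA %in% seeds, e$proteinB, e$proteinA)
  candidate <- seedEdge & other %in% setdiff(datasetProteins, seeds)
  expansion <- sort(unique(as.character(other[candidate])))

  room <- cap - length(seeds)
  if (length(expansion) > room) {
    conn <- vapply(expansion, function(p) {
      i <- candidate & other == p
      partnersSeen <- unique(ifelse(e$proteinA[i] == p, e$proteinB[i],
                                    e$proteinA[i]))
      c(nSeeds = length(intersect(partnersSeen, seeds)),
        wSum = sum(e$weight[i]))
    }, numeric(2))
    ord <- order(-conn["nSeeds", ], -conn["wSum", ], expansion)
    dropped <- expansion[ord][-seq_len(room)]
    expansion <- sort(expansion[ord][seq_len(max(room, 0))])
    message(sprintf("oneHopExpand: cap %d reached, dropped %d expansion node(s)",
                    cap, length(dropped)))
  }

  nodes <- c(seeds, expansion)
  keepEdge <- e$proteinA %in% nodes & e$proteinB %in% nodes
  edges <- e[keepEdge, , drop = FALSE]
  rownames(edges) <- NULL
  new("OneHopNetwork", seeds = seeds, expansion = expansion, edges = edges,
      category = character(), cap = as.integer(cap))
}

#' Overlay contaminant categories on a one-hop network
#'
#' Every node is annotated with its contaminant category, distinguishing
#' likely background hits from potential novel candidates; nodes absent from
#' the assessment table default to \code{"<=1%"}.
#'
#' @param network A \code{\linkS4class{OneHopNetwork}}.
#' @param assessments data.frame from \code{\link{annotateContaminants}}.
#' @return The network with its \code{category} slot filled; the category
#'   distribution is logged.
#' @export
overlayContaminants <- function(network, assessments) {
  nodes <- c(network@seeds, network@expansion)
  if (!length(nodes)) return(network)
  cat <- stats::setNames(as.character(assessments$category),
                         assessments$proteinId)[nodes]
  cat[is.na(cat)] <- .CONTAM_CATEGORIES[1]
  names(cat) <- nodes
  network@category <- cat
  tab <- table(factor(cat, levels = .CONTAM_CATEGORIES))
  message("overlayContaminants: ",
          paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  validObject(network)
  network
}

#' Write a one-hop network as TSV tables plus GraphML
#'
#' @param network A \code{\linkS4class{OneHopNetwork}}.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
writeOneHopNetwork <- function(network, prefix) {
  nodes <- c(network@seeds, network@expansion)
  role <- c(rep("seed", length(network@seeds)),
            rep("expansion", length(network@expansion)))
  cat <- if (length(network@category)) unname(network@category[nodes])
         else rep(NA_character_, length(nodes))
  nodeTab <- data.frame(id = nodes, role = role, contaminantCategory = cat,
                        stringsAsFactors = FALSE)
  nodePath <- paste0(prefix, "_nodes.tsv")
  edgePath <- paste0(prefix, "_edges.tsv")
  gmlPath <- paste0(prefix, ".graphml")
  utils::write.table(nodeTab, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(network@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- if (nrow(nodeTab)) {
    igraph::graph_from_data_frame(network@edges, directed = FALSE,
                                  vertices = nodeTab)
  } else igraph::make_empty_graph(directed = FALSE)
  igraph::write_graph(g, gmlPath, format = "graphml")
  invisible(c(nodes = nodePath, edges = edgePath, graphml = gmlPath))
}
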