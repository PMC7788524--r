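#' @include AllClasses.R
NULL

#' Default mapping from source experimental-system names to the controlled
#' evidence vocabulary
#'
#' Shipped as an editable two-column TSV
#' (\code{system.file("extdata", "experimental_system_map.tsv")}). Terms not
#' present in the mapping fall back to \code{"other"}.
#'
#' @return data.frame with columns \code{source} and \code{mapped}.
#' @export
experimentalSystemMap <- function() {
  path <- system.file("extdata", "experimental_system_map.tsv",
                      package = "apmsTimeCourse")
  .readDelim(path)
}

.mapExperimentType <- function(systems, map = experimentalSystemMap()) {
  key <- tolower(trimws(systems))
  mapped <- map$mapped[match(key, tolower(map$source))]
  mapped[is.na(mapped)] <- "other"
  mapped
}

#' Parse a BioGRID-style tab-delimited evidence export
#'
#' Reads an interaction evidence table, keeps the rows in which the bait
#' appears as either interactor, and maps each row's experimental-system name
#' onto the controlled vocabulary. One evidence record is produced per
#' retained row; rows not involving the bait are dropped with a logged count.
#'
#' @param path path to a tab-delimited export with a header containing the
#'   two interactor-symbol columns, an experimental-system column and a
#'   throughput column.
#' @param bait bait identifier (harmonised internally).
#' @param systemMap two-column data.frame mapping source system names to the
#'   controlled vocabulary; defaults to the shipped table.
#' @return data.frame of evidence records with columns \code{partnerId},
#'   \code{experimentType}, \code{throughput}, \code{sourceDb}.
#' @export
parseBiogridExport <- function(path, bait = "INSR",
                               systemMap = experimentalSystemMap()) {
  tab <- .readDelim(path)
  if (nrow(tab) == 0L) {
    warning("empty evidence export: ", path)
    return(data.frame(partnerId = character(), experimentType = character(),
                      throughput = character(), sourceDb = character()))
  }
  h <- colnames(tab)
  colA <- .resolveColumn(h, c("Official Symbol Interactor A", "symbol_a",
                              "OFFICIAL_SYMBOL_A"), "interactor A symbol")
  colB <- .resolveColumn(h, c("Official Symbol Interactor B", "symbol_b",
                              "OFFICIAL_SYMBOL_B"), "interactor B symbol")
  colSys <- .resolveColumn(h, c("Experimental System", "experimental_system"),
                           "experimental system")
  colThr <- .resolveColumn(h, c("Throughput", "throughput"), "throughput")

  bait <- harmonizeId(bait)
  a <- harmonizeId(tab[[colA]])
  b <- harmonizeId(tab[[colB]])
  keep <- (a == bait | b == bait) & (a != b)   # drop non-bait and bait-bait rows
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("parseBiogridExport: dropped %d row(s) not involving bait %s",
                    dropped, bait))
  partner <- ifelse(a[keep] == bait, b[keep], a[keep])
  thr <- ifelse(grepl("high", tab[[colThr]][keep], ignore.case = TRUE),
                "high", "low")
  data.frame(
    partnerId = partner,
    experimentType = .mapExperimentType(tab[[colSys]][keep], systemMap),
    throughput = thr,
    sourceDb = "biogrid-style",
    stringsAsFactors = FALSE
  )
}

#' Parse a STRING-style protein-links table
#'
#' Keeps bait-incident rows, normalises the combined score to [0, 1]
#' (the 0-1000 source scale is auto-detected) and deduplicates repeated
#' partner rows keeping the maximum score.
#'
#' @param path whitespace- or tab-delimited links table: two identifier
#'   columns followed by a numeric combined-score column.
#' @param bait bait identifier.
#' @return data.frame with columns \code{partnerId}, \code{combinedScore}.
#' @export
parseStringExport <- function(path, bait = "INSR") {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("empty links table: ", path)
    return(data.frame(partnerId = character(), combinedScore = numeric()))
  }
  if (ncol(raw) < 3L)
    stop("links table needs two identifier columns and a score column")
  score <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(score) & !is.na(raw[[3]]))
  if (length(bad))
    stop(sprintf("non-numeric score '%s' at data line %d", raw[[3]][bad[1]],
                 bad[1]), call. = FALSE)
  if (max(score, na.rm = TRUE) > 1) score <- score / 1000
  bait <- harmonizeId(bait)
  a <- harmonizeId(raw[[1]])
  b <- harmonizeId(raw[[2]])
  keep <- (a == bait | b == bait) & (a != b)
  partner <- ifelse(a[keep] == bait, b[keep], a[keep])
  score <- score[keep]
  # duplicate rows for the same partner: keep the maximum score
  agg <- tapply(score, partner, max)
  data.frame(partnerId = names(agg), combinedScore = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Merge evidence-table and links-table partners (union semantics)
#'
#' The merged interactome is the union of partners from both exports, so
#' interactions found in only one database are never lost. Partners present
#' only in the links table, with no evidence rows, receive a single synthetic
#' evidence record of type \code{"other"} with string-style provenance.
#'
#' @param biogridRecords data.frame from \code{\link{parseBiogridExport}}.
#' @param stringRecords data.frame from \code{\link{parseStringExport}}.
#' @return data.frame of evidence records over the union of partners, with a
#'   \code{"stringScore"} attribute (named numeric vector of combined scores
#'   kept as provenance) and a \code{"stringOnly"} attribute naming the
#'   partners that lack database evidence rows.
#' @export
mergeNetworks <- function(biogridRecords, stringRecords) {
  bg <- biogridRecords
  stringOnly <- setdiff(stringRecords$partnerId, unique(bg$partnerId))
  if (length(stringOnly)) {
    synth <- data.frame(
      partnerId = stringOnly,
      experimentType = "other",
      throughput = "high",
      sourceDb = "string-style",
      stringsAsFactors = FALSE
    )
    bg <- rbind(bg, synth)
  }
  attr(bg, "stringScore") <- stats::setNames(stringRecords$combinedScore,
                                             stringRecords$partnerId)
  attr(bg, "stringOnly") <- stringOnly
  bg
}

#' Score one interaction from its evidence records
#'
#' Confidence is banded by the amount of evidence: one record gives a low
#' confidence score in [0.1, 0.3]; two to three records give medium
#' confidence in [0.4, 0.6]; more than three give high confidence in
#' [0.7, 0.9]. Within each band the score is a deterministic, monotone
#' non-decreasing function of the evidence: a lone record carries 0.2, or the
#' band floor 0.1 when it is only string-style provenance with no
#' experimental evidence; medium scores start at 0.4 (two records), rise to
#' 0.5 (three) and gain 0.1 (capped at 0.6) when enzymatic
#' (kinase/phosphatase activity) evidence is present; high scores rise from
#' 0.7 (four to five records) through 0.8 (six to nine) to 0.9 (ten or more,
#' or any crystal-structure reconstituted complex).
#'
#' @param evidence data.frame of evidence records (columns
#'   \code{experimentType}, \code{sourceDb}) or a character vector of
#'   experiment types.
#' @return list with elements \code{score} and \code{band}.
#' @export
scoreInteraction <- function(evidence) {
  if (is.character(evidence)) {
    if (!length(evidence))
      stop("interaction cannot be scored without evidence", call. = FALSE)
    evidence <- data.frame(experimentType = evidence,
                           sourceDb = "biogrid-style",
                           stringsAsFactors = FALSE)
  }
  n <- nrow(evidence)
  if (is.null(n) || n == 0L)
    stop("interaction cannot be scored without evidence", call. = FALSE)
  types <- evidence$experimentType
  if (n == 1L) {
    stringOnly <- types[1] == "other" &&
      identical(evidence$sourceDb[1], "string-style")
    return(list(score = if (stringOnly) 0.1 else 0.2, band = "low"))
  }
  if (n <= 3L) {
    score <- if (n == 2L) 0.4 else 0.5
    if (any(types %in% c("kinase-activity", "phosphatase-activity")))
      score <- min(score + 0.1, 0.6)
    return(list(score = score, band = "medium"))
  }
  score <- if (n <= 5L) 0.7 else if (n <= 9L) 0.8 else 0.9
  if (any(types == "crystal-structure-reconstituted-complex"))
    score <- 0.9
  list(score = score, band = "high")
}

#' Score every partner in a merged evidence table
#'
#' @param merged evidence data.frame from \code{\link{mergeNetworks}} (or
#'   \code{\link{parseBiogridExport}} alone).
#' @return data.frame with one row per partner: \code{partnerId},
#'   \code{score}, \code{band}, \code{nodeSize} (evidence count) and
#'   \code{throughputBorder} (\code{"low"} if any record is low-throughput).
#' @export
scoreInteractions <- function(merged) {
  parts <- sort(unique(merged$partnerId))
  if (!length(parts))
    return(data.frame(partnerId = character(), score = numeric(),
                      band = character(), nodeSize = integer(),
                      throughputBorder = character()))
  rows <- lapply(parts, function(p) {
    ev <- merged[merged$partnerId == p, , drop = FALSE]
    sc <- scoreInteraction(ev)
    data.frame(partnerId = p, score = sc$score, band = sc$band,
               nodeSize = nrow(ev),
               throughputBorder = if (any(ev$throughput == "low")) "low" else "high",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the spoke network
#'
#' Builds the bait-centred star: one node per scored partner, rings assigned
#' from confidence band (high innermost), partners ordered by descending
#' score then lexicographic identifier for a stable layout.
#'
#' @param scored data.frame from \code{\link{scoreInteractions}}.
#' @param bait bait identifier.
#' @param evidence optional evidence data.frame to retain in the object.
#' @return An \code{\linkS4class{Interactome}}.
#' @export
buildSpokeNetwork <- function(scored, bait, evidence = NULL) {
  if (anyDuplicated(scored$partnerId))
    stop("duplicate partner identifiers: merge evidence before building",
         call. = FALSE)
  bait <- harmonizeId(bait)
  ord <- order(-scored$score, scored$partnerId)
  scored <- scored[ord, , drop = FALSE]
  nodes <- DataFrame(
    partnerId = scored$partnerId,
    score = scored$score,
    band = scored$band,
    ring = unname(.BAND_RING[scored$band]),
    nodeSize = as.integer(scored$nodeSize),
    throughputBorder = scored$throughputBorder
  )
  if (is.null(evidence))
    evidence <- data.frame(partnerId = character(), experimentType = character(),
                           throughput = character(), sourceDb = character())
  new("Interactome", bait = bait, nodes = nodes,
      evidence = DataFrame(evidence))
}

#' Build a scored interactome from database exports in one call
#'
#' Convenience wrapper: parse both exports, merge with union semantics,
#' score every partner and assemble the spoke network.
#'
#' @inheritParams parseBiogridExport
#' @param stringPath path to the STRING-style links table.
#' @return An \code{\linkS4class{Interactome}}.
#' @export
buildInteractome <- function(path, stringPath, bait = "INSR",
                             systemMap = experimentalSystemMap()) {
  bg <- parseBiogridExport(path, bait = bait, systemMap = systemMap)
  st <- parseStringExport(stringPath, bait = bait)
  merged <- mergeNetworks(bg, st)
  buildSpokeNetwork(scoreInteractions(merged), bait = bait, evidence = merged)
}

#' Write an interactome as node/edge tables plus GraphML
#'
#' Emits \code{<prefix>_nodes.tsv}, \code{<prefix>_edges.tsv} and
#' \code{<prefix>.graphml}; the GraphML node attributes mirror the node table
#' and a read-back with \code{\link{readNetwork}} reproduces the network.
#'
#' @param network An \code{\linkS4class{Interactome}}.
#' @param prefix output path prefix.
#' @return Invisibly, the three paths written.
#' @export
writeNetwork <- function(network, prefix) {
  nodes <- as.data.frame(network@nodes)
  edges <- data.frame(from = rep(network@bait, nrow(nodes)),
                      to = nodes$partnerId,
                      confidence = nodes$score,
                      stringsAsFactors = FALSE)
  nodePath <- paste0(prefix, "_nodes.tsv")
  edgePath <- paste0(prefix, "_edges.tsv")
  gmlPath <- paste0(prefix, ".graphml")
  utils::write.table(nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = network@bait, score = NA_real_,
                            band = "bait", ring = 0L, nodeSize = NA_integer_,
                            throughputBorder = "bait")
  if (nrow(nodes) > 0) {
    g <- igraph::add_vertices(g, nrow(nodes), name = nodes$partnerId,
                              score = nodes$score, band = nodes$band,
                              ring = nodes$ring, nodeSize = nodes$nodeSize,
                              throughputBorder = nodes$throughputBorder)
    idx <- match(nodes$partnerId, igraph::V(g)$name)
    el <- rbind(rep(1L, nrow(nodes)), idx)
    g <- igraph::add_edges(g, as.vector(el), confidence = nodes$score)
  }
  igraph::write_graph(g, gmlPath, format = "graphml")
  invisible(c(nodes = nodePath, edges = edgePath, graphml = gmlPath))
}

#' Read back an interactome written by \code{\link{writeNetwork}}
#'
#' @param prefix the prefix passed to \code{\link{writeNetwork}}.
#' @return An \code{\linkS4class{Interactome}} (evidence slot empty; the
#'   tables carry node attributes only).
#' @export
readNetwork <- function(prefix) {
  nodes <- .readDelim(paste0(prefix, "_nodes.tsv"))
  edges <- .readDelim(paste0(prefix, "_edges.tsv"))
  bait <- if (nrow(edges)) edges$from[1] else "UNKNOWN"
  scored <- data.frame(partnerId = as.character(nodes$partnerId),
                       score = nodes$score, band = nodes$band,
                       nodeSize = nodes$nodeSize,
                       throughputBorder = nodes$throughputBorder,
                       stringsAsFactors = FALSE)
  buildSpokeNetwork(scored, bait = bait)
}
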