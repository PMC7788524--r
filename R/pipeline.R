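#' @include AllClasses.R
NULL

#' Full-pipeline run configuration
#'
#' Collects all input paths and thresholds for \code{\link{runAll}}.
#' Referenced input files must exist at validation time; thresholds are
#' checked against their documented domains.
#'
#' @param biogridPath,stringPath interaction-database exports.
#' @param quantPath quantification table (canonical CSV/TSV dialect).
#' @param contaminantPath contaminant repository file.
#' @param edgePath local interaction edge table for the one-hop expansion.
#' @param bait bait identifier.
#' @param minUniquePeptides,minQuantifiedPeptides identification and
#'   quantification peptide thresholds.
#' @param minAbsLog2Fc,maxP,maxContaminantCategory candidate filter
#'   thresholds (see \code{\link{filterSpec}}).
#' @param minR anchored-clustering correlation threshold.
#' @param cap one-hop node cap.
#' @param seed RNG seed recorded in the report.
#' @param outDir output directory (created by \code{\link{runAll}}).
#' @return object of class \code{"RunConfig"}.
#' @export
runConfig <- function(biogridPath, stringPath, quantPath, contaminantPath,
                      edgePath, bait = "INSR",
                      minUniquePeptides = 2L, minQuantifiedPeptides = 3L,
                      minAbsLog2Fc = 1, maxP = 0.05,
                      maxContaminantCategory = "<=10%",
                      minR = 0.7, cap = 500L, seed = 1L,
                      outDir = "apms_run") {
  paths <- c(biogrid = biogridPath, string = stringPath, quant = quantPath,
             contaminants = contaminantPath, edges = edgePath)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  if (minR <= -1 || minR > 1) stop("minR must lie in (-1, 1]", call. = FALSE)
  if (cap < 1L) stop("cap must be positive", call. = FALSE)
  spec <- filterSpec(minUniquePeptides, minAbsLog2Fc, maxP,
                     maxContaminantCategory)   # validates thresholds
  structure(list(
    biogridPath = biogridPath, stringPath = stringPath,
    quantPath = quantPath, contaminantPath = contaminantPath,
    edgePath = edgePath, bait = bait,
    minUniquePeptides = as.integer(minUniquePeptides),
    minQuantifiedPeptides = as.integer(minQuantifiedPeptides),
    filterSpec = spec, minR = minR, cap = as.integer(cap),
    seed = as.integer(seed), outDir = outDir), class = "RunConfig")
}

#' Run the full discovery workflow
#'
#' Executes the fixed stage order: build the literature interactome, ingest
#' and filter the quantification table, normalise, score contaminants,
#' cluster temporal profiles anchored on known binders, compute differentials
#' and shortlist candidates, and expand one hop from the detected known
#' interactors. All outputs plus a machine-readable \code{report.json} are
#' written atomically (temporary directory, then rename). Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config A \code{\link{runConfig}}.
#' @return The run report (a list), invisibly; the same content is written to
#'   \code{<outDir>/report.json}.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  tmp <- tempfile("apms_run_")
  dir.create(tmp, recursive = TRUE)
  report <- list(
    package = "apmsTimeCourse",
    version = as.character(utils::packageVersion("apmsTimeCourse")),
    seed = config$seed,
    config = config[setdiff(names(config), "filterSpec")],
    filterSpec = unclass(config$filterSpec),
    stages = list())

  interactome <- stage("interactome", {
    net <- buildInteractome(config$biogridPath, config$stringPath,
                            bait = config$bait)
    writeNetwork(net, file.path(tmp, "interactome"))
    net
  })
  report$stages$interactome <- list(partners = length(interactome))

  qt <- stage("ingest", readQuantCSV(config$quantPath))
  nIn <- nrow(qt)
  qtId <- stage("identification_filter",
                suppressWarnings(applyIdentificationFilter(
                  qt, config$minUniquePeptides)))
  qtQ <- stage("quantification_filter",
               applyQuantificationFilter(qtId, config$minQuantifiedPeptides))
  qtN <- stage("normalise", normalizeAbundances(qtQ))
  stage("ingest_write", writeQuantCSV(qtN, file.path(tmp, "quant_filtered.csv")))
  report$stages$ingest <- list(proteinsIn = nIn,
                               afterIdentification = nrow(qtId),
                               afterQuantification = nrow(qtQ))

  repo <- stage("contaminants", readContaminantRepository(config$contaminantPath))
  gene <- stats::setNames(rowData(qtN)$geneSymbol, rownames(qtN))
  assessments <- stage("contaminants", {
    a <- annotateContaminants(unname(gene), repo)
    a$proteinId <- names(gene)          # key by accession downstream
    utils::write.table(a, file.path(tmp, "contaminants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    a
  })
  report$stages$contaminants <- list(
    proteins = nrow(assessments),
    categories = as.list(table(assessments$category)))

  clusterStage <- stage("clustering", {
    prof <- profileMatrix(qtN)
    knownAcc <- names(gene)[gene %in% partnerIds(interactome) |
                            names(gene) %in% partnerIds(interactome)]
    if (nrow(prof) >= 2L && length(intersect(knownAcc, rownames(prof)))) {
      tree <- hierarchicalCluster(prof)
      clusters <- extractAnchoredClusters(tree, prof, knownAcc,
                                          minR = config$minR)
      writeClusters(clusters, tree, tmp)
    } else {
      clusters <- data.frame(anchor = character(), member = character(),
                             r = numeric())
    }
    list(profiles = prof, clusters = clusters)
  })
  report$stages$clustering <- list(
    profilesClustered = nrow(clusterStage$profiles),
    profilesExcluded = length(attr(clusterStage$profiles, "excluded")),
    anchors = length(unique(clusterStage$clusters$anchor)),
    clusteredMembers = length(unique(clusterStage$clusters$member)))

  candidates <- stage("filtering", {
    diffs <- computeDifferentials(qtN)
    cand <- applyFilters(diffs, qtN, assessments, config$filterSpec,
                         clusters = clusterStage$clusters)
    utils::write.table(cand, file.path(tmp, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(attr(cand, "excluded"),
                       file.path(tmp, "excluded.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(volcanoTable(diffs), file.path(tmp, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cand
  })
  report$stages$filtering <- list(
    proteinsTested = nrow(qtN),
    candidates = nrow(candidates),
    excluded = nrow(attr(candidates, "excluded")))

  oneHop <- stage("one_hop", {
    edges <- readEdgeTable(config$edgePath)
    seeds <- mapKnownInteractors(unname(gene), interactome)
    net <- oneHopExpand(seeds, edges, unname(gene), cap = config$cap)
    net <- overlayContaminants(net, {
      a <- assessments; a$proteinId <- unname(gene[a$proteinId]); a
    })
    writeOneHopNetwork(net, file.path(tmp, "one_hop"))
    net
  })
  report$stages$one_hop <- list(
    seeds = length(seedNodes(oneHop)),
    expansion = length(expansionNodes(oneHop)),
    nodes = length(seedNodes(oneHop)) + length(expansionNodes(oneHop)),
    cap = config$cap)

  report$startedAt <- format(t0, "%Y-%m-%dT%H:%M:%OS3%z")
  report$finishedAt <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  jsonlite::write_json(report, file.path(tmp, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## atomic publish: write everything to a temp dir, then rename into place
  if (dir.exists(config$outDir)) unlink(config$outDir, recursive = TRUE)
  dir.create(dirname(config$outDir), showWarnings = FALSE, recursive = TRUE)
  ok <- file.rename(tmp, config$outDir)
  if (!ok) {   # cross-device fallback
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(tmp, full.names = TRUE), config$outDir,
              recursive = TRUE)
    unlink(tmp, recursive = TRUE)
  }
  invisible(report)
}
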