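#' @include AllClasses.R
NULL

## Category boundaries for a repository of `total` control experiments:
## the largest counts whose detection percentage does not exceed 1% and 10%.
## For the reference total of 411 these are 4 and 41.
.contamBounds <- function(total) {
  c(low = floor(0.01 * total), mid = floor(0.10 * total))
}

#' Categorise a protein's contaminant-repository detection count
#'
#' Converts a detection count into a percentage frequency over the
#' repository's control experiments and assigns the three-tier
#' false-positive-chance category: counts up to 1% of the total (0-4 of 411)
#' are \code{"<=1%"}, counts up to 10% (5-41 of 411) are \code{"<=10%"}, and
#' everything above (42-411 of 411) is \code{"<=100%"}.
#'
#' @param count integer vector of detection counts.
#' @param total total number of control experiments (default 411).
#' @return data.frame with columns \code{count}, \code{percent} (in
#'   [0, 100]) and \code{category} (ordered factor
#'   \code{"<=1%" < "<=10%" < "<=100%"}).
#' @export
scoreContaminant <- function(count, total = 411L) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("counts must lie in [0, total]", call. = FALSE)
  b <- .contamBounds(total)
  category <- ifelse(count <= b["low"], .CONTAM_CATEGORIES[1],
              ifelse(count <= b["mid"], .CONTAM_CATEGORIES[2],
                     .CONTAM_CATEGORIES[3]))
  data.frame(
    count = as.integer(count),
    percent = 100 * count / total,
    category = factor(category, levels = .CONTAM_CATEGORIES, ordered = TRUE)
  )
}

#' Read a contaminant repository file
#'
#' Two accepted layouts: (a) a two-column TSV (\code{protein_id},
#' \code{count}) preceded by a header comment line
#' \code{# total_experiments=<N>}; (b) a full binary 0/1 protein x experiment
#' matrix (first column protein identifiers), from which counts are row sums
#' and the total is the number of experiment columns.
#'
#' @param path input TSV.
#' @return A \code{\linkS4class{ContaminantRepository}}.
#' @export
readContaminantRepository <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*total_experiments\\s*=", first)) {
    total <- as.integer(sub("^#\\s*total_experiments\\s*=\\s*", "", first))
    tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                             stringsAsFactors = FALSE)
    ContaminantRepository(stats::setNames(tab[[2]], tab[[1]]), total)
  } else {
    tab <- .readDelim(path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!all(m %in% c(0, 1)))
      stop("matrix layout must be binary 0/1", call. = FALSE)
    ContaminantRepository(stats::setNames(rowSums(m), tab[[1]]),
                          ncol(m))
  }
}

#' Write a contaminant repository in the two-column dialect
#'
#' @param repo A \code{\linkS4class{ContaminantRepository}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeContaminantRepository <- function(repo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_experiments=%d", repositoryTotal(repo)), con)
  utils::write.table(
    data.frame(protein_id = names(repositoryCounts(repo)),
               count = as.integer(repositoryCounts(repo))),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate a protein list against the contaminant repository
#'
#' Proteins absent from the repository are treated as never observed
#' (count 0, category \code{"<=1%"}) but flagged, since absence of evidence
#' is not evidence of absence. Output order matches input order.
#'
#' @param proteins character vector of protein identifiers.
#' @param repo A \code{\linkS4class{ContaminantRepository}}.
#' @return data.frame with columns \code{proteinId}, \code{count},
#'   \code{percent}, \code{category}, \code{absent}.
#' @export
annotateContaminants <- function(proteins, repo) {
  proteins <- harmonizeId(proteins)
  counts <- repositoryCounts(repo)[proteins]
  absent <- is.na(counts)
  counts[absent] <- 0L
  sc <- scoreContaminant(unname(counts), repositoryTotal(repo))
  data.frame(proteinId = proteins, count = sc$count, percent = sc$percent,
             category = sc$category, absent = unname(absent),
             row.names = NULL, stringsAsFactors = FALSE)
}
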