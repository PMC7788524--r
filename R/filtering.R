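#' @include AllClasses.R
NULL

#' Per-time-point log2 fold changes relative to the unstimulated baseline
#'
#' For every protein and every stimulated time point,
#' \code{log2 FC = mean(log2 abundance at t) - mean(log2 abundance at 0)},
#' computed over the available replicates. A protein-time-point cell is
#' evaluable only when both the baseline and the time point have at least two
#' replicates with positive abundance; otherwise the record is flagged, never
#' reported as infinite.
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @param baselineTime baseline time point in minutes, default 0.
#' @return data.frame with columns \code{proteinId}, \code{timePoint},
#'   \code{log2FoldChange}, \code{evaluable}.
#' @export
computeFoldChanges <- function(qt, baselineTime = 0L) {
  tp <- colData(qt)$timePoint
  if (!baselineTime %in% tp)
    stop("baseline time point ", baselineTime, " missing from the table",
         call. = FALSE)
  la <- log2(assay(qt, "abundance"))
  la[!is.finite(la)] <- NA
  stim <- sort(setdiff(unique(tp), baselineTime))
  base <- la[, tp == baselineTime, drop = FALSE]
  nBase <- rowSums(!is.na(base))
  mBase <- rowMeans(base, na.rm = TRUE)
  out <- lapply(stim, function(t) {
    cur <- la[, tp == t, drop = FALSE]
    nCur <- rowSums(!is.na(cur))
    ok <- nBase >= 2L & nCur >= 2L
    fc <- rowMeans(cur, na.rm = TRUE) - mBase
    fc[!ok] <- NA
    data.frame(proteinId = rownames(la), timePoint = t,
               log2FoldChange = unname(fc), evaluable = unname(ok),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-protein significance across the time course
#'
#' Per protein: a classical one-way ANOVA (equal-variance F test) across all
#' time-point groups on log2 abundances, and a per-time-point Welch two-sample
#' t-test against the baseline. Groups need at least two replicates; when the
#' test statistic is undefined (zero variance everywhere) the p-value is
#' reported as not-evaluable (\code{NA}), never 0. Benjamini-Hochberg
#' adjustment of the t-test p-values across proteins within each time point
#' is optional.
#'
#' @param qt A \code{\linkS4class{QuantTable}}.
#' @param baselineTime baseline time point, default 0.
#' @param adjust \code{"none"} (default, matching raw reporting) or
#'   \code{"BH"}.
#' @return data.frame with columns \code{proteinId}, \code{timePoint},
#'   \code{pT} (per-time-point t-test vs baseline, adjusted if requested)
#'   and \code{pAnova} (one per protein, repeated across its time points).
#' @export
computeSignificance <- function(qt, baselineTime = 0L,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  tp <- colData(qt)$timePoint
  la <- log2(assay(qt, "abundance"))
  la[!is.finite(la)] <- NA
  stim <- sort(setdiff(unique(tp), baselineTime))
  grp <- factor(tp)

  pAnova <- apply(la, 1, function(y) {
    ok <- !is.na(y)
    g <- droplevels(grp[ok])
    if (nlevels(g) < 2L || any(table(g) < 2L)) return(NA_real_)
    p <- tryCatch(
      stats::oneway.test(y[ok] ~ g, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    if (!is.finite(p)) NA_real_ else p
  })

  out <- lapply(stim, function(t) {
    base <- la[, tp == baselineTime, drop = FALSE]
    cur <- la[, tp == t, drop = FALSE]
    pT <- vapply(seq_len(nrow(la)), function(i) {
      x <- base[i, ]; y <- cur[i, ]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      p <- tryCatch(stats::t.test(y, x)$p.value, error = function(e) NA_real_)
      if (!is.finite(p)) NA_real_ else p
    }, numeric(1))
    data.frame(proteinId = rownames(la), timePoint = t, pT = pT,
               pAnova = unname(pAnova), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (adjust == "BH") {
    for (t in stim) {
      i <- res$timePoint == t
      res$pT[i] <- stats::p.adjust(res$pT[i], method = "BH")
    }
  }
  res
}

#' Fold changes and significance in one table
#'
#' @inheritParams computeSignificance
#' @return merged data.frame with columns \code{proteinId}, \code{timePoint},
#'   \code{log2FoldChange}, \code{evaluable}, \code{pT}, \code{pAnova}.
#' @export
computeDifferentials <- function(qt, baselineTime = 0L,
                                 adjust = c("none", "BH")) {
  fc <- computeFoldChanges(qt, baselineTime)
  sig <- computeSignificance(qt, baselineTime, adjust)
  merge(fc, sig, by = c("proteinId", "timePoint"), sort = TRUE)
}

#' Construct a candidate filter specification
#'
#' Defaults follow conventional label-free proteomics practice: at least 2
#' unique peptides (3 in the strict setting), absolute log2 fold change of at
#' least 1 (two-fold), raw p <= 0.05, and contaminant category no worse than
#' \code{"<=10%"}.
#'
#' @param minUniquePeptides 2 or 3.
#' @param minAbsLog2Fc minimum |log2 FC|.
#' @param maxP maximum p-value.
#' @param maxContaminantCategory worst acceptable contaminant category, or
#'   \code{NA} for no contaminant criterion.
#' @param multipleTesting \code{"none"} or \code{"BH"}.
#' @param pSource which p-value the significance criterion uses:
#'   \code{"anova"} (default) applies the per-protein one-way ANOVA across
#'   all time-point groups — the time-course test the workflow's
#'   quantification software exports; \code{"t"} applies the per-time-point
#'   Welch t-test against baseline.
#' @return object of class \code{"FilterSpec"}.
#' @export
filterSpec <- function(minUniquePeptides = 2L, minAbsLog2Fc = 1,
                       maxP = 0.05, maxContaminantCategory = "<=10%",
                       multipleTesting = c("none", "BH"),
                       pSource = c("anova", "t")) {
  multipleTesting <- match.arg(multipleTesting)
  pSource <- match.arg(pSource)
  stopifnot(minUniquePeptides %in% c(2L, 3L),
            is.finite(minAbsLog2Fc), minAbsLog2Fc >= 0,
            is.finite(maxP), maxP > 0, maxP <= 1)
  if (!is.na(maxContaminantCategory) &&
      !maxContaminantCategory %in% .CONTAM_CATEGORIES)
    stop("maxContaminantCategory must be one of: ",
         paste(.CONTAM_CATEGORIES, collapse = ", "), call. = FALSE)
  structure(list(minUniquePeptides = as.integer(minUniquePeptides),
                 minAbsLog2Fc = minAbsLog2Fc, maxP = maxP,
                 maxContaminantCategory = maxContaminantCategory,
                 multipleTesting = multipleTesting, pSource = pSource),
            class = "FilterSpec")
}

#' Classify a protein's temporal recruitment pattern
#'
#' Given which stimulated time points pass the filter and the fold-change
#' signs: \code{early} passes at 2 min only, \code{intermediate} at 7 min
#' only, \code{late} at 15 min only; \code{dissociating} when every passing
#' point has negative fold change; with multiple positive passing points the
#' class is the latest passing point when the fold changes are monotone
#' non-decreasing over the evaluable stimulated points, otherwise
#' \code{mixed}.
#'
#' @param timePoints stimulated time points (minutes), ascending.
#' @param passes logical, which time points pass.
#' @param log2fc fold changes at those time points (NA = not evaluable).
#' @return character(1): one of \code{early}, \code{intermediate},
#'   \code{late}, \code{dissociating}, \code{mixed}, or \code{NA} when no
#'   point passes.
#' @export
classifyTemporalPattern <- function(timePoints, passes, log2fc) {
  ord <- order(timePoints)
  timePoints <- timePoints[ord]; passes <- passes[ord]; log2fc <- log2fc[ord]
  passes[is.na(passes)] <- FALSE
  if (!any(passes)) return(NA_character_)
  passTp <- timePoints[passes]
  passFc <- log2fc[passes]
  single <- c("2" = "early", "7" = "intermediate", "15" = "late")
  if (all(passFc < 0)) return("dissociating")
  if (length(passTp) == 1L) {
    cls <- single[as.character(passTp)]
    return(if (is.na(cls)) "mixed" else unname(cls))
  }
  evalFc <- log2fc[!is.na(log2fc)]
  if (all(diff(evalFc) >= 0) && all(passFc > 0)) {
    cls <- single[as.character(max(passTp))]
    return(if (is.na(cls)) "mixed" else unname(cls))
  }
  "mixed"
}

#' Apply the candidate filter cascade
#'
#' A protein is shortlisted when it (a) has enough unique peptides, (b) is no
#' worse than the allowed contaminant category, and (c) at one or more
#' stimulated time points is evaluable with |log2 FC| and p-value inside the
#' thresholds (the p-value being the per-protein ANOVA or the per-time-point
#' t-test, per the spec's \code{pSource}). Candidates are sorted by best p
#' then descending |log2 FC|;
#' non-candidates are returned with their exclusion reason in
#' \code{attr(, "excluded")}.
#'
#' @param diffs data.frame from \code{\link{computeDifferentials}}.
#' @param qt the \code{\linkS4class{QuantTable}} the differentials came from
#'   (supplies peptide counts).
#' @param contaminants data.frame from \code{\link{annotateContaminants}}
#'   keyed like the quantification rows, or \code{NULL} to skip the
#'   contaminant criterion.
#' @param spec A \code{\link{filterSpec}}.
#' @return data.frame of candidates: \code{proteinId}, \code{temporalClass},
#'   \code{passingTimePoints}, \code{bestP}, \code{maxAbsLog2Fc},
#'   \code{contaminantCategory}, \code{clusterAnchors}.
#' @param clusters optional data.frame from
#'   \code{\link{extractAnchoredClusters}} used to annotate candidates with
#'   the anchors of clusters they belong to.
#' @export
applyFilters <- function(diffs, qt, contaminants = NULL, spec = filterSpec(),
                         clusters = NULL) {
  if (spec$multipleTesting == "BH") {
    if (spec$pSource == "t") {
      for (t in unique(diffs$timePoint)) {
        i <- diffs$timePoint == t
        diffs$pT[i] <- stats::p.adjust(diffs$pT[i], method = "BH")
      }
    } else {
      ## one ANOVA p per protein: adjust across proteins once
      firstTp <- min(diffs$timePoint)
      i <- diffs$timePoint == firstTp
      adj <- stats::setNames(stats::p.adjust(diffs$pAnova[i], method = "BH"),
                             diffs$proteinId[i])
      diffs$pAnova <- unname(adj[diffs$proteinId])
    }
  }
  rd <- rowData(qt)
  peptides <- stats::setNames(rd$uniquePeptides, rownames(qt))
  contamCat <- NULL
  if (!is.null(contaminants))
    contamCat <- stats::setNames(
      as.character(contaminants$category), contaminants$proteinId)

  proteins <- unique(diffs$proteinId)
  candRows <- list(); exclRows <- list()
  for (p in proteins) {
    dd <- diffs[diffs$proteinId == p, , drop = FALSE]
    dd <- dd[order(dd$timePoint), , drop = FALSE]
    if (!is.na(peptides[p]) && peptides[p] < spec$minUniquePeptides) {
      exclRows[[p]] <- "peptides"
      next
    }
    cat <- if (!is.null(contamCat)) contamCat[p] else NA_character_
    if (!is.na(spec$maxContaminantCategory) && !is.null(contamCat) &&
        !is.na(cat) &&
        match(cat, .CONTAM_CATEGORIES) >
          match(spec$maxContaminantCategory, .CONTAM_CATEGORIES)) {
      exclRows[[p]] <- "contaminant"
      next
    }
    pv <- if (spec$pSource == "anova") dd$pAnova else dd$pT
    pass <- dd$evaluable & !is.na(pv) &
      abs(dd$log2FoldChange) >= spec$minAbsLog2Fc & pv <= spec$maxP
    pass[is.na(pass)] <- FALSE
    if (!any(pass)) {
      exclRows[[p]] <- "no_passing_timepoint"
      next
    }
    anchors <- ""
    if (!is.null(clusters) && nrow(clusters))
      anchors <- paste(sort(unique(clusters$anchor[clusters$member == p])),
                       collapse = ",")
    candRows[[p]] <- data.frame(
      proteinId = p,
      temporalClass = classifyTemporalPattern(dd$timePoint, pass,
                                              dd$log2FoldChange),
      passingTimePoints = paste(dd$timePoint[pass], collapse = ","),
      bestP = min(pv[pass]),
      maxAbsLog2Fc = max(abs(dd$log2FoldChange[pass])),
      contaminantCategory = if (is.na(cat)) NA_character_ else cat,
      clusterAnchors = anchors,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(candRows)) do.call(rbind, candRows) else
    data.frame(proteinId = character(), temporalClass = character(),
               passingTimePoints = character(), bestP = numeric(),
               maxAbsLog2Fc = numeric(), contaminantCategory = character(),
               clusterAnchors = character(), stringsAsFactors = FALSE)
  res <- res[order(res$bestP, -res$maxAbsLog2Fc, res$proteinId), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- data.frame(
    proteinId = names(exclRows),
    reason = unlist(exclRows, use.names = FALSE),
    stringsAsFactors = FALSE)
  res
}

#' Volcano-plot table
#'
#' One row per evaluable protein-time-point pair: the log2 fold change and
#' \code{-log10} of the per-time-point p-value. Rows with not-evaluable
#' p-values are omitted and counted in \code{attr(, "omitted")}.
#'
#' @param diffs data.frame from \code{\link{computeDifferentials}}.
#' @return data.frame with columns \code{proteinId}, \code{timePoint},
#'   \code{log2FoldChange}, \code{negLog10P}.
#' @export
volcanoTable <- function(diffs) {
  ok <- diffs$evaluable & !is.na(diffs$pT) & !is.na(diffs$log2FoldChange)
  out <- data.frame(proteinId = diffs$proteinId[ok],
                    timePoint = diffs$timePoint[ok],
                    log2FoldChange = diffs$log2FoldChange[ok],
                    negLog10P = -log10(diffs$pT[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "omitted") <- sum(!ok)
  out
}

#' Diagnostic volcano plot
#'
#' @param diffs data.frame from \code{\link{computeDifferentials}}.
#' @param spec A \code{\link{filterSpec}} whose thresholds are drawn as
#'   guide lines.
#' @return Invisibly, the plotted \code{\link{volcanoTable}}.
#' @export
plotVolcano <- function(diffs, spec = filterSpec()) {
  vt <- volcanoTable(diffs)
  tps <- sort(unique(vt$timePoint))
  old <- graphics::par(mfrow = c(1, length(tps)))
  on.exit(graphics::par(old))
  for (t in tps) {
    v <- vt[vt$timePoint == t, ]
    graphics::plot(v$log2FoldChange, v$negLog10P,
                   pch = 16, cex = 0.6, col = "grey40",
                   xlab = "log2 fold change vs 0 min",
                   ylab = "-log10 p", main = sprintf("%d min", t))
    graphics::abline(v = c(-1, 1) * spec$minAbsLog2Fc, lty = 2)
    graphics::abline(h = -log10(spec$maxP), lty = 2)
  }
  invisible(vt)
}
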