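#' @include AllClasses.R
NULL

#' Uncentred Pearson correlation (cosine similarity)
#'
#' \eqn{r = \sum x_i y_i / (\sqrt{\sum x_i^2}\,\sqrt{\sum y_i^2})}: the
#' Pearson correlation without mean subtraction, i.e. the cosine of the angle
#' between the two profile vectors. Sensitive to shared direction from the
#' origin, symmetric, and invariant to positive rescaling of either argument.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
uncentredPearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("vectors must have equal length >= 2", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("uncentred correlation undefined for a zero-norm vector",
         call. = FALSE)
  max(-1, min(1, sum(x * y) / (nx * ny)))
}

#' Z-score standardisation of one profile
#'
#' Centers to mean 0 and scales to sample standard deviation 1. Constant
#' profiles cannot be standardised; they return a zero vector carrying
#' \code{attr(, "constant") = TRUE} and are excluded from clustering.
#'
#' @param x numeric vector of length >= 2.
#' @return standardised vector.
#' @export
zscoreStandardise <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Per-time-point temporal profiles from a quantification table
#'
#' Builds the matrix clustered by \code{\link{hierarchicalCluster}}: per
#' protein, the log2 abundances are z-scored across all runs and then
#' averaged within each time point, giving one ordered value per time point.
#' Proteins whose profile is constant (zero variance) or not fully evaluable
#' are excluded and listed in \code{attr(, "excluded")}.
#'
#' @param qt A \code{\linkS4class{QuantTable}} (normalised abundances
#'   recommended).
#' @return numeric matrix (proteins x time points) with time-point column
#'   names \code{t<minutes>}.
#' @export
profileMatrix <- function(qt) {
  ab <- assay(qt, "abundance")
  la <- log2(ab)
  la[!is.finite(la)] <- NA
  tp <- colData(qt)$timePoint
  tps <- sort(unique(tp))
  n <- nrow(la)
  prof <- matrix(NA_real_, n, length(tps),
                 dimnames = list(rownames(la), paste0("t", tps)))
  constant <- logical(n)
  for (i in seq_len(n)) {
    z <- zscoreStandardise(la[i, ])
    constant[i] <- isTRUE(attr(z, "constant"))
    prof[i, ] <- vapply(tps, function(t) mean(z[tp == t], na.rm = TRUE),
                        numeric(1))
  }
  usable <- !constant & rowSums(!is.finite(prof)) == 0L
  out <- prof[usable, , drop = FALSE]
  attr(out, "excluded") <- rownames(la)[!usable]
  out
}

## Pairwise uncentred-Pearson similarity matrix over profile rows.
.cosineSimilarity <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0))
    stop("zero-norm profile(s): ",
         paste(rownames(m)[norms == 0], collapse = ", "), call. = FALSE)
  s <- (m %*% t(m)) / outer(norms, norms)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Agglomerative complete-linkage clustering with uncentred-Pearson distance
#'
#' Clusters temporal profiles with the dissimilarity \eqn{d = 1 - r}
#' (uncentred Pearson \eqn{r}) under complete linkage: the distance between
#' two clusters is the maximum pairwise member distance, which guarantees
#' merge heights never decrease. Tie-breaking is fully deterministic: every
#' cluster is identified by its lexicographically smallest member label, and
#' among candidate merges at the minimal distance the pair whose sorted
#' (id_a, id_b) is lexicographically smallest merges first, so permuting the
#' input rows leaves the tree unchanged.
#'
#' @param profiles numeric matrix (>= 2 rows) with unique row names; rows are
#'   profiles, e.g. from \code{\link{profileMatrix}}.
#' @return An object of class \code{"hclust"} (merge matrix, heights, labels,
#'   leaf order), directly usable with \code{\link[stats]{cutree}}.
#' @export
hierarchicalCluster <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L)
    stop("need at least 2 profiles to cluster", call. = FALSE)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("profiles need unique row names", call. = FALSE)
  labels <- rownames(m)
  n <- nrow(m)
  d <- 1 - .cosineSimilarity(m)
  d[d < 1e-12] <- 0
  diag(d) <- Inf

  ## active cluster bookkeeping: id = lexicographically smallest member label
  clusterId <- labels               # per active cluster
  mergeRef <- -seq_len(n)           # hclust convention: -leaf or +step
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## deterministic tie-break on sorted cluster-id pairs
    pairIds <- t(apply(cand, 1, function(rc)
      sort(c(clusterId[idx[rc[1]]], clusterId[idx[rc[2]]]))))
    best <- order(pairIds[, 1], pairIds[, 2])[1]
    i <- idx[cand[best, 1]]; j <- idx[cand[best, 2]]

    a <- mergeRef[i]; b <- mergeRef[j]
    if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
        (a > 0 && b < 0)) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a, b)
    height[step] <- h

    ## complete linkage: new cluster distance is the max of the two
    newd <- pmax(d[i, ], d[j, ])
    d[i, ] <- newd; d[, i] <- newd
    d[i, i] <- Inf
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    clusterId[i] <- min(clusterId[i], clusterId[j])
    mergeRef[i] <- step
  }

  order <- .leafOrder(merge, n)
  structure(
    list(merge = merge, height = height, order = order, labels = labels,
         method = "complete", call = match.call(),
         dist.method = "uncentred-pearson"),
    class = "hclust")
}

.leafOrder <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(n - 1L)
}

#' Extract clusters anchored on known bait binders
#'
#' Cuts the tree at height \code{1 - minR} and, for every known binder
#' present in the data, reports the binder's cluster, post-filtered so that
#' every reported member's uncentred Pearson correlation with the anchor
#' profile is at least \code{minR}. Clusters from distinct anchors may
#' overlap and are reported separately.
#'
#' @param tree \code{hclust} object from \code{\link{hierarchicalCluster}}.
#' @param profiles the profile matrix the tree was built from.
#' @param knownBinders character vector of known-binder identifiers.
#' @param minR minimum anchor-member correlation, default 0.7.
#' @return data.frame with columns \code{anchor}, \code{member}, \code{r}
#'   (the anchor rows themselves have \code{r = 1}).
#' @export
extractAnchoredClusters <- function(tree, profiles, knownBinders,
                                    minR = 0.7) {
  if (minR <= -1 || minR > 1)
    stop("minR must lie in (-1, 1]", call. = FALSE)
  profiles <- as.matrix(profiles)
  anchors <- intersect(knownBinders, rownames(profiles))
  empty <- data.frame(anchor = character(), member = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (!length(anchors)) {
    warning("no known binder present in the profile matrix")
    return(empty)
  }
  cl <- stats::cutree(tree, h = 1 - minR)
  out <- lapply(anchors, function(a) {
    members <- names(cl)[cl == cl[[a]]]
    r <- vapply(members, function(mb)
      uncentredPearson(profiles[mb, ], profiles[a, ]), numeric(1))
    keep <- r >= minR - 1e-12
    data.frame(anchor = a, member = members[keep], r = unname(r[keep]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write cluster outputs
#'
#' Emits the cluster-membership table (anchor, member, r) and the tree's
#' merge history as TSV.
#'
#' @param clusters data.frame from \code{\link{extractAnchoredClusters}}.
#' @param tree \code{hclust} object.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeClusters <- function(clusters, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "clusters.tsv")
  p2 <- file.path(dir, "merge_history.tsv")
  utils::write.table(clusters, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(step = seq_along(tree$height), a = tree$merge[, 1],
               b = tree$merge[, 2], height = tree$height),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(clusters = p1, merges = p2))
}
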