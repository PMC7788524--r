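#' Harmonise a protein identifier
#'
#' Uppercases gene symbols, trims whitespace and strips numeric species-taxon
#' prefixes of the form \code{"9606."} that STRING-style exports prepend, so
#' that mouse MS hits can be matched onto a cross-species literature network
#' by symbol equality.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of harmonised identifiers.
#' @export
harmonizeId <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[0-9]+\\.", "", x)
  toupper(x)
}

## Largest-remainder (Hamilton) apportionment of n items to proportions.
## Deterministic: ties in remainders resolved by position order.
largestRemainder <- function(proportions, n) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, n >= 0)
  quota <- proportions * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    ord <- order(-rem, seq_along(rem))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

## Resolve one required column among candidate header spellings
## (case/punctuation-insensitive). Errors naming the column role if absent.
.resolveColumn <- function(headers, candidates, role) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  hit <- match(norm(candidates), norm(headers))
  hit <- hit[!is.na(hit)]
  if (!length(hit))
    stop(sprintf("required column for %s not found (looked for: %s)",
                 role, paste(candidates, collapse = ", ")), call. = FALSE)
  headers[hit[1]]
}

.readDelim <- function(path, sep = "\t", ...) {
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", ...)
}
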