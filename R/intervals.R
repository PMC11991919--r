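#' @keywords internal
"_PACKAGE"

## Exon chains are integer matrices with columns start, end in 0-based
## half-open coordinates. All interval arithmetic in the package goes
## through the helpers below; the GTF converters are the only place the
## 1-based shift happens.

#' Build an exon-chain matrix
#'
#' @param start,end Integer vectors of 0-based half-open exon coordinates.
#' @return An integer matrix with columns `start` and `end`, sorted by start.
#' @export
exon_chain <- function(start, end) {
  stopifnot(length(start) == length(end))
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m <- m[order(m[, "start"]), , drop = FALSE]
  validate_exons(m)
  m
}

validate_exons <- function(exons) {
  if (!is.matrix(exons) || ncol(exons) != 2L || nrow(exons) < 1L)
    stop("exons must be a matrix with columns start, end and >= 1 row")
  if (any(exons[, 1] < 0L) || any(exons[, 2] <= exons[, 1]))
    stop("invalid exon: require 0 <= start < end")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons[-nrow(exons), 2] > exons[-1L, 1]))
    stop("exons must be pairwise non-overlapping (touching exons merge upstream)")
  invisible(exons)
}

## Introns are the gaps between consecutive exons; empty matrix for
## single-exon chains.
introns_of <- function(exons) {
  n <- nrow(exons)
  if (n < 2L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exons[-n, 2], end = exons[-1L, 1])
}

exon_span <- function(exons) c(exons[1L, 1], exons[nrow(exons), 2])

exon_length <- function(exons) sum(exons[, 2] - exons[, 1])

## Total overlapping bases between two exon chains.
exonic_overlap_bp <- function(a, b) {
  total <- 0L
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    total <- total + sum(pmax(0L, hi - lo))
  }
  total
}

## Key for exact junction (intron) matching: "start-end" strings.
intron_keys <- function(exons) {
  ii <- introns_of(exons)
  if (nrow(ii) == 0L) return(character(0))
  paste(ii[, 1], ii[, 2], sep = "-")
}

## Is `inner` (a chain of intron keys) a contiguous sub-chain of `outer`?
## Empty inner counts as a sub-chain at any position.
is_contiguous_subchain <- function(inner, outer) {
  if (length(inner) == 0L) return(TRUE)
  if (length(inner) > length(outer)) return(FALSE)
  for (off in 0:(length(outer) - length(inner))) {
    if (all(outer[off + seq_along(inner)] == inner)) return(TRUE)
  }
  FALSE
}
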