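#' Genomic interval frames
#'
#' All coordinates inside dirtseq live in a single convention: 0-based,
#' half-open `[start, end)`, so `length = end - start` and abutting features
#' share a breakpoint without overlapping. GFF3 input (1-based, inclusive) is
#' converted at parse time; BED input is already 0-based half-open and is
#' taken as-is. Intervals are stored as plain data frames with columns
#' `chrom`, `start`, `end`, `strand` so they print, subset and join like any
#' other table.
#'
#' @param chrom character vector of chromosome/scaffold names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded), recycled.
#' @return data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing numbers")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end < start)) stop("interval end must be >= start")
  bad <- !strand %in% c("+", "-", "*")
  if (any(bad)) stop("strand must be one of '+', '-', '*'")
  data.frame(
    chrom = as.character(chrom), start = start, end = end,
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
}

#' Interval lengths
#'
#' @param x interval frame (see [genomic_intervals()]).
#' @return numeric vector of `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

## TRUE where intervals a[i] and b[i] (recycled b) share >= 1 base on the
## same chromosome; half-open, so abutting intervals do not overlap.
interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  pmax(a_start, b_start) < pmin(a_end, b_end)
}

## IRanges view of an interval frame (1-based closed) for overlap machinery.
## Zero-length intervals are dropped: they cover no base.
.as_iranges <- function(x) {
  keep <- x$end > x$start
  IRanges::IRanges(start = x$start[keep] + 1L, end = x$end[keep])
}

## Any-overlap test of each row of `x` against a set of intervals `y`,
## chromosome-aware. Returns logical along rows of x.
overlaps_any <- function(x, y) {
  out <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    if (!length(yi)) next
    xr <- IRanges::IRanges(x$start[xi] + 1L, pmax(x$end[xi], x$start[xi] + 1L))
    ## zero-length x intervals cannot overlap anything: mask them below
    yr <- .as_iranges(y[yi, , drop = FALSE])
    hit <- IRanges::overlapsAny(xr, yr)
    hit[x$end[xi] == x$start[xi]] <- FALSE
    out[xi] <- hit
  }
  out
}
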