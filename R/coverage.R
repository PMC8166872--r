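#' Count reads per feature
#'
#' Assigns alignment records to features by any-overlap of aligned blocks,
#' with the two counting policies used in the pipeline:
#'
#' * `policy = "pcg"` — featureCounts-style: only records with
#'   `mapq >= mapq_min` (default 10) are assigned; a read contributes at most
#'   once to each feature it overlaps. Paired-end data represented with a
#'   shared read id per fragment is therefore counted per fragment.
#' * `policy = "trna"` — no mapping-quality filter and multi-mapped records
#'   retained: with hundreds of near-identical tRNA genes, unique mapping is
#'   rarely possible and discarding multi-mappers would silence most loci.
#'
#' @param alignments a `dirt_alignments` object.
#' @param features data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and an id column named by `id_col`.
#' @param policy `"pcg"` or `"trna"`.
#' @param id_col name of the feature-id column.
#' @param mapq_min mapping-quality threshold for `policy = "pcg"`.
#' @return named integer vector of raw counts, one per feature row.
#' @export
count_feature_reads <- function(alignments, features, policy = c("pcg", "trna"),
                                id_col = NULL, mapq_min = 10L) {
  policy <- match.arg(policy)
  stopifnot(inherits(alignments, "dirt_alignments"))
  if (is.null(id_col))
    id_col <- intersect(c("feature_id", "trna_id", "gene_id"), names(features))[1]
  if (is.na(id_col) || is.null(id_col)) stop("cannot determine feature id column")
  ids <- as.character(features[[id_col]])
  counts <- stats::setNames(integer(nrow(features)), ids)
  bl <- alignments$blocks
  if (policy == "pcg") bl <- bl[bl$mapq >= mapq_min, ]
  if (!nrow(bl) || !nrow(features)) return(counts)
  if (any(features$end <= features$start))
    warning("degenerate (empty) feature interval(s): counted as 0")
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch & features$end > features$start)
    if (!length(fi)) next
    bi <- bl$chrom == ch
    if (!any(bi)) {
      warning("no alignments on chromosome '", ch, "': counts set to 0")
      next
    }
    br <- IRanges::IRanges(bl$start[bi] + 1L, bl$end[bi])
    fr <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    hits <- IRanges::findOverlaps(br, fr)
    if (!length(hits)) next
    dt <- data.table::data.table(
      read_id = bl$read_id[bi][S4Vectors::queryHits(hits)],
      feat = S4Vectors::subjectHits(hits)
    )
    per <- dt[, list(n = length(unique(read_id))), by = "feat"]
    counts[fi[per$feat]] <- counts[fi[per$feat]] + per$n
  }
  counts
}

#' Per-base read coverage of a region
#'
#' `counts[i]` is the number of aligned blocks covering base
#' `region$start + i - 1`. No mapping-quality filter is applied: this mirrors
#' total coverage computed on merged alignments. An empty region yields an
#' empty (valid) track.
#'
#' @param alignments a `dirt_alignments` object.
#' @param region a one-row interval frame (`chrom`, `start`, `end`).
#' @return a `coverage_track`: list with `region` and integer `counts` of
#'   length `region$end - region$start`.
#' @export
per_base_coverage <- function(alignments, region) {
  stopifnot(inherits(alignments, "dirt_alignments"), nrow(region) == 1L)
  len <- as.integer(region$end - region$start)
  if (len < 0L) stop("region end < start")
  counts <- integer(len)
  if (len > 0L) {
    bl <- alignments$blocks
    bi <- bl$chrom == region$chrom & bl$start < region$end & bl$end > region$start
    if (any(bi)) {
      ## difference-array accumulation over clipped blocks
      s <- pmax(bl$start[bi], region$start) - region$start + 1L
      e <- pmin(bl$end[bi], region$end) - region$start
      delta <- integer(len + 1L)
      tab_s <- tabulate(s, nbins = len + 1L)
      tab_e <- tabulate(e + 1L, nbins = len + 1L)
      counts <- cumsum(tab_s - tab_e)[seq_len(len)]
    }
  }
  structure(list(region = region, counts = counts), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s:%d-%d (%d bp), mean %.3f\n",
              x$region$chrom, x$region$start, x$region$end,
              length(x$counts),
              if (length(x$counts)) mean(x$counts) else NA_real_))
  invisible(x)
}

#' Mean per-base coverage of a track
#'
#' @param track a `coverage_track`.
#' @return arithmetic mean of the counts. Errors on an empty region, which
#'   drives zero-length intergenic gaps onto the `untestable` path.
#' @export
mean_region_coverage <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (!length(track$counts))
    stop("mean coverage of an empty region is undefined")
  mean(track$counts)
}

#' Sum coverage tracks over replicates
#'
#' @param tracks list of `coverage_track`s over the same region.
#' @return a merged `coverage_track` with summed counts.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  r0 <- tracks[[1L]]$region
  for (t in tracks) stopifnot(identical(t$region$chrom, r0$chrom),
                              t$region$start == r0$start,
                              t$region$end == r0$end)
  counts <- Reduce(`+`, lapply(tracks, `[[`, "counts"))
  structure(list(region = r0, counts = as.integer(counts)),
            class = "coverage_track")
}

## Whole-chromosome coverage as Rle per chromosome; used internally so that
## one pass over the blocks serves every region lookup in a group run.
.coverage_rle <- function(alignments) {
  bl <- alignments$blocks
  out <- list()
  for (ch in unique(bl$chrom)) {
    bi <- bl$chrom == ch
    out[[ch]] <- IRanges::coverage(IRanges::IRanges(bl$start[bi] + 1L,
                                                    bl$end[bi]))
  }
  out
}

## Extract a region's counts from a .coverage_rle result.
.rle_window <- function(cov, chrom, start, end) {
  len <- as.integer(end - start)
  if (len <= 0L) return(integer(0))
  r <- cov[[chrom]]
  if (is.null(r)) return(integer(len))
  n <- length(r)
  lo <- start + 1L; hi <- end
  if (lo > n) return(integer(len))
  inside <- as.integer(S4Vectors::window(r, lo, min(hi, n)))
  c(inside, integer(len - length(inside)))
}

#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph (0-based half-open) suitable for genome-browser
#' inspection of candidate loci.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  cnt <- track$counts
  if (length(cnt)) {
    r <- rle(cnt)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", track$region$chrom,
                         track$region$start + starts[keep],
                         track$region$start + ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Write a feature-by-replicate count matrix as TSV
#'
#' @param counts matrix (features in rows, replicates in columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
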