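#' Read aligned reads from SAM or BAM
#'
#' Loads mapped records into a light in-memory representation used by the
#' counting and coverage routines: one row per alignment record plus one row
#' per aligned block (spliced alignments with `N` CIGAR operations contribute
#' several blocks; skipped gaps carry no coverage, so a spliced alignment
#' across an intergenic gap cannot fake read-through). Coordinates are
#' converted to the internal 0-based half-open convention. Secondary and
#' supplementary alignments are kept (multi-mapped reads are informative for
#' tRNA loci); unmapped records are dropped.
#'
#' SAM input is converted on the fly with [Rsamtools::asBam()] (sorted and
#' indexed in a temporary directory); BAM input must be accompanied by an
#' index or be sortable in place.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return an object of class `dirt_alignments`: list with
#'   * `reads`: data.table `read_id`, `chrom`, `start`, `end`, `mapq`, `nh`,
#'   * `blocks`: data.table `read_id`, `chrom`, `start`, `end`,
#'   * `source`: the input path.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (ext == "bam") {
    bam <- path
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
      ## unindexed BAM: sort+index a temporary copy rather than erroring on
      ## the user's file in place
      dest <- tempfile(fileext = "")
      sorted <- Rsamtools::sortBam(path, dest)
      Rsamtools::indexBam(sorted)
      bam <- sorted
    }
  } else stop("expected a .sam or .bam file, got: ", path)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  meta <- S4Vectors::mcols(ga)
  nh <- meta$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(ga))
  nh[is.na(nh)] <- 1L
  mapq <- meta$mapq
  mapq[is.na(mapq)] <- 0L
  reads <- data.table::data.table(
    read_id = as.character(meta$qname),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1,
    end = as.numeric(GenomicAlignments::end(ga)),
    mapq = as.integer(mapq),
    nh = as.integer(nh)
  )
  bl <- GenomicAlignments::grglist(ga, drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(bl)
  flat <- unlist(bl, use.names = FALSE)
  blocks <- data.table::data.table(
    read_id = rep(reads$read_id, nb),
    chrom = rep(reads$chrom, nb),
    start = GenomicRanges::start(flat) - 1,
    end = as.numeric(GenomicRanges::end(flat)),
    mapq = rep(reads$mapq, nb)
  )
  dirt_alignments(reads, blocks, source = path)
}

#' Construct an alignment set from tables
#'
#' Mainly used by the simulator and tests to build alignment sets without
#' file I/O. `blocks` defaults to one block per read (unspliced records).
#'
#' @param reads data frame with `read_id`, `chrom`, `start`, `end`, `mapq`,
#'   `nh` (0-based half-open).
#' @param blocks optional data frame `read_id`, `chrom`, `start`, `end`,
#'   `mapq`.
#' @param source label recorded for provenance.
#' @return a `dirt_alignments` object.
#' @export
dirt_alignments <- function(reads, blocks = NULL, source = "<memory>") {
  reads <- data.table::as.data.table(reads)
  if (!"nh" %in% names(reads)) reads$nh <- 1L
  if (!"mapq" %in% names(reads)) reads$mapq <- 60L
  if (is.null(blocks))
    blocks <- reads[, c("read_id", "chrom", "start", "end", "mapq")]
  blocks <- data.table::as.data.table(blocks)
  structure(list(reads = reads, blocks = blocks, source = source),
            class = "dirt_alignments")
}

#' @export
print.dirt_alignments <- function(x, ...) {
  cat("dirt_alignments:", nrow(x$reads), "records,",
      nrow(x$blocks), "aligned blocks [", x$source, "]\n")
  invisible(x)
}

#' Concatenate alignment sets (replicate merging)
#'
#' Equivalent to merging BAM files: coverage of the merged set equals the
#' sum of the per-replicate coverages.
#'
#' @param ... `dirt_alignments` objects, or a single list of them.
#' @return a merged `dirt_alignments`.
#' @export
merge_alignments <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "dirt_alignments")) xs <- xs[[1L]]
  stopifnot(all(vapply(xs, inherits, logical(1), "dirt_alignments")))
  dirt_alignments(
    data.table::rbindlist(lapply(xs, `[[`, "reads")),
    data.table::rbindlist(lapply(xs, `[[`, "blocks")),
    source = "<merged>"
  )
}

#' Read a replicate-grouping table
#'
#' A TSV with columns `group_id`, `replicate_id`, `path` mapping alignment
#' files to biological replicates and groups (e.g. growing sub-regions or
#' tissues). Relative paths are resolved against the table's directory.
#'
#' @param path path to the TSV.
#' @return data frame `group_id`, `replicate_id`, `path`.
#' @export
read_group_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "replicate_id", "path")
  if (!all(need %in% names(g)))
    stop("group table needs columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", g$path)
  g$path[rel] <- file.path(dirname(path), g$path[rel])
  g[, need]
}
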