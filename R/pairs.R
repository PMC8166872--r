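#' Assemble adjacent tRNA / protein-coding gene pairs
#'
#' For every tRNA gene that does not overlap any protein-coding gene span
#' (UTRs and introns included), the nearest PCG upstream and the nearest PCG
#' downstream on the same chromosome each form a candidate pair, so a tRNA
#' flanked on both sides yields two pairs. Strand is recorded but ignored:
#' read-through is detectable in either genomic orientation. tRNAs that
#' overlap a PCG are discarded (their reads cannot be assigned unambiguously)
#' and tRNAs on chromosomes absent from the gene models yield no pair.
#'
#' Each pair carries its intergenic interval (the gap between the two feature
#' spans, possibly empty), the distance in bp, and the coordinates of up to
#' two introns of the PCG closest to the intergenic gap, closest first.
#' Equidistant genes on one side are resolved toward the smaller start
#' coordinate and flagged in `tie_flag`.
#'
#' @param trnas tRNA table from [parse_trna_annotations()].
#' @param pcgs gene models from [parse_gene_models()] (a `pcg_set`).
#' @param max_distance drop pairs whose intergenic gap exceeds this many bp
#'   (default `Inf`: no cap).
#' @return data frame with one row per pair: `trna_id`, `gene_id`, `chrom`,
#'   `orientation` (`tRNA-upstream` / `tRNA-downstream` relative to the PCG),
#'   feature coordinates, `intergenic_start`, `intergenic_end`, `distance`,
#'   `n_introns`, `intron1_start/end`, `intron2_start/end` (NA when absent)
#'   and `tie_flag`.
#' @export
assemble_pairs <- function(trnas, pcgs, max_distance = Inf) {
  stopifnot(inherits(pcgs, "pcg_set"))
  genes <- pcgs$genes
  if (!nrow(trnas)) return(.empty_pairs())

  overlapped <- overlaps_any(trnas, genes)
  missing_chrom <- !trnas$chrom %in% genes$chrom
  if (any(missing_chrom & !overlapped))
    message(sum(missing_chrom & !overlapped),
            " tRNA(s) on chromosomes absent from the gene models: no pairs")
  cand <- trnas[!overlapped & !missing_chrom, , drop = FALSE]

  rows <- vector("list", 2L * nrow(cand))
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    t <- cand[i, ]
    g <- genes[genes$chrom == t$chrom, , drop = FALSE]
    ## upstream of the tRNA: gene ends at or before the tRNA start
    up <- g[g$end <= t$start, , drop = FALSE]
    if (nrow(up)) {
      d <- t$start - up$end
      sel <- which(d == min(d))
      tie <- length(sel) > 1L
      sel <- sel[which.min(up$start[sel])]
      k <- k + 1L
      rows[[k]] <- .pair_row(t, up[sel, ], pcgs,
                             orientation = "tRNA-downstream",
                             ig_start = up$end[sel], ig_end = t$start,
                             tie = tie)
    }
    ## downstream of the tRNA: gene starts at or after the tRNA end
    dn <- g[g$start >= t$end, , drop = FALSE]
    if (nrow(dn)) {
      d <- dn$start - t$end
      sel <- which(d == min(d))
      tie <- length(sel) > 1L
      sel <- sel[which.min(dn$start[sel])]
      k <- k + 1L
      rows[[k]] <- .pair_row(t, dn[sel, ], pcgs,
                             orientation = "tRNA-upstream",
                             ig_start = t$end, ig_end = dn$start[sel],
                             tie = tie)
    }
  }
  if (!k) return(.empty_pairs())
  out <- do.call(rbind, rows[seq_len(k)])
  out <- out[out$distance <= max_distance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## one assembled pair; introns ranked by proximity to the intergenic gap
.pair_row <- function(trna, gene, pcgs, orientation, ig_start, ig_end, tie) {
  ex <- pcgs$exons[pcgs$exons$gene_id == gene$gene_id, , drop = FALSE]
  introns <- derive_introns(ex)
  if (nrow(introns)) {
    ## intergenic gap sits before the gene (tRNA upstream) -> first introns
    ## are closest; gap after the gene -> last introns are closest
    ord <- if (orientation == "tRNA-upstream") order(introns$start)
           else order(-introns$start)
    introns <- introns[ord, , drop = FALSE]
  }
  i1 <- if (nrow(introns) >= 1) introns[1, ] else NULL
  i2 <- if (nrow(introns) >= 2) introns[2, ] else NULL
  data.frame(
    trna_id = trna$trna_id, gene_id = gene$gene_id, chrom = trna$chrom,
    orientation = orientation,
    trna_start = trna$start, trna_end = trna$end,
    gene_start = gene$start, gene_end = gene$end,
    intergenic_start = ig_start, intergenic_end = ig_end,
    distance = ig_end - ig_start,
    n_introns = nrow(introns),
    intron1_start = if (is.null(i1)) NA_real_ else i1$start,
    intron1_end = if (is.null(i1)) NA_real_ else i1$end,
    intron2_start = if (is.null(i2)) NA_real_ else i2$start,
    intron2_end = if (is.null(i2)) NA_real_ else i2$end,
    tie_flag = tie,
    stringsAsFactors = FALSE
  )
}

.empty_pairs <- function() {
  data.frame(
    trna_id = character(0), gene_id = character(0), chrom = character(0),
    orientation = character(0), trna_start = numeric(0), trna_end = numeric(0),
    gene_start = numeric(0), gene_end = numeric(0),
    intergenic_start = numeric(0), intergenic_end = numeric(0),
    distance = numeric(0), n_introns = integer(0),
    intron1_start = numeric(0), intron1_end = numeric(0),
    intron2_start = numeric(0), intron2_end = numeric(0),
    tie_flag = logical(0), stringsAsFactors = FALSE
  )
}

#' Write a candidate-pair table as TSV
#'
#' @param pairs pair table from [assemble_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("trna_id", "gene_id", "chrom", "orientation",
            "intergenic_start", "intergenic_end", "distance")
  utils::write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
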