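#' Detection configuration
#'
#' Thresholds of the detection procedure. Defaults follow the published
#' workflow: a tRNA is "expressed" from a single raw read (tRNAs are heavily
#' underrepresented in standard RNA-seq libraries), a PCG from 10 reads;
#' candidate intergenic regions must beat both flanking introns at
#' Benjamini-Hochberg FDR < 0.05; featureCounts-style gene assignment uses
#' mapping quality >= 10.
#'
#' @param trna_min_reads minimum group-level raw reads on the tRNA (>= 1).
#' @param pcg_min_reads minimum group-level raw reads on the PCG (>= 10).
#' @param fdr_alpha BH FDR threshold, in (0, 1).
#' @param mapq_min mapping-quality threshold for PCG read assignment.
#' @param max_distance maximum intergenic distance in bp (`Inf`: no cap).
#' @return object of class `detection_config`.
#' @export
detection_config <- function(trna_min_reads = 1L, pcg_min_reads = 10L,
                             fdr_alpha = 0.05, mapq_min = 10L,
                             max_distance = Inf) {
  stopifnot(trna_min_reads >= 0, pcg_min_reads >= 0, mapq_min >= 0,
            fdr_alpha > 0, fdr_alpha < 1, max_distance >= 0)
  structure(list(trna_min_reads = trna_min_reads,
                 pcg_min_reads = pcg_min_reads,
                 fdr_alpha = fdr_alpha, mapq_min = mapq_min,
                 max_distance = max_distance),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(paste0("detection_config: tRNA >= %d reads, PCG >= %d reads, ",
                     "FDR < %g, mapq >= %d, max distance %s bp\n"),
              x$trna_min_reads, x$pcg_min_reads, x$fdr_alpha, x$mapq_min,
              format(x$max_distance)))
  invisible(x)
}

#' Expression filter on assembled pairs
#'
#' A pair survives iff its tRNA has at least `trna_min_reads` and its PCG at
#' least `pcg_min_reads` raw reads, counts summed over the group's
#' replicates.
#'
#' @param pairs pair table from [assemble_pairs()].
#' @param trna_counts named numeric vector of group-level tRNA counts.
#' @param pcg_counts named numeric vector of group-level PCG counts.
#' @param config a [detection_config()].
#' @return the surviving subset of `pairs`.
#' @export
filter_expressed_pairs <- function(pairs, trna_counts, pcg_counts,
                                   config = detection_config()) {
  if (!nrow(pairs)) return(pairs)
  missing_t <- setdiff(pairs$trna_id, names(trna_counts))
  missing_g <- setdiff(pairs$gene_id, names(pcg_counts))
  if (length(missing_t) || length(missing_g))
    stop("pair(s) reference features with no counts: ",
         paste(c(missing_t, missing_g), collapse = ", "))
  keep <- trna_counts[pairs$trna_id] >= config$trna_min_reads &
    pcg_counts[pairs$gene_id] >= config$pcg_min_reads
  pairs[keep, , drop = FALSE]
}

#' Intergenic-versus-intron contrast test
#'
#' Paired one-sided t-test across biological replicates of the hypothesis
#' that mean intergenic coverage exceeds mean intron coverage, computed on
#' the per-replicate differences. Degenerate cases, common with integer
#' coverage on short regions, have explicit conventions: all differences
#' exactly zero gives p = 1 (no evidence); nonzero constant differences
#' (zero variance, nonzero mean) give a vanishing p with
#' `degenerate = TRUE`.
#'
#' @param intergenic_means per-replicate mean intergenic coverage.
#' @param intron_means per-replicate mean intron coverage, aligned by
#'   replicate.
#' @return list with `p` (in (0, 1]), `direction` (sign of the mean
#'   difference) and `degenerate`.
#' @export
intron_contrast_test <- function(intergenic_means, intron_means) {
  if (length(intergenic_means) != length(intron_means))
    stop("replicate vectors must be aligned (equal length)")
  n <- length(intergenic_means)
  if (n < 2L) stop("at least 2 replicates required for the contrast test")
  d <- intergenic_means - intron_means
  if (all(d == 0))
    return(list(p = 1, direction = 0, degenerate = FALSE))
  if (stats::sd(d) == 0)  # constant nonzero difference: infinite t statistic
    return(list(p = .Machine$double.xmin, direction = sign(d[1L]),
                degenerate = TRUE))
  tt <- stats::t.test(d, mu = 0, alternative = "greater")
  list(p = max(tt$p.value, .Machine$double.xmin),
       direction = sign(mean(d)), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (order-preserving, capped at 1),
#' pooled over all pairs and both intron contrasts within one group run.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return vector of q-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Continuity criterion
#'
#' TRUE iff every base of the merged intergenic track carries at least one
#' read: evidence that at least one full-length dicistronic molecule was
#' sequenced. An empty region is vacuously continuous (such pairs are
#' already routed to the `untestable` verdict).
#'
#' @param track merged intergenic `coverage_track`.
#' @return logical scalar; attribute `vacuous` marks the empty-region case.
#' @export
continuity_check <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (!length(track$counts))
    return(structure(TRUE, vacuous = TRUE))
  structure(min(track$counts) >= 1L, vacuous = FALSE)
}

#' Run the full dicistronic detection procedure
#'
#' For each replicate group independently (e.g. each growing sub-region or
#' tissue), this executes the decision cascade on every assembled pair:
#'
#' 1. expression filter: tRNA and PCG raw counts over the group's replicates
#'    (tRNA counting keeps multi-mapped reads; PCG counting applies the
#'    mapping-quality threshold);
#' 2. intergenic-vs-intron contrasts: per-replicate mean coverages of the
#'    intergenic gap against the closest (and, when present, second-closest)
#'    intron, each a paired one-sided t-test; all p-values of the group run
#'    are BH-adjusted together and every contrast must reach
#'    `q < fdr_alpha`;
#' 3. direction: merged (summed over replicates) intergenic mean coverage
#'    must exceed each merged intron mean;
#' 4. continuity: at least one read on every intergenic base of the merged
#'    track.
#'
#' Single-intron genes are tested against that one intron; intronless genes,
#' zero-length intergenic gaps ("adjacent" pairs) and groups with fewer than
#' two replicates are `untestable`.
#'
#' @param pairs pair table from [assemble_pairs()].
#' @param alignments named list mapping replicate ids to `dirt_alignments`
#'   objects or SAM/BAM paths.
#' @param groups data frame `group_id`, `replicate_id`.
#' @param config a [detection_config()].
#' @param trnas,pcg_genes optional feature tables (`trna_id`/`gene_id`,
#'   `chrom`, `start`, `end`) for counting; defaults are reconstructed from
#'   `pairs`, which is sufficient for pairs-only runs.
#' @return data frame of class `dirt_calls`, one row per pair per group:
#'   ids, coordinates, per-contrast p and q, merged means, `direction_ok`,
#'   `continuous`, `verdict` in `{dicistronic, rejected_expression,
#'   rejected_test, rejected_direction, rejected_continuity, untestable}`.
#'   Per-replicate means are attached as attribute `replicate_means`.
#' @export
run_dirt <- function(pairs, alignments, groups, config = detection_config(),
                     trnas = NULL, pcg_genes = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "replicate_id") %in% names(groups)))
  pairs <- pairs[pairs$distance <= config$max_distance, , drop = FALSE]
  if (is.null(trnas))
    trnas <- unique(data.frame(trna_id = pairs$trna_id, chrom = pairs$chrom,
                               start = pairs$trna_start, end = pairs$trna_end,
                               stringsAsFactors = FALSE))
  if (is.null(pcg_genes))
    pcg_genes <- unique(data.frame(gene_id = pairs$gene_id, chrom = pairs$chrom,
                                   start = pairs$gene_start, end = pairs$gene_end,
                                   stringsAsFactors = FALSE))
  alignments <- lapply(alignments, function(a)
    if (inherits(a, "dirt_alignments")) a else read_alignments(a))

  out <- list()
  rep_means_all <- list()
  for (grp in unique(groups$group_id)) {
    reps <- groups$replicate_id[groups$group_id == grp]
    missing <- setdiff(reps, names(alignments))
    if (length(missing))
      stop("group '", grp, "' references unknown replicate(s): ",
           paste(missing, collapse = ", "))
    aln <- alignments[reps]
    res <- .run_group(pairs, aln, grp, config, trnas, pcg_genes)
    out[[grp]] <- res$calls
    rep_means_all[[grp]] <- res$replicate_means
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  attr(calls, "replicate_means") <-
    do.call(rbind, c(rep_means_all, list(make.row.names = FALSE)))
  attr(calls, "config") <- config
  class(calls) <- c("dirt_calls", class(calls))
  calls
}

.run_group <- function(pairs, aln, grp, config, trnas, pcg_genes) {
  n <- nrow(pairs)
  testable_group <- length(aln) >= 2L
  if (!testable_group)
    warning("group '", grp, "' has < 2 replicates: all pairs untestable")

  ## group-level expression counts (summed over replicates)
  trna_counts <- Reduce(`+`, lapply(aln, count_feature_reads, trnas,
                                    policy = "trna", id_col = "trna_id"))
  pcg_counts <- Reduce(`+`, lapply(aln, count_feature_reads, pcg_genes,
                                   policy = "pcg", id_col = "gene_id",
                                   mapq_min = config$mapq_min))
  expressed <- trna_counts[pairs$trna_id] >= config$trna_min_reads &
    pcg_counts[pairs$gene_id] >= config$pcg_min_reads

  calls <- data.frame(
    group_id = grp, pairs[, c("trna_id", "gene_id", "chrom", "orientation",
                              "intergenic_start", "intergenic_end",
                              "distance", "n_introns")],
    trna_count = as.numeric(trna_counts[pairs$trna_id]),
    pcg_count = as.numeric(pcg_counts[pairs$gene_id]),
    mean_intergenic = NA_real_, mean_intron1 = NA_real_,
    mean_intron2 = NA_real_,
    p_intron1 = NA_real_, p_intron2 = NA_real_,
    q_intron1 = NA_real_, q_intron2 = NA_real_,
    degenerate_test = FALSE,
    direction_ok = NA, continuous = NA,
    verdict = NA_character_,
    stringsAsFactors = FALSE
  )

  verdict <- rep(NA_character_, n)
  verdict[!expressed] <- "rejected_expression"
  untest <- is.na(verdict) &
    (!testable_group | pairs$n_introns == 0L | pairs$distance == 0)
  verdict[untest] <- "untestable"
  test_idx <- which(is.na(verdict))
  rep_means_df <- NULL

  if (length(test_idx)) {
    ## region table: intergenic gap + up to two nearest introns per pair
    two <- test_idx[pairs$n_introns[test_idx] >= 2L]
    regions <- data.frame(
      pair = c(test_idx, test_idx, two),
      kind = c(rep("ig", length(test_idx)), rep("i1", length(test_idx)),
               rep("i2", length(two))),
      chrom = pairs$chrom[c(test_idx, test_idx, two)],
      start = c(pairs$intergenic_start[test_idx],
                pairs$intron1_start[test_idx], pairs$intron2_start[two]),
      end = c(pairs$intergenic_end[test_idx],
              pairs$intron1_end[test_idx], pairs$intron2_end[two]),
      stringsAsFactors = FALSE
    )
    ## per-replicate mean coverage: one coverage pass + one Views call per
    ## replicate and chromosome
    rep_mean <- vapply(aln, function(a)
      .region_stat(.coverage_rle(a), regions, IRanges::viewMeans),
      numeric(nrow(regions)))
    if (is.null(dim(rep_mean))) rep_mean <- t(rep_mean)  # single region

    ## merged (summed over replicates) coverage: direction + continuity
    merged_cov <- .coverage_rle(merge_alignments(aln))
    merged_mean <- .region_stat(merged_cov, regions, IRanges::viewMeans)
    merged_min <- .region_stat(merged_cov, regions, IRanges::viewMins)

    is_ig <- regions$kind == "ig"; is_i1 <- regions$kind == "i1"
    is_i2 <- regions$kind == "i2"
    row_of <- function(sel) match(test_idx, regions$pair[sel])
    ig_rows <- which(is_ig)[row_of(is_ig)]
    i1_rows <- which(is_i1)[row_of(is_i1)]
    i2_rows <- which(is_i2)[match(test_idx, regions$pair[is_i2])]

    p_pool <- numeric(0); p_slot <- list()
    for (k in seq_along(test_idx)) {
      i <- test_idx[k]
      ig <- rep_mean[ig_rows[k], ]
      t1 <- intron_contrast_test(ig, rep_mean[i1_rows[k], ])
      calls$p_intron1[i] <- t1$p
      calls$degenerate_test[i] <- t1$degenerate
      p_pool <- c(p_pool, t1$p); p_slot[[length(p_pool)]] <- c(i, 1L)
      if (!is.na(i2_rows[k])) {
        t2 <- intron_contrast_test(ig, rep_mean[i2_rows[k], ])
        calls$p_intron2[i] <- t2$p
        calls$degenerate_test[i] <- calls$degenerate_test[i] || t2$degenerate
        p_pool <- c(p_pool, t2$p); p_slot[[length(p_pool)]] <- c(i, 2L)
      }
    }

    ## BH over the complete set of p-values of this group run
    q <- bh_adjust(p_pool)
    for (k in seq_along(q)) {
      s <- p_slot[[k]]
      if (s[2L] == 1L) calls$q_intron1[s[1L]] <- q[k]
      else calls$q_intron2[s[1L]] <- q[k]
    }

    calls$mean_intergenic[test_idx] <- merged_mean[ig_rows]
    calls$mean_intron1[test_idx] <- merged_mean[i1_rows]
    calls$mean_intron2[test_idx] <- ifelse(is.na(i2_rows), NA_real_,
                                           merged_mean[i2_rows])
    calls$direction_ok[test_idx] <-
      calls$mean_intergenic[test_idx] > calls$mean_intron1[test_idx] &
      (is.na(calls$mean_intron2[test_idx]) |
         calls$mean_intergenic[test_idx] > calls$mean_intron2[test_idx])
    calls$continuous[test_idx] <- merged_min[ig_rows] >= 1

    q_bad <- calls$q_intron1[test_idx] >= config$fdr_alpha |
      (!is.na(calls$q_intron2[test_idx]) &
         calls$q_intron2[test_idx] >= config$fdr_alpha)
    verdict[test_idx] <- ifelse(
      q_bad, "rejected_test",
      ifelse(!calls$direction_ok[test_idx], "rejected_direction",
             ifelse(!calls$continuous[test_idx], "rejected_continuity",
                    "dicistronic")))

    rep_means_df <- data.frame(
      group_id = grp,
      trna_id = rep(pairs$trna_id[regions$pair], ncol(rep_mean)),
      gene_id = rep(pairs$gene_id[regions$pair], ncol(rep_mean)),
      region = rep(regions$kind, ncol(rep_mean)),
      replicate_id = rep(colnames(rep_mean), each = nrow(regions)),
      mean_coverage = as.vector(rep_mean),
      stringsAsFactors = FALSE
    )
  }
  calls$verdict <- verdict
  list(calls = calls, replicate_means = rep_means_df)
}

## vectorized region statistic over an .coverage_rle result, zero-padding
## chromosomes that end before a requested region does
.region_stat <- function(cov, regions, viewfun) {
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    maxend <- max(regions$end[ri])
    r <- cov[[ch]]
    if (is.null(r)) r <- S4Vectors::Rle(0L, maxend)
    else if (length(r) < maxend) r <- c(r, S4Vectors::Rle(0L, maxend - length(r)))
    v <- IRanges::Views(r, start = regions$start[ri] + 1L,
                        end = regions$end[ri])
    out[ri] <- viewfun(v)
  }
  out
}

#' Write a call table as TSV
#'
#' @param calls a `dirt_calls` table from [run_dirt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export dicistronic candidates as BED6
#'
#' One record per candidate spanning tRNA through PCG (the full putative
#' dicistronic transcript) for genome-browser inspection.
#'
#' @param calls a `dirt_calls` table.
#' @param pairs the pair table the calls were computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_bed <- function(calls, pairs, path) {
  hit <- calls[calls$verdict == "dicistronic", , drop = FALSE]
  key <- paste(pairs$trna_id, pairs$gene_id)
  idx <- match(paste(hit$trna_id, hit$gene_id), key)
  p <- pairs[idx, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%s\t0\t.",
                   p$chrom, as.integer(pmin(p$trna_start, p$gene_start)),
                   as.integer(pmax(p$trna_end, p$gene_end)),
                   hit$trna_id, hit$gene_id, hit$group_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records configuration, seed and input digests for reproducibility.
#'
#' @param path output path.
#' @param config a [detection_config()].
#' @param inputs character vector of input file paths (md5-digested).
#' @param seed optional integer seed.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(0),
                               seed = NULL) {
  digests <- if (length(inputs))
    stats::setNames(as.list(tools::md5sum(inputs)), basename(inputs))
  else NULL
  jsonlite::write_json(
    list(config = unclass(config), seed = seed, inputs = digests,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
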