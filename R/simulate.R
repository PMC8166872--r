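## anticodon table used to mint GtRNAdb-style names for simulated loci
.sim_isotypes <- data.frame(
  amino_acid = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val"),
  anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC", "GCC",
                "GTG", "AAT", "AAG", "CTT", "CAT", "GAA", "TGG", "AGA",
                "AGT", "CCA", "GTA", "AAC"),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Describes a synthetic chromosome of adjacent tRNA / protein-coding gene
#' loci and the sequencing model used to generate already-aligned reads.
#' Defaults emulate the data the detector was designed for: 2x75 bp Illumina
#' libraries collapsed to 75 bp single-end fragments, four biological
#' replicates per group, intergenic gaps drawn from a discretized log-normal
#' clipped to \[1, 1065\] bp with median approximately 133 bp, and a low
#' uniform background modelling DNA contamination or spurious transcription.
#'
#' Depths are mean reads per base. Planted dicistronic loci are sequenced as
#' read-through fragments spanning tRNA, intergenic gap and the adjacent
#' exon, so every intergenic base is covered in expectation; monocistronic
#' loci receive independent tRNA and exonic PCG fragments with no intergenic
#' signal beyond background. Simulated tRNA reads are emitted as
#' multi-mapped records (NH = 4, mapq 2), mirroring the ambiguity of mapping
#' to large tRNA gene families.
#'
#' @param n_pairs number of tRNA-PCG loci.
#' @param dicistronic_fraction fraction of loci planted as dicistronic.
#' @param replicates_per_group biological replicates per group (>= 2).
#' @param groups character vector of group labels.
#' @param read_length read length in bp.
#' @param depth_dicistronic mean reads/base across a planted read-through
#'   span.
#' @param depth_monocistronic_trna mean reads/base on monocistronic tRNAs.
#' @param depth_monocistronic_pcg mean reads/base on monocistronic PCG exons.
#' @param background_rate mean spurious reads/base genome-wide.
#' @param intergenic_min,intergenic_max bounds on the intergenic gap (bp).
#' @param intergenic_median target median of the log-normal gap sampler.
#' @param intergenic_sdlog log-scale SD of the gap sampler.
#' @param intron_count_range integer candidate intron counts per PCG,
#'   sampled uniformly.
#' @param trna_length,exon_length,intron_length,spacer locus geometry (bp).
#' @param seed integer seed; the whole dataset is deterministic given the
#'   configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 100L, dicistronic_fraction = 0.2,
                       replicates_per_group = 4L, groups = "G1",
                       read_length = 75L,
                       depth_dicistronic = 30,
                       depth_monocistronic_trna = 5,
                       depth_monocistronic_pcg = 20,
                       background_rate = 0.05,
                       intergenic_min = 1L, intergenic_max = 1065L,
                       intergenic_median = 133, intergenic_sdlog = 1,
                       intron_count_range = 1:3,
                       trna_length = 80L, exon_length = 300L,
                       intron_length = 150L, spacer = 1500L,
                       seed = 1L) {
  stopifnot(n_pairs >= 1, dicistronic_fraction >= 0, dicistronic_fraction <= 1,
            replicates_per_group >= 2, read_length >= 20,
            depth_dicistronic >= 0, depth_monocistronic_trna >= 0,
            depth_monocistronic_pcg >= 0, background_rate >= 0,
            intergenic_min >= 1, intergenic_max >= intergenic_min,
            all(intron_count_range >= 0), trna_length > 0, exon_length > 0,
            intron_length > 0, spacer >= read_length)
  if (trna_length < read_length)
    stop("trna_length must be >= read_length so that read-through edge ",
         "effects do not reach into the intergenic gap")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d loci (%.0f%% dicistronic), %d group(s) x ",
                     "%d replicates, %d bp reads, seed %d\n"),
              x$n_pairs, 100 * x$dicistronic_fraction, length(x$groups),
              x$replicates_per_group, x$read_length, x$seed))
  invisible(x)
}

#' Simulate a fully synthetic detection dataset
#'
#' Lays out `n_pairs` tRNA-PCG loci on one synthetic chromosome (random
#' orientation, log-normal intergenic gaps, uniform intron counts), plants
#' the first `round(n_pairs * dicistronic_fraction)` loci as dicistronic
#' after shuffling, and samples aligned reads independently per replicate:
#' Poisson read numbers at the configured depths, uniform placement, fixed
#' read length. The planted truth is identical across replicates and groups.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, `genes.gff3`,
#'   `trnas.bed`, one `<group>_<replicate>.sam` per replicate, `truth.tsv`,
#'   `groups.tsv` and `config.json` are written there.
#' @return list with `trnas` (tRNA table), `pcgs` (`pcg_set`), `truth`
#'   (data frame `trna_id`, `gene_id`, `planted_dicistronic`, per-feature
#'   expected depths), `alignments` (named list replicate id ->
#'   `dirt_alignments`), `groups` (data frame `group_id`, `replicate_id`),
#'   `chrom_length`, `config`, and `files` when `dir` was given.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom <- "simchr"
  rl <- config$read_length

  ## --- genome layout -------------------------------------------------
  n <- config$n_pairs
  gaps <- pmin(pmax(round(stats::rlnorm(n, log(config$intergenic_median),
                                        config$intergenic_sdlog)),
                    config$intergenic_min), config$intergenic_max)
  n_introns <- if (length(config$intron_count_range) > 1L)
    sample(config$intron_count_range, n, replace = TRUE)
  else rep(config$intron_count_range, n)
  orient <- sample(c("tRNA-upstream", "tRNA-downstream"), n, replace = TRUE)
  planted <- rep(FALSE, n)
  planted[sample.int(n, round(n * config$dicistronic_fraction))] <- TRUE

  cursor <- 1000
  loci <- vector("list", n)
  anti_counter <- integer(nrow(.sim_isotypes))
  iso_idx <- sample.int(nrow(.sim_isotypes), n, replace = TRUE)
  for (i in seq_len(n)) {
    k <- n_introns[i]
    pcg_len <- (k + 1L) * config$exon_length + k * config$intron_length
    if (orient[i] == "tRNA-upstream") {
      t_start <- cursor
      t_end <- t_start + config$trna_length
      g_start <- t_end + gaps[i]
      g_end <- g_start + pcg_len
    } else {
      g_start <- cursor
      g_end <- g_start + pcg_len
      t_start <- g_end + gaps[i]
      t_end <- t_start + config$trna_length
    }
    iso <- iso_idx[i]
    anti_counter[iso] <- anti_counter[iso] + 1L
    loci[[i]] <- list(
      trna_id = sprintf("tRNA-%s-%s-%d-1", .sim_isotypes$amino_acid[iso],
                        .sim_isotypes$anticodon[iso], anti_counter[iso]),
      gene_id = sprintf("SIMPCG%04d", i),
      t_start = t_start, t_end = t_end, g_start = g_start, g_end = g_end,
      n_introns = k, gap = gaps[i], orientation = orient[i],
      planted = planted[i]
    )
    cursor <- max(t_end, g_end) + config$spacer
  }
  chrom_length <- cursor + 1000
  if (chrom_length > 5e8) stop("infeasible geometry: chromosome exceeds budget")

  trnas <- do.call(rbind, lapply(loci, function(l) data.frame(
    trna_id = l$trna_id, chrom = chrom, start = l$t_start, end = l$t_end,
    strand = "+", stringsAsFactors = FALSE)))
  trnas <- cbind(trnas,
                 parse_trna_name(trnas$trna_id)[, c("amino_acid", "anticodon",
                                                    "isodecoder_family",
                                                    "gene_copy",
                                                    "undefined_flag")])
  trnas <- trnas[, .trna_cols]

  exons <- do.call(rbind, lapply(loci, function(l) {
    k <- l$n_introns
    starts <- l$g_start + (seq_len(k + 1L) - 1L) *
      (config$exon_length + config$intron_length)
    data.frame(gene_id = l$gene_id, chrom = chrom, start = starts,
               end = starts + config$exon_length, stringsAsFactors = FALSE)
  }))
  genes <- do.call(rbind, lapply(loci, function(l) data.frame(
    gene_id = l$gene_id, chrom = chrom, start = l$g_start, end = l$g_end,
    strand = "+", mrna_id = paste0(l$gene_id, ".1"),
    n_exons = l$n_introns + 1L, stringsAsFactors = FALSE)))
  pcgs <- structure(list(genes = genes, exons = exons), class = "pcg_set")

  truth <- do.call(rbind, lapply(loci, function(l) data.frame(
    trna_id = l$trna_id, gene_id = l$gene_id,
    planted_dicistronic = l$planted, orientation = l$orientation,
    intergenic_length = l$gap,
    expected_depth_intergenic = if (l$planted) config$depth_dicistronic else 0,
    expected_depth_trna = if (l$planted) config$depth_dicistronic
    else config$depth_monocistronic_trna,
    expected_depth_pcg = if (l$planted) config$depth_dicistronic
    else config$depth_monocistronic_pcg,
    stringsAsFactors = FALSE)))

  ## --- reads ---------------------------------------------------------
  groups_df <- expand.grid(replicate = seq_len(config$replicates_per_group),
                           group_id = config$groups,
                           stringsAsFactors = FALSE)
  groups_df$replicate_id <- sprintf("%s_rep%d", groups_df$group_id,
                                    groups_df$replicate)
  groups_df <- groups_df[, c("group_id", "replicate_id")]

  alignments <- list()
  for (r in seq_len(nrow(groups_df))) {
    rid <- groups_df$replicate_id[r]
    alignments[[rid]] <- .simulate_replicate(loci, config, chrom,
                                             chrom_length, rid)
  }

  out <- list(trnas = trnas, pcgs = pcgs, truth = truth,
              alignments = alignments, groups = groups_df,
              chrom_length = chrom_length, config = config)
  if (!is.null(dir)) out$files <- .write_sim_files(out, dir)
  out
}

## reads of one replicate; depth d over a span S is realised as
## Poisson(d * W / rl) reads with starts uniform on the W = |S| + rl - 1
## positions overlapping S, giving interior per-base coverage d in
## expectation
.simulate_replicate <- function(loci, config, chrom, chrom_length, rid) {
  rl <- config$read_length
  starts <- numeric(0); mapq <- integer(0); nh <- integer(0)

  span_reads <- function(s, e, depth, contained = FALSE) {
    if (depth <= 0) return(numeric(0))
    if (contained) {
      w <- (e - s) - rl + 1
      if (w < 1) return(numeric(0))
      k <- stats::rpois(1, depth * (e - s) / rl)
      if (!k) return(numeric(0))
      s + floor(stats::runif(k, 0, w))
    } else {
      w <- (e - s) + rl - 1
      k <- stats::rpois(1, depth * w / rl)
      if (!k) return(numeric(0))
      (s - rl + 1) + floor(stats::runif(k, 0, w))
    }
  }
  add <- function(st, q, h) {
    starts <<- c(starts, st)
    mapq <<- c(mapq, rep(q, length(st)))
    nh <<- c(nh, rep(h, length(st)))
  }

  for (l in loci) {
    if (l$planted) {
      ## read-through fragments: tRNA + intergenic + adjacent exon
      if (l$orientation == "tRNA-upstream") {
        span_s <- l$t_start
        span_e <- l$g_start + config$exon_length      # first exon
      } else {
        span_s <- l$g_end - config$exon_length        # last exon
        span_e <- l$t_end
      }
      add(span_reads(span_s, span_e, config$depth_dicistronic), 60L, 1L)
    } else {
      ## independent monocistronic transcripts, reads contained in features
      add(span_reads(l$t_start, l$t_end, config$depth_monocistronic_trna,
                     contained = TRUE), 2L, 4L)
      k <- l$n_introns
      ex_starts <- l$g_start + (seq_len(k + 1L) - 1L) *
        (config$exon_length + config$intron_length)
      for (es in ex_starts)
        add(span_reads(es, es + config$exon_length,
                       config$depth_monocistronic_pcg, contained = TRUE),
            60L, 1L)
    }
  }
  ## uniform background over the whole chromosome
  if (config$background_rate > 0) {
    k <- stats::rpois(1, config$background_rate * chrom_length / rl)
    if (k) add(floor(stats::runif(k, 0, chrom_length - rl)), 30L, 1L)
  }
  starts <- pmax(0, pmin(starts, chrom_length - rl))
  ord <- order(starts)
  reads <- data.table::data.table(
    read_id = sprintf("%s_r%07d", rid, seq_along(starts)),
    chrom = chrom, start = starts, end = starts + rl,
    mapq = mapq, nh = nh
  )[ord]
  dirt_alignments(reads, source = sprintf("<sim:%s>", rid))
}

## writers: GFF3 (1-based inclusive), BED6 (0-based), SAM, truth/groups TSV
.write_sim_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- sim$trnas$chrom[1]
  gff <- file.path(dir, "genes.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(sim$pcgs$genes))) {
    g <- sim$pcgs$genes[i, ]
    ex <- sim$pcgs$exons[sim$pcgs$exons$gene_id == g$gene_id, , drop = FALSE]
    writeLines(c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$mrna_id, g$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              ex$chrom, ex$start + 1L, ex$end, g$strand, g$mrna_id)
    ), con)
  }
  close(con)

  bed <- file.path(dir, "trnas.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", sim$trnas$chrom,
                     as.integer(sim$trnas$start), as.integer(sim$trnas$end),
                     sim$trnas$trna_id, sim$trnas$strand), bed)

  sams <- character(0)
  for (rid in names(sim$alignments)) {
    p <- file.path(dir, paste0(rid, ".sam"))
    write_sam(sim$alignments[[rid]],
              stats::setNames(sim$chrom_length, chrom), p)
    sams[rid] <- p
  }

  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  groups <- file.path(dir, "groups.tsv")
  gt <- sim$groups
  gt$path <- basename(sams[gt$replicate_id])
  utils::write.table(gt, groups, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cfg, auto_unbox = TRUE, digits = NA)
  list(gff3 = gff, bed = bed, sam = sams, truth = truth, groups = groups,
       config = cfg)
}

#' Write an alignment set as SAM
#'
#' Emits unspliced single-block records (`<len>M` CIGAR) with `NH` tags and
#' omitted sequence/quality, sorted by coordinate.
#'
#' @param alignments a `dirt_alignments` object (single-block reads).
#' @param chrom_lengths named vector of chromosome lengths for the header.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  reads <- alignments$reads[order(alignments$reads$chrom,
                                  alignments$reads$start)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths))), con)
  if (nrow(reads))
    writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                       reads$read_id, reads$chrom,
                       as.integer(reads$start) + 1L, reads$mapq,
                       as.integer(reads$end - reads$start), reads$nh), con)
  invisible(path)
}
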