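# Fixture builders and independent brute-force oracles shared across tests.
# Everything is generated in code; no binary fixtures.

# in-memory alignment set of fixed-length unspliced reads
mk_aln <- function(starts, len = 10, chrom = "chr1", mapq = 60L, nh = 1L,
                   ids = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("r%04d", seq_len(n))
  dirt_alignments(data.frame(
    read_id = ids, chrom = rep_len(chrom, n), start = starts,
    end = starts + len,
    mapq = rep_len(mapq, n), nh = rep_len(nh, n),
    stringsAsFactors = FALSE
  ))
}

# GFF3 writer for micro gene models: genes = list of list(id, chrom, strand,
# mrnas = list of list(id, exons = matrix of 1-based inclusive start/end))
write_micro_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- range(unlist(lapply(g$mrnas, function(m) m$exons)))
    lines <- c(lines, sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, span[1], span[2], g$strand %||% "+",
                              g$id))
    for (m in g$mrnas) {
      lines <- c(lines, sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$chrom, min(m$exons), max(m$exons),
                                g$strand %||% "+", m$id, g$id))
      for (r in seq_len(nrow(m$exons)))
        lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                  g$chrom, m$exons[r, 1], m$exons[r, 2],
                                  g$strand %||% "+", m$id))
    }
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_micro_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start, df$end,
                     df$name, df$strand %||% rep("+", nrow(df))), path)
  path
}

# brute-force per-base interval-stabbing coverage oracle
oracle_coverage <- function(blocks, region_start, region_end) {
  vapply(seq(region_start, region_end - 1L), function(b)
    sum(blocks$start <= b & blocks$end > b), numeric(1))
}

# brute-force BH step-up: sort, p * m / rank, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# brute-force pairing oracle: overlap exclusion + nearest PCG on each side
oracle_pairs <- function(trnas, genes) {
  out <- list()
  for (i in seq_len(nrow(trnas))) {
    t <- trnas[i, ]
    g <- genes[genes$chrom == t$chrom, , drop = FALSE]
    if (any(pmax(t$start, g$start) < pmin(t$end, g$end))) next  # overlap
    up <- g[g$end <= t$start, , drop = FALSE]
    if (nrow(up)) {
      best <- up[up$end == max(up$end), , drop = FALSE]
      best <- best[which.min(best$start), ]
      out[[length(out) + 1L]] <- data.frame(
        trna_id = t$trna_id, gene_id = best$gene_id,
        distance = t$start - best$end, stringsAsFactors = FALSE)
    }
    dn <- g[g$start >= t$end, , drop = FALSE]
    if (nrow(dn)) {
      best <- dn[dn$start == min(dn$start), , drop = FALSE]
      best <- best[which.min(best$start), ]
      out[[length(out) + 1L]] <- data.frame(
        trna_id = t$trna_id, gene_id = best$gene_id,
        distance = best$start - t$end, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(trna_id = character(0),
                                      gene_id = character(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

# one-locus annotation used by the decision-cascade tests: tRNA [100,180),
# intergenic [180,300), PCG with configurable introns starting at 300
micro_locus <- function(n_introns = 2, exon_len = 100, intron_len = 50) {
  trnas <- data.frame(trna_id = "tRNA-Gly-GCC-1-1", chrom = "chr1",
                      start = 100, end = 180, strand = "+",
                      stringsAsFactors = FALSE)
  starts <- 300 + (seq_len(n_introns + 1) - 1) * (exon_len + intron_len)
  exons <- data.frame(gene_id = "G1", chrom = "chr1", start = starts,
                      end = starts + exon_len, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = min(exons$start),
                      end = max(exons$end), strand = "+", mrna_id = "G1.1",
                      n_exons = n_introns + 1, stringsAsFactors = FALSE)
  pcgs <- structure(list(genes = genes, exons = exons), class = "pcg_set")
  list(trnas = trnas, pcgs = pcgs,
       pairs = assemble_pairs(trnas, pcgs))
}

# replicate alignments giving a micro_locus pair the designated coverages:
# `ig_reads` read starts tile the intergenic gap (1 bp reads for exact
# control), tRNA and exon-1 reads guarantee expression
micro_replicate <- function(loc, ig_depth = 3, intron_depth = 0,
                            rep_id = "r1", mask = integer(0)) {
  p <- loc$pairs
  ig <- seq(p$intergenic_start, p$intergenic_end - 1)
  ig <- setdiff(ig, mask)
  starts <- c(rep(ig, ig_depth),
              rep(seq(p$trna_start, p$trna_start + 4), 2),       # tRNA reads
              rep(seq(p$gene_start, p$gene_start + 9), 2))       # PCG reads
  if (intron_depth > 0 && !is.na(p$intron1_start)) {
    i1 <- seq(p$intron1_start, p$intron1_end - 1)
    starts <- c(starts, rep(i1, intron_depth))
  }
  mk_aln(starts, len = 1, ids = sprintf("%s_%06d", rep_id, seq_along(starts)))
}
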