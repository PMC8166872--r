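#' Parse protein-coding gene models from GFF3
#'
#' Reads an Ensembl-style GFF3 (gene/mRNA/exon hierarchy resolved through
#' `Parent` attributes) and returns one gene model per gene, built from the
#' exons of its canonical transcript. The canonical transcript is the mRNA
#' with the longest genomic span (ties broken by mRNA identifier); its exons
#' are merged, sorted and converted to the internal 0-based half-open
#' convention. The gene interval is recomputed as the span of the retained
#' exons (5'UTR through 3'UTR in Ensembl models).
#'
#' Records with `end < start` abort the parse with the offending line number;
#' exons whose `Parent` cannot be resolved are skipped with a warning, and
#' genes left without any exon are dropped with a warning.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @return an object of class `pcg_set`: a list with
#'   * `genes`: data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'     `mrna_id`, `n_exons` (0-based half-open),
#'   * `exons`: data frame `gene_id`, `chrom`, `start`, `end` sorted within
#'     gene.
#' @export
parse_gene_models <- function(path) {
  .check_gff3_coordinates(path)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- meta$Parent   # CharacterList; exons can have several parents

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_gene)) stop("no 'gene' features found in ", path)

  gene_ids <- ids[is_gene]
  mrna_id <- ids[is_mrna]
  mrna_parent <- vapply(parents[is_mrna], function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  mrna_width <- GenomicRanges::width(gr[is_mrna])

  ## canonical transcript: longest mRNA span per gene, ties to smaller id
  ord <- order(mrna_parent, -mrna_width, mrna_id)
  first <- !duplicated(mrna_parent[ord])
  canon <- data.frame(gene_id = mrna_parent[ord][first],
                      mrna_id = mrna_id[ord][first],
                      stringsAsFactors = FALSE)
  canon <- canon[canon$gene_id %in% gene_ids, , drop = FALSE]

  exon_parent_list <- parents[is_exon]
  exon_start <- GenomicRanges::start(gr[is_exon]) - 1L  # to 0-based half-open
  exon_end <- GenomicRanges::end(gr[is_exon])
  exon_chrom <- as.character(GenomicRanges::seqnames(gr[is_exon]))
  np <- lengths(exon_parent_list)
  known <- c(mrna_id, gene_ids)
  orphan <- vapply(exon_parent_list, function(p)
    length(p) > 0 && !any(p %in% known), logical(1)) | np == 0L
  if (any(orphan))
    warning(sum(orphan), " exon(s) with unknown Parent skipped")

  ## expand exons to one row per (exon, parent) and keep canonical mRNAs
  idx <- rep(seq_along(exon_parent_list), np)
  flat_parent <- unlist(exon_parent_list, use.names = FALSE)
  keep <- flat_parent %in% canon$mrna_id
  ex <- data.frame(
    mrna_id = flat_parent[keep],
    chrom = exon_chrom[idx][keep],
    start = exon_start[idx][keep],
    end = exon_end[idx][keep],
    stringsAsFactors = FALSE
  )
  ex$gene_id <- canon$gene_id[match(ex$mrna_id, canon$mrna_id)]
  ex <- ex[order(ex$gene_id, ex$start, ex$end), c("gene_id", "chrom", "start", "end")]
  ex <- unique(ex)

  no_exon <- setdiff(gene_ids, unique(ex$gene_id))
  if (length(no_exon))
    warning("gene(s) without exons dropped: ", paste(no_exon, collapse = ", "))

  gene_strand <- as.character(GenomicRanges::strand(gr[is_gene]))
  gene_strand[!gene_strand %in% c("+", "-")] <- "*"
  agg_start <- tapply(ex$start, ex$gene_id, min)
  agg_end <- tapply(ex$end, ex$gene_id, max)
  agg_chrom <- tapply(ex$chrom, ex$gene_id, `[`, 1L)
  agg_n <- tapply(ex$start, ex$gene_id, length)
  gid <- names(agg_start)
  genes <- data.frame(
    gene_id = gid,
    chrom = as.character(agg_chrom),
    start = as.numeric(agg_start),
    end = as.numeric(agg_end),
    strand = gene_strand[match(gid, gene_ids)],
    mrna_id = canon$mrna_id[match(gid, canon$gene_id)],
    n_exons = as.integer(agg_n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = ex), class = "pcg_set")
}

## record-level coordinate sanity check naming the offending line
.check_gff3_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) return(invisible())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ln <- which(body)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 5) next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (!is.na(s) && !is.na(e) && e < s)
      stop("malformed coordinates (end < start) at line ", ln[i], " of ", path)
  }
  invisible()
}

#' @export
print.pcg_set <- function(x, ...) {
  cat("pcg_set:", nrow(x$genes), "protein-coding genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Parse a GtRNAdb-style tRNA gene name
#'
#' GtRNAdb names encode the isotype, anticodon, isodecoder family and gene
#' copy as `tRNA-<AA>-<anticodon>-<family>-<copy>` (e.g. `tRNA-Gly-GCC-1-6`).
#' Names that do not match the pattern, or whose isotype is `Und`, are kept
#' but flagged as undefined.
#'
#' @param name character vector of tRNA gene names.
#' @return data frame: `trna_id`, `amino_acid`, `anticodon`,
#'   `isodecoder_family`, `gene_copy`, `undefined_flag`.
#' @examples
#' parse_trna_name("tRNA-Gly-GCC-1-6")
#' @export
parse_trna_name <- function(name) {
  pat <- "^tRNA-([A-Za-z]+)-([ACGTUNacgtun]{3})-([0-9]+)-([0-9]+)$"
  ok <- grepl(pat, name)
  aa <- rep("Und", length(name)); ac <- rep("NNN", length(name))
  fam <- rep(NA_integer_, length(name)); cp <- fam
  aa[ok] <- sub(pat, "\\1", name[ok])
  ac[ok] <- toupper(sub(pat, "\\2", name[ok]))
  fam[ok] <- as.integer(sub(pat, "\\3", name[ok]))
  cp[ok] <- as.integer(sub(pat, "\\4", name[ok]))
  data.frame(
    trna_id = name, amino_acid = aa, anticodon = ac,
    isodecoder_family = as.integer(fam), gene_copy = as.integer(cp),
    undefined_flag = !ok | aa == "Und",
    stringsAsFactors = FALSE
  )
}

#' Parse tRNA gene annotations from BED6
#'
#' BED coordinates are already 0-based half-open and pass through unchanged.
#' The name column is interpreted as a GtRNAdb-style identifier via
#' [parse_trna_name()]; unparseable names are retained with
#' `undefined_flag = TRUE` and the raw name preserved.
#'
#' @param path path to a BED6 file.
#' @return data frame with one row per tRNA gene: `trna_id`, `chrom`,
#'   `start`, `end`, `strand`, `amino_acid`, `anticodon`,
#'   `isodecoder_family`, `gene_copy`, `undefined_flag`.
#' @export
parse_trna_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    out <- cbind(parse_trna_name(character(0)),
                 data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), strand = character(0)))
    return(out[, .trna_cols])
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 4)) stop("BED records need at least 4 columns (BED6 expected)")
  get <- function(i, default) vapply(f, function(x)
    if (length(x) >= i) x[[i]] else default, character(1))
  chrom <- get(1, NA_character_)
  start <- as.numeric(get(2, NA_character_))
  end <- as.numeric(get(3, NA_character_))
  name <- get(4, NA_character_)
  strand <- get(6, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (any(is.na(start) | is.na(end) | end < start))
    stop("malformed BED coordinates in ", path)
  info <- parse_trna_name(name)
  out <- cbind(info, data.frame(chrom = chrom, start = start, end = end,
                                strand = strand, stringsAsFactors = FALSE))
  out[, .trna_cols]
}

.trna_cols <- c("trna_id", "chrom", "start", "end", "strand", "amino_acid",
                "anticodon", "isodecoder_family", "gene_copy", "undefined_flag")

#' Derive introns from an exon set
#'
#' Introns are the gaps between consecutive exons of the canonical
#' transcript, in genomic order; a single-exon gene has none.
#'
#' @param exons data frame with `start`, `end` (0-based half-open),
#'   non-overlapping. A `chrom` column, if present, is carried through.
#' @return data frame `chrom` (if supplied), `start`, `end` with
#'   `max(0, nrow(exons) - 1)` rows.
#' @examples
#' derive_introns(data.frame(start = c(100, 300), end = c(200, 400)))
#' @export
derive_introns <- function(exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  if (n <= 1L) {
    out <- data.frame(start = numeric(0), end = numeric(0))
  } else {
    out <- data.frame(start = exons$end[-n], end = exons$start[-1L])
    out <- out[out$end > out$start, , drop = FALSE]  # abutting exons: no intron
  }
  if ("chrom" %in% names(exons))
    out <- cbind(data.frame(chrom = rep(exons$chrom[1L], nrow(out)),
                            stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
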