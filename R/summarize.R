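#' Counts per million (CPM / logCPM)
#'
#' `count * 1e6 / library_size`, optionally log-transformed as
#' `log2(CPM + 1)` so that zero counts stay at zero and the transform is
#' monotone.
#'
#' @param counts numeric matrix (features x samples) or vector.
#' @param library_sizes total mapped reads per sample (> 0), recycled along
#'   columns.
#' @param log logical; return log2(CPM + 1)?
#' @return matrix (or vector) of the same shape.
#' @export
cpm <- function(counts, library_sizes, log = FALSE) {
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.matrix(counts)) {
    if (length(library_sizes) != ncol(counts))
      stop("need one library size per column")
    out <- sweep(counts, 2L, library_sizes, function(x, n) x * 1e6 / n)
  } else {
    out <- counts * 1e6 / library_sizes
  }
  if (log) out <- log2(out + 1)
  out
}

#' Correlate dicistronic transcript components across groups
#'
#' Intergenic-region read counts serve as a proxy for dicistronic-transcript
#' expression (reads there can only come from a read-through molecule,
#' whereas tRNA and PCG reads are ambiguous between monocistronic and
#' dicistronic origin). For each candidate, Pearson correlation of the
#' tRNA-vs-intergenic and PCG-vs-intergenic expression profiles across
#' groups is computed with a two-sided t-approximation p-value.
#'
#' @param expr_trna,expr_intergenic,expr_pcg numeric matrices
#'   (candidates x groups) with identical dimensions; rownames identify
#'   candidates.
#' @param alpha significance level for the `significant` flag.
#' @return data frame: `candidate`, `contrast`
#'   (`trna_vs_intergenic` / `pcg_vs_intergenic`), `r`, `p`, `significant`,
#'   `note` (`"zero variance"` when r is undefined).
#' @export
correlate_components <- function(expr_trna, expr_intergenic, expr_pcg,
                                 alpha = 0.05) {
  stopifnot(all(dim(expr_trna) == dim(expr_intergenic)),
            all(dim(expr_pcg) == dim(expr_intergenic)))
  if (ncol(expr_intergenic) < 3L)
    stop("need >= 3 groups for correlation")
  ids <- rownames(expr_intergenic)
  if (is.null(ids)) ids <- sprintf("candidate%d", seq_len(nrow(expr_intergenic)))
  one <- function(x, y, id, label) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(candidate = id, contrast = label, r = NA_real_,
                        p = NA_real_, significant = NA,
                        note = "zero variance", stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(candidate = id, contrast = label,
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, note = "",
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(ids), function(i) rbind(
    one(expr_trna[i, ], expr_intergenic[i, ], ids[i], "trna_vs_intergenic"),
    one(expr_pcg[i, ], expr_intergenic[i, ], ids[i], "pcg_vs_intergenic")
  ))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a candidate table
#'
#' Tallies a dicistronic candidate table (columns `trna_id`, `gene_id` and a
#' tissue/group label): per-tissue candidate counts (a row labelled
#' `"A and B"` counts toward both tissues), distinct tRNA genes, isoacceptor
#' families (distinct amino acids), distinct anticodons and distinct
#' chromosomes. Chromosome tokens come from a `chrom` column when present,
#' otherwise from Ensembl-style gene accessions (`VIT_08s... -> "08"`).
#' Candidates with unparseable tRNA names still count toward totals but are
#' excluded from the family/anticodon tallies, with a warning. When a
#' `distance` column is present its median and maximum are reported.
#'
#' @param candidates data frame with `trna_id`, `gene_id` and a `tissue`
#'   (or `group_id`) column.
#' @return object of class `candidate_summary`: list with `n_candidates`,
#'   `tissue_counts` (named), `n_in_all_tissues`, `n_distinct_trna_genes`,
#'   `n_isoacceptor_families`, `n_distinct_anticodons`,
#'   `n_distinct_chromosomes`, `distance_median`, `distance_max`.
#' @examples
#' summarize_candidates(dirt_table1())
#' @export
summarize_candidates <- function(candidates) {
  label_col <- intersect(c("tissue", "group_id"), names(candidates))[1]
  if (is.na(label_col)) stop("candidate table needs a tissue/group_id column")
  n <- nrow(candidates)
  memberships <- strsplit(as.character(candidates[[label_col]]),
                          " and ", fixed = TRUE)
  tissues <- sort(unique(unlist(memberships)))
  tissue_counts <- vapply(tissues, function(t)
    sum(vapply(memberships, function(m) t %in% m, logical(1))), integer(1))
  n_all <- if (length(tissues) > 1L)
    sum(vapply(memberships, function(m) all(tissues %in% m), logical(1)))
  else 0L

  info <- parse_trna_name(as.character(candidates$trna_id))
  if (n && any(info$undefined_flag))
    warning(sum(info$undefined_flag),
            " candidate(s) with unparseable tRNA names excluded from ",
            "family/anticodon tallies")
  ok <- !info$undefined_flag
  chrom_tok <- if ("chrom" %in% names(candidates)) {
    as.character(candidates$chrom)
  } else {
    m <- regmatches(candidates$gene_id,
                    regexpr("(?<=_)[0-9]+(?=s)", candidates$gene_id,
                            perl = TRUE))
    if (length(m) == n) m else NA_character_
  }
  structure(list(
    n_candidates = n,
    tissue_counts = tissue_counts,
    n_in_all_tissues = n_all,
    n_distinct_trna_genes = length(unique(candidates$trna_id)),
    n_isoacceptor_families = length(unique(info$amino_acid[ok])),
    n_distinct_anticodons = length(unique(info$anticodon[ok])),
    n_distinct_chromosomes = length(unique(stats::na.omit(chrom_tok))),
    distance_median = if ("distance" %in% names(candidates) && n)
      stats::median(candidates$distance) else NA_real_,
    distance_max = if ("distance" %in% names(candidates) && n)
      max(candidates$distance) else NA_real_
  ), class = "candidate_summary")
}

#' @export
print.candidate_summary <- function(x, ...) {
  cat("candidate_summary:", x$n_candidates, "candidates\n")
  if (length(x$tissue_counts))
    cat("  per tissue:", paste(names(x$tissue_counts), x$tissue_counts,
                               sep = "=", collapse = ", "),
        sprintf(" (in all: %d)\n", x$n_in_all_tissues))
  cat(sprintf(paste0("  distinct tRNA genes: %d; isoacceptor families: %d; ",
                     "anticodons: %d; chromosomes: %d\n"),
              x$n_distinct_trna_genes, x$n_isoacceptor_families,
              x$n_distinct_anticodons, x$n_distinct_chromosomes))
  if (!is.na(x$distance_median))
    cat(sprintf("  intergenic distance: median %g bp, max %g bp\n",
                x$distance_median, x$distance_max))
  invisible(x)
}

#' Union size of two expressed-feature sets
#'
#' Inclusion-exclusion on per-tissue detection counts:
#' `n_a + n_b - n_both`. Used to check that per-tissue expressed-tRNA
#' tallies are consistent with the reported union.
#'
#' @param n_a,n_b features detected in each tissue.
#' @param n_both features detected in both.
#' @return the union count.
#' @examples
#' count_union(124, 90, 77)  # 137 expressed tRNAs
#' @export
count_union <- function(n_a, n_b, n_both) {
  stopifnot(n_both <= n_a, n_both <= n_b)
  n_a + n_b - n_both
}
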