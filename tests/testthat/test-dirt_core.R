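test_that("expression filter applies both thresholds on group counts", {
  loc <- micro_locus()
  pairs <- loc$pairs
  cfg <- detection_config()
  keep <- function(tc, gc) nrow(filter_expressed_pairs(
    pairs, c("tRNA-Gly-GCC-1-1" = tc), c(G1 = gc), cfg))
  expect_equal(keep(0, 100), 0)   # tRNA count 0 -> dropped
  expect_equal(keep(1, 9), 0)     # PCG count 9 -> dropped
  expect_equal(keep(1, 10), 1)    # boundary kept
  expect_equal(nrow(filter_expressed_pairs(pairs[0, ], numeric(0),
                                           numeric(0), cfg)), 0)
  expect_error(filter_expressed_pairs(pairs, c(other = 5), c(G1 = 50), cfg),
               "no counts")
})

test_that("contrast test matches an independent t-distribution evaluation", {
  ig <- c(10, 12, 11, 13); intr <- c(1, 2, 1, 2)
  got <- intron_contrast_test(ig, intr)
  # closed-form paired one-sided t-test, written out independently
  d <- ig - intr
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$p, stats::pt(tstat, df = length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(got$p, 0.01)
  expect_equal(got$direction, 1)

  # identical vectors: zero differences by convention
  same <- intron_contrast_test(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$p, 1)
  expect_equal(same$direction, 0)

  # reversed direction can never pass the one-sided test
  neg <- intron_contrast_test(c(1, 1, 1), c(5, 5, 6))
  expect_equal(neg$direction, -1)
  expect_gt(neg$p, 0.5)

  # degenerate: constant nonzero difference
  deg <- intron_contrast_test(c(5, 6, 7), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(deg$p > 0 && deg$p < 1e-100)

  expect_error(intron_contrast_test(1, 1), "2 replicates")
  expect_error(intron_contrast_test(c(1, 2), 1), "aligned")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(21)
  for (rep in 1:100) {
    p <- runif(sample(1:1000, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("continuity requires a read on every intergenic base", {
  mk_track <- function(counts) structure(
    list(region = genomic_intervals("c", 0, length(counts)),
         counts = as.integer(counts)), class = "coverage_track")
  expect_true(continuity_check(mk_track(c(1, 1, 2, 3))))
  expect_false(continuity_check(mk_track(c(1, 0, 5))))
  vac <- continuity_check(mk_track(integer(0)))
  expect_true(vac)
  expect_true(attr(vac, "vacuous"))
})

test_that("decision cascade: planted signal is called, masked base rejects", {
  loc <- micro_locus(n_introns = 2)
  depths <- c(3, 4, 3, 5)
  aln <- lapply(seq_along(depths), function(i)
    micro_replicate(loc, ig_depth = depths[i], rep_id = paste0("r", i)))
  names(aln) <- paste0("r", 1:4)
  groups <- data.frame(group_id = "g", replicate_id = names(aln))

  calls <- run_dirt(loc$pairs, aln, groups)
  expect_equal(calls$verdict, "dicistronic")
  expect_true(calls$direction_ok)
  expect_true(calls$continuous)
  expect_lt(calls$q_intron1, 0.05)
  expect_lt(calls$q_intron2, 0.05)

  # one zero-coverage base anywhere in the gap forces rejection
  mask_at <- loc$pairs$intergenic_start + 57
  aln_masked <- lapply(seq_along(depths), function(i)
    micro_replicate(loc, ig_depth = depths[i], rep_id = paste0("r", i),
                    mask = mask_at))
  names(aln_masked) <- names(aln)
  calls2 <- run_dirt(loc$pairs, aln_masked, groups)
  expect_equal(calls2$verdict, "rejected_continuity")
  expect_false(calls2$continuous)
})

test_that("single-intron genes are tested; intronless genes are untestable", {
  groups <- data.frame(group_id = "g", replicate_id = paste0("r", 1:4))
  depths <- c(3, 4, 3, 5)

  one <- micro_locus(n_introns = 1)
  aln <- lapply(1:4, function(i)
    micro_replicate(one, ig_depth = depths[i], rep_id = paste0("r", i)))
  names(aln) <- paste0("r", 1:4)
  calls <- run_dirt(one$pairs, aln, groups)
  expect_equal(calls$verdict, "dicistronic")
  expect_false(is.na(calls$p_intron1))
  expect_true(is.na(calls$p_intron2))   # only one contrast performed

  zero <- micro_locus(n_introns = 0)
  aln0 <- lapply(1:4, function(i)
    micro_replicate(zero, ig_depth = depths[i], rep_id = paste0("r", i)))
  names(aln0) <- paste0("r", 1:4)
  calls0 <- run_dirt(zero$pairs, aln0, groups)
  expect_equal(calls0$verdict, "untestable")
})

test_that("groups with < 2 replicates warn and yield untestable pairs", {
  loc <- micro_locus()
  aln <- list(r1 = micro_replicate(loc, ig_depth = 3))
  groups <- data.frame(group_id = "g", replicate_id = "r1")
  expect_warning(calls <- run_dirt(loc$pairs, aln, groups), "untestable")
  expect_equal(calls$verdict, "untestable")
})

test_that("unexpressed pairs and zero-length gaps route to their verdicts", {
  loc <- micro_locus()
  # drop the PCG reads below threshold: only tRNA + intergenic reads
  aln <- lapply(1:2, function(i) {
    p <- loc$pairs
    starts <- c(seq(p$trna_start, p$trna_start + 4),
                seq(p$intergenic_start, p$intergenic_end - 1))
    mk_aln(starts, len = 1, ids = sprintf("q%d_%04d", i, seq_along(starts)))
  })
  names(aln) <- c("r1", "r2")
  groups <- data.frame(group_id = "g", replicate_id = c("r1", "r2"))
  calls <- run_dirt(loc$pairs, aln, groups)
  expect_equal(calls$verdict, "rejected_expression")

  # abutting tRNA and gene: adjacent, untestable
  trnas <- data.frame(trna_id = "tRNA-Gly-GCC-1-1", chrom = "chr1",
                      start = 100, end = 300, strand = "+",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "G1", chrom = "chr1",
                      start = c(300, 500), end = c(400, 600),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 300, end = 600,
                      strand = "+", mrna_id = "G1.1", n_exons = 2L,
                      stringsAsFactors = FALSE)
  pcgs <- structure(list(genes = genes, exons = exons), class = "pcg_set")
  pairs <- assemble_pairs(trnas, pcgs)
  expect_equal(pairs$distance, 0)
  aln2 <- lapply(1:2, function(i)
    mk_aln(seq(100, 400), len = 1, ids = sprintf("z%d_%04d", i, 1:301)))
  names(aln2) <- c("r1", "r2")
  calls2 <- run_dirt(pairs, aln2, groups)
  expect_equal(calls2$verdict, "untestable")
})

test_that("verdict is monotone in added intergenic coverage", {
  loc <- micro_locus()
  depths <- c(3, 4, 3, 5)
  groups <- data.frame(group_id = "g", replicate_id = paste0("r", 1:4))
  for (boost in c(0, 2, 10)) {
    aln <- lapply(1:4, function(i)
      micro_replicate(loc, ig_depth = depths[i] + boost,
                      rep_id = paste0("r", i)))
    names(aln) <- paste0("r", 1:4)
    calls <- run_dirt(loc$pairs, aln, groups)
    expect_equal(calls$verdict, "dicistronic", info = paste("boost", boost))
  }
})

test_that("fdr_alpha limits gate every expressed, directionally-positive pair", {
  loc <- micro_locus()
  depths <- c(3, 4, 3, 5)
  aln <- lapply(1:4, function(i)
    micro_replicate(loc, ig_depth = depths[i], rep_id = paste0("r", i)))
  names(aln) <- paste0("r", 1:4)
  groups <- data.frame(group_id = "g", replicate_id = paste0("r", 1:4))
  lo <- run_dirt(loc$pairs, aln, groups,
                 detection_config(fdr_alpha = 1e-12))
  expect_equal(lo$verdict, "rejected_test")
  hi <- run_dirt(loc$pairs, aln, groups,
                 detection_config(fdr_alpha = 0.999999))
  expect_equal(hi$verdict, "dicistronic")
})

test_that("identical inputs give byte-identical call tables", {
  loc <- micro_locus()
  depths <- c(3, 4, 3, 5)
  aln <- lapply(1:4, function(i)
    micro_replicate(loc, ig_depth = depths[i], rep_id = paste0("r", i)))
  names(aln) <- paste0("r", 1:4)
  groups <- data.frame(group_id = "g", replicate_id = paste0("r", 1:4))
  f1 <- tempfile(); f2 <- tempfile()
  write_call_table(run_dirt(loc$pairs, aln, groups), f1)
  write_call_table(run_dirt(loc$pairs, aln, groups), f2)
  expect_identical(readLines(f1), readLines(f2))
})
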