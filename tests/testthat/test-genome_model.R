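test_that("GtRNAdb-style names parse into their components", {
  x <- parse_trna_name(c("tRNA-Gly-GCC-1-6", "tRNA-Und-NNN-1-1", "not-a-name"))
  expect_equal(x$amino_acid, c("Gly", "Und", "Und"))
  expect_equal(x$anticodon, c("GCC", "NNN", "NNN"))
  expect_equal(x$isodecoder_family, c(1L, 1L, NA_integer_))
  expect_equal(x$gene_copy, c(6L, 1L, NA_integer_))
  expect_equal(x$undefined_flag, c(FALSE, TRUE, TRUE))
  expect_equal(x$trna_id[3], "not-a-name")  # raw name preserved
})

test_that("BED6 tRNA annotations pass through 0-based and parse names", {
  bed <- write_micro_bed(data.frame(
    chrom = "chr1", start = c(1000L, 5000L), end = c(1072L, 5072L),
    name = c("tRNA-Gly-GCC-1-6", "weird"), strand = c("+", "-"),
    stringsAsFactors = FALSE))
  tr <- parse_trna_annotations(bed)
  expect_equal(tr$start, c(1000, 5000))   # BED taken as-is
  expect_equal(tr$end, c(1072, 5072))
  expect_equal(tr$undefined_flag, c(FALSE, TRUE))
  expect_equal(tr$strand, c("+", "-"))

  empty <- tempfile(fileext = ".bed"); writeLines(character(0), empty)
  expect_equal(nrow(parse_trna_annotations(empty)), 0)
})

test_that("GFF3 genes convert to 0-based half-open and keep the longest mRNA", {
  gff <- write_micro_gff3(list(
    list(id = "G1", chrom = "chr1", mrnas = list(
      list(id = "G1.s", exons = rbind(c(101, 500), c(701, 1000))),   # 900 bp span
      list(id = "G1.l", exons = rbind(c(101, 600), c(901, 1300)))))  # 1200 bp span
  ))
  p <- parse_gene_models(gff)
  expect_equal(p$genes$start, 100)  # GFF 101 -> internal 100
  expect_equal(p$genes$end, 1300)
  expect_equal(p$genes$mrna_id, "G1.l")
  expect_equal(p$exons$start, c(100, 900))
  expect_equal(p$exons$end, c(600, 1300))
})

test_that("parse errors are record-level and exon-less genes are dropped", {
  # three genes, one without exons -> 2 gene models + warning
  gff <- write_micro_gff3(list(
    list(id = "A", chrom = "chr1", mrnas = list(
      list(id = "A.1", exons = rbind(c(101, 200))))),
    list(id = "B", chrom = "chr1", mrnas = list(
      list(id = "B.1", exons = rbind(c(301, 400), c(501, 600)))))
  ))
  cat(sprintf("chr1\ttest\tgene\t701\t800\t.\t+\t.\tID=C\n"),
      file = gff, append = TRUE)
  expect_warning(p <- parse_gene_models(gff), "without exons")
  expect_equal(sort(p$genes$gene_id), c("A", "B"))

  # exon with unknown Parent -> skipped with warning
  cat("chr1\ttest\texon\t710\t790\t.\t+\t.\tParent=nope\n",
      file = gff, append = TRUE)
  expect_warning(expect_warning(parse_gene_models(gff), "unknown Parent"),
                 "without exons")

  # end < start aborts naming the line
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t500\t100\t.\t+\t.\tID=X"), bad)
  expect_error(parse_gene_models(bad), "line 2")
})

test_that("introns are the gaps between consecutive exons", {
  expect_equal(derive_introns(data.frame(start = c(100, 300),
                                         end = c(200, 400))),
               data.frame(start = 200, end = 300))
  expect_equal(nrow(derive_introns(data.frame(start = 100, end = 200))), 0)
  tri <- derive_introns(data.frame(start = c(0, 20, 50), end = c(10, 30, 60)))
  expect_equal(tri$start, c(10, 30))
  expect_equal(tri$end, c(20, 50))
  # unsorted input is sorted first; abutting exons yield no intron
  expect_equal(nrow(derive_introns(data.frame(start = c(20, 0),
                                              end = c(40, 20)))), 0)
})

test_that("pair assembly: adjacency, overlap exclusion, both flanks", {
  trnas <- parse_trna_annotations(write_micro_bed(data.frame(
    chrom = "chr1",
    start = c(1000L, 4100L, 9000L),
    end = c(1075L, 4180L, 9080L),
    name = c("tRNA-Gly-GCC-1-1",   # free, flanked downstream
             "tRNA-Ala-AGC-1-1",   # inside G1's intron -> excluded
             "tRNA-Val-CAC-1-1"),  # flanked on both sides
    stringsAsFactors = FALSE)))
  pcgs <- parse_gene_models(write_micro_gff3(list(
    list(id = "G1", chrom = "chr1", mrnas = list(
      list(id = "G1.1", exons = rbind(c(1209, 4000), c(4501, 5000))))),
    list(id = "G2", chrom = "chr1", mrnas = list(
      list(id = "G2.1", exons = rbind(c(7001, 8000))))),
    list(id = "G3", chrom = "chr1", mrnas = list(
      list(id = "G3.1", exons = rbind(c(9501, 9900)))))
  )))
  pairs <- assemble_pairs(trnas, pcgs)

  # the worked adjacency example: gap [1075, 1208), 133 bp
  p1 <- pairs[pairs$trna_id == "tRNA-Gly-GCC-1-1", ]
  expect_equal(nrow(p1), 1)  # nothing upstream of it
  expect_equal(p1$gene_id, "G1")
  expect_equal(p1$intergenic_start, 1075)
  expect_equal(p1$intergenic_end, 1208)
  expect_equal(p1$distance, 133)
  expect_equal(p1$orientation, "tRNA-upstream")
  # intron nearest the gap comes first
  expect_equal(p1$intron1_start, 4000)
  expect_equal(p1$intron1_end, 4500)

  # tRNA inside an intron is excluded entirely
  expect_false("tRNA-Ala-AGC-1-1" %in% pairs$trna_id)

  # flanked tRNA pairs with both neighbours
  p3 <- pairs[pairs$trna_id == "tRNA-Val-CAC-1-1", ]
  expect_setequal(p3$gene_id, c("G2", "G3"))
  expect_setequal(p3$orientation, c("tRNA-downstream", "tRNA-upstream"))

  # max_distance drops the long pair (G2 is 1000 bp away)
  capped <- assemble_pairs(trnas, pcgs, max_distance = 500)
  expect_false("G2" %in% capped$gene_id)
})

test_that("equidistant genes tie toward the smaller start and are flagged", {
  trnas <- data.frame(trna_id = "tRNA-Gly-GCC-1-1", chrom = "c",
                      start = 1000, end = 1080, strand = "+",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("Gb", "Ga"), chrom = "c",
                      start = c(400, 300), end = c(900, 900),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("Gb", "Ga"), chrom = "c",
                      start = c(400, 300), end = c(900, 900), strand = "+",
                      mrna_id = c("Gb.1", "Ga.1"), n_exons = 1L,
                      stringsAsFactors = FALSE)
  pcgs <- structure(list(genes = genes, exons = exons), class = "pcg_set")
  p <- assemble_pairs(trnas, pcgs)
  expect_equal(p$gene_id, "Ga")  # same end, smaller start wins
  expect_true(p$tie_flag)
})

test_that("assembly agrees with the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n_t <- sample(3:12, 1); n_g <- sample(3:12, 1)
    chroms <- sample(c("c1", "c2"), n_t + n_g, replace = TRUE)
    t_start <- sample.int(5000, n_t)
    g_start <- sample.int(5000, n_g)
    trnas <- data.frame(trna_id = sprintf("tRNA-Gly-GCC-%d-1", seq_len(n_t)),
                        chrom = chroms[seq_len(n_t)], start = t_start,
                        end = t_start + sample(40:90, n_t, replace = TRUE),
                        strand = "+", stringsAsFactors = FALSE)
    g_end <- g_start + sample(100:800, n_g, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("G%02d", seq_len(n_g)),
                        chrom = chroms[n_t + seq_len(n_g)], start = g_start,
                        end = g_end, strand = "+",
                        mrna_id = sprintf("G%02d.1", seq_len(n_g)),
                        n_exons = 1L, stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
    pcgs <- structure(list(genes = genes, exons = exons), class = "pcg_set")

    got <- suppressMessages(assemble_pairs(trnas, pcgs))
    want <- oracle_pairs(trnas, genes)
    key <- function(d) sort(paste(d$trna_id, d$gene_id, d$distance))
    expect_identical(key(got), key(want))
    # every emitted pair: disjoint features, gap length = distance
    expect_true(all(got$distance == got$intergenic_end - got$intergenic_start))
    expect_true(all(pmax(got$trna_start, got$gene_start) >=
                      pmin(got$trna_end, got$gene_end) |
                      got$distance >= 0))
  }
})
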