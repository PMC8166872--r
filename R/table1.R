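## Packaged reproduction of the published grapevine candidate table:
## 19 dicistronic tRNA-mRNA candidates from leaf and berry RNA-seq.
.table1_rows <- data.frame(
  trna_id = c(
    "tRNA-Phe-GAA-1-4", "tRNA-Ala-AGC-1-7", "tRNA-Pro-CGG-2-2",
    "tRNA-Arg-TCG-2-2", "tRNA-Gly-GCC-1-1", "tRNA-Gly-GCC-1-5",
    "tRNA-Gly-GCC-1-6", "tRNA-Val-CAC-1-7", "tRNA-Asn-GTT-2-2",
    "tRNA-Met-CAT-1-3", "tRNA-His-GTG-8-1", "tRNA-Gly-TCC-1-6",
    "tRNA-Thr-AGT-1-4", "tRNA-Ile-AAT-3-1", "tRNA-Pro-TGG-2-9",
    "tRNA-Phe-GAA-1-4", "tRNA-Leu-TAA-2-3", "tRNA-Gly-CCC-1-3",
    "tRNA-Thr-AGT-2-1"
  ),
  gene_id = c(
    "VIT_07s0005g02200", "VIT_14s0066g02600", "VIT_14s0060g01370",
    "VIT_09s0002g04750", "VIT_02s0154g00160", "VIT_07s0005g02990",
    "VIT_08s0058g00460", "VIT_15s0046g02860", "VIT_18s0001g12620",
    "VIT_07s0129g00230", "VIT_17s0000g06990", "VIT_13s0064g00200",
    "VIT_00s0322g00020", "VIT_04s0023g03700", "VIT_18s0001g09050",
    "VIT_07s0005g02210", "VIT_08s0007g03950", "VIT_19s0177g00220",
    "VIT_05s0077g01490"
  ),
  tissue = c(
    rep("Leaf", 10), rep("Leaf and Berry", 6), rep("Berry", 3)
  ),
  stringsAsFactors = FALSE
)

#' Packaged candidate table (grapevine leaf/berry)
#'
#' The 19-row reproduction of the published dicistronic tRNA-mRNA candidate
#' table for grapevine: tRNA gene, Ensembl gene accession and tissue(s) of
#' detection. Used by the summarizer tests and as a worked example.
#'
#' @return data frame with columns `trna_id`, `gene_id`, `tissue`.
#' @examples
#' nrow(dirt_table1())  # 19 candidates
#' @export
dirt_table1 <- function() .table1_rows

#' Write the packaged candidate table as a TSV fixture
#'
#' @param path output path (default: `table1_candidates.tsv` in the working
#'   directory).
#' @return `path`, invisibly.
#' @export
write_fixture_table1 <- function(path = "table1_candidates.tsv") {
  utils::write.table(dirt_table1(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
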