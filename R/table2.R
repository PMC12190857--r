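#' Published robust hypermethylated DMRs (packaged reference table)
#'
#' The 15 robustly hypermethylated, gene-annotated 300-bp regions reported
#' for ovarian-cancer plasma cfDNA, shipped with the package as a small
#' TSV. Printed coordinates are 1-based inclusive; the reader also derives
#' internal 0-based half-open `start`/`end` columns and the region width.
#'
#' @param path override the packaged TSV (mainly for tests).
#' @return data frame with `gene`, `chrom`, `start_1`, `stop_1`,
#'   `log2FC`, `padj`, plus derived `start`, `end`, `width`.
#' @examples
#' tab <- robust_dmr_table()
#' nrow(tab)          # 15 genes
#' unique(tab$width)  # all spans are 300 bp
#' @export
robust_dmr_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "robust_dmrs_published.tsv",
                        package = "cfmedip", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  iv <- from_one_based(tab$chrom, tab$start_1, tab$stop_1, name = tab$gene)
  tab$start <- iv$start
  tab$end <- iv$end
  tab$width <- tab$stop_1 - tab$start_1 + 1L
  tab
}
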