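#' Derive CpG-context sets: islands, shores, shelves, open sea
#'
#' Standard flanking conventions: shores are the 0-2 kb flanks of merged
#' CpG islands (minus the islands), shelves the 2-4 kb flanks (minus
#' islands and shores), open sea everything else. The four sets partition
#' the genome exactly.
#'
#' @param islands CpG-island interval data frame.
#' @param layout a [genome_layout()].
#' @param shore_width,shelf_width flank widths in bp (defaults 2000 each,
#'   i.e. shores 0-2 kb and shelves 2-4 kb from an island edge).
#' @return named list of interval data frames: `island`, `shore`, `shelf`,
#'   `open_sea`.
#' @export
derive_cpg_context <- function(islands, layout, shore_width = 2000L,
                               shelf_width = 2000L) {
  genome_gr <- as_granges(data.frame(chrom = layout$chrom, start = 0,
                                     end = layout$length), layout)
  if (nrow(islands) == 0L) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character())
    return(list(island = empty, shore = empty, shelf = empty,
                open_sea = granges_to_df(genome_gr)))
  }
  validate_gintervals(islands, layout)
  isl <- GenomicRanges::reduce(as_granges(islands, layout))
  # flank expansion deliberately runs past chromosome ends; trim clips it
  near <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::reduce(isl + shore_width)))
  far <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::reduce(isl + (shore_width + shelf_width))))
  shore <- GenomicRanges::setdiff(near, isl)
  shelf <- GenomicRanges::setdiff(far, GenomicRanges::union(isl, shore))
  open_sea <- GenomicRanges::setdiff(genome_gr, far)
  list(island = granges_to_df(isl), shore = granges_to_df(shore),
       shelf = granges_to_df(shelf), open_sea = granges_to_df(open_sea))
}

# logical matrix: query interval x category, TRUE iff >= 1 bp overlap with
# any interval of that category's set
classify_intervals <- function(query, sets, layout) {
  if (nrow(query) == 0L) {
    return(matrix(logical(0), nrow = 0, ncol = length(sets),
                  dimnames = list(NULL, names(sets))))
  }
  q <- as_granges(query, layout)
  hits <- vapply(sets, function(s) {
    if (is.null(s) || nrow(s) == 0L) return(rep(FALSE, nrow(query)))
    GenomicRanges::countOverlaps(q, as_granges(s, layout), minoverlap = 1L) > 0
  }, logical(nrow(query)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1, dimnames = list(NULL, names(sets)))
  hits
}

#' Classify regions by CpG context
#'
#' Every category a region overlaps by >= 1 bp is reported, so a 300-bp
#' region straddling an island edge belongs to both `island` and `shore`.
#'
#' @param regions interval data frame (e.g. called DMRs).
#' @param context output of [derive_cpg_context()].
#' @param layout a [genome_layout()].
#' @return logical matrix, regions x {island, shore, shelf, open_sea}.
#' @export
classify_cpg <- function(regions, context, layout) {
  classify_intervals(regions, context, layout)
}

# build strand-aware promoter / upstream interval sets from gene models
promoter_upstream_sets <- function(genes, layout, promoter_width = 1000L,
                                   upstream_max = 5000L) {
  clip <- function(df) {
    len <- chrom_length(layout, df$chrom)
    df$start <- pmax(df$start, 0)
    df$end <- pmin(df$end, len)
    df[df$start < df$end, , drop = FALSE]
  }
  plus <- genes$strand == "+"
  prom <- data.frame(chrom = genes$chrom,
                     start = ifelse(plus, genes$tss - promoter_width, genes$tss),
                     end = ifelse(plus, genes$tss, genes$tss + promoter_width))
  up <- data.frame(chrom = genes$chrom,
                   start = ifelse(plus, genes$tss - upstream_max,
                                  genes$tss + promoter_width),
                   end = ifelse(plus, genes$tss - promoter_width,
                                genes$tss + upstream_max))
  list(promoter = clip(prom), upstream_1to5kb = clip(up))
}

#' Classify regions by gene feature
#'
#' Categories: `promoter` (1 kb upstream of the TSS, strand-aware),
#' `upstream_1to5kb` (1-5 kb upstream of the TSS), `exon`, `intron`
#' (gene body minus exons), `utr5`, `utr3`, and `intergenic` (no other
#' category hit). Multi-category hits are all reported.
#'
#' @param regions interval data frame.
#' @param annotation an `annotation_db` (needs `genes`, `exons`, `utr5`,
#'   `utr3`).
#' @param layout a [genome_layout()].
#' @return logical matrix, regions x categories.
#' @export
classify_gene_feature <- function(regions, annotation, layout) {
  genes <- annotation$genes
  pu <- promoter_upstream_sets(genes, layout)
  body_gr <- GenomicRanges::reduce(as_granges(genes, layout))
  exon_gr <- GenomicRanges::reduce(as_granges(annotation$exons, layout))
  intron <- granges_to_df(GenomicRanges::setdiff(body_gr, exon_gr))
  sets <- list(promoter = pu$promoter, upstream_1to5kb = pu$upstream_1to5kb,
               exon = annotation$exons, intron = intron,
               utr5 = annotation$utr5, utr3 = annotation$utr3)
  hits <- classify_intervals(regions, sets, layout)
  cbind(hits, intergenic = rowSums(hits) == 0)
}

#' Classify regions by repeat class
#'
#' Repeat classes come from the track's `name` column and must be one of
#' LINE, SINE, LTR, other. All overlapped classes are reported; `none`
#' is set iff a region overlaps no repeat at all.
#'
#' @param regions interval data frame.
#' @param repeats repeat interval data frame with class in `name`.
#' @param layout a [genome_layout()].
#' @return logical matrix, regions x {LINE, SINE, LTR, other, none}.
#' @export
classify_repeat <- function(regions, repeats, layout) {
  classes <- c("LINE", "SINE", "LTR", "other")
  unknown <- setdiff(unique(repeats$name), classes)
  if (length(unknown)) stop("unknown repeat class label(s): ",
                            paste(unknown, collapse = ", "))
  sets <- lapply(classes, function(cl) repeats[repeats$name == cl, , drop = FALSE])
  names(sets) <- classes
  hits <- classify_intervals(regions, sets, layout)
  cbind(hits, none = rowSums(hits) == 0)
}

#' Category distribution of a region set
#'
#' Each (region, category) assignment counts once; the percentage is the
#' category's assignment count over the total number of assignments, so a
#' region hitting two categories contributes half a unit to each bar and
#' the percentages within a family always sum to 100.
#'
#' @param hits logical classification matrix (regions x categories) from
#'   one of the `classify_*` functions.
#' @return data frame with `category`, `count`, `percent`.
#' @export
feature_distribution <- function(hits) {
  if (nrow(hits) == 0L) stop("no regions to summarize")
  count <- colSums(hits)
  total <- sum(count)
  if (total == 0) stop("no category assignments")
  data.frame(category = colnames(hits), count = as.integer(count),
             percent = 100 * count / total, row.names = NULL,
             stringsAsFactors = FALSE)
}
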