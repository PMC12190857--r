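#' Genome layout: ordered chromosome names and lengths
#'
#' A genome layout is the coordinate frame shared by every stage of the
#' analysis: an ordered set of chromosome names with their lengths in base
#' pairs. The order is stable and defines the serialization order of every
#' derived object (bin grids, BED tracks, count matrices).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (>= 1).
#' @return A `genome_layout` data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e5, 5e4))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.integer(length)
  if (length(chrom) == 0L) stop("genome layout must contain at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(is.na(length)) || any(length < 1L)) stop("chromosome lengths must be positive integers")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read / write a two-column chrom.sizes file
#'
#' @param path file path; tab-separated `name<TAB>length`, no header.
#' @return `read_chrom_sizes` returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "integer"))
  genome_layout(x$chrom, x$length)
}

#' @param layout a [genome_layout()].
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Construct genomic intervals (0-based, half-open)
#'
#' Internal coordinates are 0-based half-open `[start, end)`, the BED
#' convention. Published tables typically print 1-based inclusive
#' coordinates; use [from_one_based()] to ingest those losslessly.
#'
#' @param chrom,start,end vectors (recycled) defining the intervals.
#' @param name optional interval names.
#' @param layout optional [genome_layout()]; when given, intervals are
#'   validated against chromosome bounds.
#' @return data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
gintervals <- function(chrom, start, end, name = NA_character_, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = as.character(name),
                   stringsAsFactors = FALSE)
  validate_gintervals(df, layout)
  df
}

validate_gintervals <- function(df, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) stop("invalid interval(s) at row(s) ", paste(bad, collapse = ", "),
                        ": need 0 <= start < end")
  if (!is.null(layout)) {
    len <- chrom_length(layout, df$chrom)
    oob <- which(df$end > len)
    if (length(oob)) stop("interval(s) beyond chromosome end at row(s) ",
                          paste(oob, collapse = ", "))
  }
  invisible(df)
}

#' Convert 1-based inclusive coordinates to internal intervals
#'
#' Report tables print genomic regions as 1-based inclusive start/stop
#' pairs (so a 300-bp bin prints as e.g. 114,671,701..114,672,000).
#' This converts to 0-based half-open: `start = start_1 - 1`, `end = stop_1`.
#'
#' @param chrom chromosome name(s).
#' @param start_1,stop_1 1-based inclusive coordinates, `stop_1 >= start_1`.
#' @param name optional names.
#' @return interval data frame as from [gintervals()].
#' @export
from_one_based <- function(chrom, start_1, stop_1, name = NA_character_) {
  if (any(start_1 < 1)) stop("1-based start must be >= 1")
  if (any(stop_1 < start_1)) stop("stop before start in 1-based coordinates")
  gintervals(chrom, start_1 - 1, stop_1, name)
}

#' Echo intervals in 1-based inclusive coordinates
#'
#' @param intervals interval data frame.
#' @return the input with `start_1` and `stop_1` columns appended.
#' @export
to_one_based <- function(intervals) {
  intervals$start_1 <- intervals$start + 1
  intervals$stop_1 <- intervals$end
  intervals
}

#' Pairwise interval overlap test
#'
#' Two half-open intervals overlap iff they share at least one base pair:
#' same chromosome, `a.start < b.end` and `b.start < a.end`. Adjacent
#' intervals (`end == start`) do not overlap. Vectorized elementwise with
#' recycling.
#'
#' @param a,b interval data frames.
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] & a$start[ai] < b$end[bi] & b$start[bi] < a$end[ai]
}

# Convert interval data frame to GRanges (1-based closed internally to
# GenomicRanges) on the layout's seqlevels, for set operations.
as_granges <- function(df, layout) {
  sl <- stats::setNames(layout$length, layout$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = layout$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = sl)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name
                    else rep(NA_character_, length(gr)),
             stringsAsFactors = FALSE)
}

#' Tile a genome into fixed-width non-overlapping bins
#'
#' Each chromosome is tiled left to right with `width`-bp bins; the last
#' bin of a chromosome is truncated at the chromosome end (and kept), so a
#' chromosome of length L yields `ceiling(L / width)` bins. Bins carry a
#' global 1-based index running through chromosomes in layout order; the
#' index <-> (chrom, start) mapping is a bijection.
#'
#' @param layout a [genome_layout()].
#' @param width bin width in bp (default 300, the standard cfMeDIP-seq
#'   window size).
#' @return a `bin_grid` list with elements `layout`, `width`, `offset`
#'   (per-chromosome global index offset) and `n_bins`.
#' @export
build_bin_grid <- function(layout, width = 300L) {
  if (!inherits(layout, "genome_layout")) layout <- genome_layout(layout$chrom, layout$length)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("bin width must be >= 1")
  nb <- as.integer(ceiling(layout$length / width))
  structure(list(layout = layout, width = width,
                 offset = c(0L, cumsum(nb))[seq_along(nb)],
                 n_per_chrom = nb, n_bins = sum(nb)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", nrow(x$layout), "chromosome(s),", x$width, "bp bins,",
      x$n_bins, "bins total\n")
  invisible(x)
}

#' Enumerate all bins of a grid as intervals
#'
#' @param grid a `bin_grid`.
#' @return interval data frame with a `bin_id` column (global index).
#' @export
bin_intervals <- function(grid) {
  L <- grid$layout
  out <- lapply(seq_len(nrow(L)), function(i) {
    n <- grid$n_per_chrom[i]
    s <- (seq_len(n) - 1L) * grid$width
    data.frame(bin_id = grid$offset[i] + seq_len(n),
               chrom = L$chrom[i], start = s,
               end = pmin(s + grid$width, L$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map genomic positions to global bin indices
#'
#' @param grid a `bin_grid`.
#' @param chrom chromosome names.
#' @param pos 0-based positions, `0 <= pos < length(chrom)`.
#' @return integer global bin ids.
#' @export
bin_index_at <- function(grid, chrom, pos) {
  i <- match(chrom, grid$layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  if (any(pos < 0) || any(pos >= grid$layout$length[i])) stop("position outside chromosome")
  grid$offset[i] + pos %/% grid$width + 1L
}

#' Recover the interval of given global bin ids
#'
#' @param grid a `bin_grid`.
#' @param bin_id integer global bin ids.
#' @return interval data frame with `bin_id`, `chrom`, `start`, `end`.
#' @export
bin_interval_of <- function(grid, bin_id) {
  if (any(bin_id < 1L) || any(bin_id > grid$n_bins)) stop("bin id out of range")
  ci <- findInterval(bin_id - 1L, grid$offset)
  local <- bin_id - grid$offset[ci] - 1L
  s <- local * grid$width
  data.frame(bin_id = bin_id, chrom = grid$layout$chrom[ci], start = s,
             end = pmin(s + grid$width, grid$layout$length[ci]),
             stringsAsFactors = FALSE)
}

#' Read / write BED (3+ columns, 0-based half-open)
#'
#' Malformed or out-of-bounds records are rejected with the offending line
#' number. Column 4, when present, becomes the interval `name`.
#'
#' @param path BED file path.
#' @param layout optional [genome_layout()] for bounds checking.
#' @return `read_bed` returns an interval data frame.
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("malformed BED line ", idx[which(nf < 3L)[1]],
                         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", idx[bad[1]], ": non-numeric coordinates")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) stop("invalid interval at BED line ", idx[bad[1]],
                        ": need 0 <= start < end")
  if (!is.null(layout)) {
    known <- chrom %in% layout$chrom
    if (!all(known)) stop("unknown chromosome at BED line ", idx[which(!known)[1]],
                          ": ", chrom[which(!known)[1]])
    len <- chrom_length(layout, chrom)
    oob <- which(end > len)
    if (length(oob)) stop("interval beyond chromosome end at BED line ", idx[oob[1]])
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' @param intervals interval data frame to write.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  validate_gintervals(intervals)
  has_name <- "name" %in% names(intervals) && !all(is.na(intervals$name))
  cols <- if (has_name) {
    data.frame(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE),
               ifelse(is.na(intervals$name), ".", intervals$name))
  } else {
    data.frame(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count CpG dinucleotides in a DNA sequence
#'
#' Counts occurrences of the dinucleotide "CG" on the forward strand,
#' scanning at step 1 (so "CGCG" contains 2). CpG is its own reverse
#' complement, so forward-strand counting covers both strands.
#'
#' @param sequence character vector of DNA sequences over A/C/G/T/N
#'   (case-insensitive).
#' @return integer vector of CpG counts.
#' @export
count_cpg <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (any(grepl("[^ACGTN]", s))) stop("sequence contains non-IUPAC characters")
  vapply(s, function(x) {
    if (nchar(x) < 2L) return(0L)
    m <- gregexpr("(?=CG)", x, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-bin CpG counts from a genome sequence
#'
#' A CpG site straddling a bin boundary is credited to the bin containing
#' its C (the dinucleotide's first base).
#'
#' @param grid a `bin_grid`.
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, covering
#'   every chromosome of the grid's layout.
#' @return integer vector of length `grid$n_bins` of CpG counts per bin.
#' @export
bin_cpg_counts <- function(grid, genome) {
  L <- grid$layout
  missing <- setdiff(L$chrom, names(genome))
  if (length(missing)) stop("genome sequence missing for: ", paste(missing, collapse = ", "))
  counts <- integer(grid$n_bins)
  for (i in seq_len(nrow(L))) {
    seq <- genome[[L$chrom[i]]]
    if (length(seq) != L$length[i]) stop("sequence length mismatch for ", L$chrom[i])
    hits <- Biostrings::matchPattern("CG", seq)
    if (length(hits)) {
      pos0 <- BiocGenerics::start(hits) - 1L  # 0-based position of the C
      tab <- table(pos0 %/% grid$width)
      idx <- grid$offset[i] + as.integer(names(tab)) + 1L
      counts[idx] <- counts[idx] + as.integer(tab)
    }
  }
  counts
}

#' Read / write FASTA genomes
#'
#' Thin wrappers around Biostrings readers keeping chromosome order.
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @param genome a [Biostrings::DNAStringSet].
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
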