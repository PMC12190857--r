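#' Count fragments into genome bins by midpoint
#'
#' Each cfDNA fragment increments exactly one bin: the bin containing its
#' midpoint `floor((start + end) / 2)`. This conserves totals (column sum
#' equals fragment count) and avoids double-counting fragments that span a
#' bin boundary.
#'
#' @param fragments interval data frame of one sample's fragments.
#' @param grid a `bin_grid`.
#' @return integer vector of length `grid$n_bins`.
#' @export
count_fragments <- function(fragments, grid) {
  if (nrow(fragments) == 0L) return(integer(grid$n_bins))
  ci <- match(fragments$chrom, grid$layout$chrom)
  bad <- which(is.na(ci) | fragments$start < 0 |
                 fragments$end > grid$layout$length[ci])
  if (length(bad)) stop("fragment outside genome layout at record ", bad[1])
  mid <- (fragments$start + fragments$end) %/% 2
  ids <- bin_index_at(grid, fragments$chrom, mid)
  counts <- integer(grid$n_bins)
  tab <- tabulate(ids, nbins = grid$n_bins)
  as.integer(tab)
}

#' Build a bin x sample count matrix from per-sample fragment sets
#'
#' @param fragment_list named list of fragment interval data frames, one
#'   per sample.
#' @param grid a `bin_grid`.
#' @return integer matrix (bins x samples) with rownames = global bin ids.
#' @export
count_matrix_from_fragments <- function(fragment_list, grid) {
  m <- vapply(fragment_list, count_fragments, integer(grid$n_bins), grid = grid)
  rownames(m) <- as.character(seq_len(grid$n_bins))
  m
}

# bins (global ids) overlapping any of a set of intervals, by tiling
# arithmetic: interval [s, e) touches bins floor(s/w) .. floor((e-1)/w)
bins_overlapping <- function(grid, intervals) {
  if (nrow(intervals) == 0L) return(integer(0))
  validate_gintervals(intervals, grid$layout)
  ci <- match(intervals$chrom, grid$layout$chrom)
  w <- grid$width
  ids <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    lo <- intervals$start[i] %/% w
    hi <- (intervals$end[i] - 1) %/% w
    grid$offset[ci[i]] + (lo:hi) + 1L
  }))
  sort(unique(as.integer(ids)))
}

#' Filtering cascade for cfMeDIP bin counts
#'
#' Four sequential bin filters are applied before differential testing:
#'
#' 1. `blacklist_filter`: bins overlapping (>= 1 bp) any blacklist
#'    artifact region are removed.
#' 2. `pbl_background_filter`: bins with more than `threshold` (default
#'    20, strict) read counts in at least one peripheral-blood-leukocyte
#'    sample are removed — these reflect hematopoietic background rather
#'    than tumor-derived signal.
#' 3. `low_total_filter`: bins whose total count across all cfDNA samples
#'    is below `min_total` (default 10, strict) are removed as
#'    low-coverage noise.
#' 4. `cpg_presence_filter`: bins without a single CpG site are removed.
#'
#' Each stage function returns the global bin ids its rule removes,
#' evaluated on the full grid; [run_filter_cascade()] applies them in the
#' order above and reports per-stage removals among the bins still alive.
#'
#' @param grid a `bin_grid`.
#' @param blacklist interval data frame of artifact regions.
#' @return integer vector of removed global bin ids.
#' @rdname filter_cascade
#' @export
blacklist_filter <- function(grid, blacklist) {
  bins_overlapping(grid, blacklist)
}

#' @param pbl_counts integer matrix of PBL sample columns (bins x samples).
#' @param threshold PBL read-count cutoff; a bin is removed iff some PBL
#'   sample strictly exceeds it.
#' @rdname filter_cascade
#' @export
pbl_background_filter <- function(pbl_counts, threshold = 20) {
  if (is.null(dim(pbl_counts))) pbl_counts <- matrix(pbl_counts, ncol = 1)
  if (ncol(pbl_counts) == 0L) stop("no PBL samples")
  ids <- which(apply(pbl_counts, 1L, max) > threshold)
  as.integer(rownames(pbl_counts)[ids] %||% ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param counts integer matrix over cfDNA samples (bins x samples).
#' @param min_total minimum total count across cfDNA samples; bins with
#'   total strictly below it are removed.
#' @rdname filter_cascade
#' @export
low_total_filter <- function(counts, min_total = 10) {
  ids <- which(rowSums(counts) < min_total)
  as.integer(rownames(counts)[ids] %||% ids)
}

#' @param cpg integer per-bin CpG counts (as from [bin_cpg_counts()]).
#' @rdname filter_cascade
#' @export
cpg_presence_filter <- function(cpg) {
  which(cpg == 0L)
}

#' Apply the four-stage filter cascade and report per-stage removals
#'
#' Order: blacklist, PBL background, low total, CpG presence. The output
#' count matrix keeps only cfDNA samples (groups OC/benign/healthy);
#' PBL columns enter only as the background reference of stage 2. With no
#' PBL samples, stage 2 is skipped and a warning is recorded in the
#' report.
#'
#' @param counts integer matrix (bins x samples), rownames = global bin
#'   ids, covering cfDNA samples and (optionally) PBL samples.
#' @param sheet sample sheet with `sample_id` and `group` columns; groups
#'   `OC`, `benign`, `healthy` are cfDNA, `PBL` is background.
#' @param grid a `bin_grid`.
#' @param blacklist interval data frame.
#' @param cpg per-bin CpG counts.
#' @param pbl_threshold,min_total stage thresholds (defaults 20 and 10).
#' @return list with `counts` (filtered cfDNA matrix), `report` (stage,
#'   removed, remaining, note) and `surviving_bins`.
#' @export
run_filter_cascade <- function(counts, sheet, grid, blacklist, cpg,
                               pbl_threshold = 20, min_total = 10) {
  if (is.null(rownames(counts))) rownames(counts) <- as.character(seq_len(nrow(counts)))
  miss <- setdiff(colnames(counts), sheet$sample_id)
  if (length(miss)) stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  grp <- sheet$group[match(colnames(counts), sheet$sample_id)]
  cf_cols <- colnames(counts)[grp %in% c("OC", "benign", "healthy")]
  pbl_cols <- colnames(counts)[grp == "PBL"]
  if (length(cf_cols) == 0L) stop("no cfDNA samples in count matrix")

  alive <- as.integer(rownames(counts))
  stages <- c("blacklist", "pbl_background", "low_total", "no_cpg")
  removed_n <- integer(4); notes <- character(4)
  for (k in seq_along(stages)) {
    rm_ids <- switch(stages[k],
      blacklist = blacklist_filter(grid, blacklist),
      pbl_background = {
        if (length(pbl_cols) == 0L) {
          notes[k] <- "skipped: no PBL samples"
          integer(0)
        } else {
          pbl_background_filter(counts[, pbl_cols, drop = FALSE], pbl_threshold)
        }
      },
      low_total = {
        cf <- counts[as.character(alive), cf_cols, drop = FALSE]
        low_total_filter(cf, min_total)
      },
      no_cpg = which(cpg == 0L))
    hit <- intersect(alive, rm_ids)
    removed_n[k] <- length(hit)
    alive <- setdiff(alive, hit)
  }
  report <- data.frame(stage = stages, removed = removed_n,
                       remaining = nrow(counts) - cumsum(removed_n),
                       note = notes, stringsAsFactors = FALSE)
  list(counts = counts[as.character(alive), cf_cols, drop = FALSE],
       report = report, surviving_bins = alive)
}

#' Read / write a bin count table (TSV)
#'
#' Layout: `bin_id`, `chrom`, `start`, `end`, then one integer column per
#' sample. Coordinates are 0-based half-open.
#'
#' @param counts integer matrix with rownames = global bin ids.
#' @param grid a `bin_grid` (for the coordinate columns).
#' @param path output TSV path.
#' @export
write_count_table <- function(counts, grid, path) {
  iv <- bin_interval_of(grid, as.integer(rownames(counts)))
  df <- cbind(iv, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @return `read_count_table` returns an integer matrix with rownames =
#'   bin ids.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("bin_id", "chrom", "start", "end")),
                    drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$bin_id)
  m
}
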