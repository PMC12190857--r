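#' Variance-flattening transform of normalized counts
#'
#' `log2(count / size_factor + 1)`: a simple monotone transform that
#' flattens the count-variance relationship enough for SVD/PCA-style
#' decomposition. Doubling a sample's counts and its factor leaves its
#' column unchanged.
#'
#' @param counts integer matrix (bins x samples).
#' @param factors positive size factors.
#' @return numeric matrix, same shape, with attribute `transform`.
#' @export
vst_transform <- function(counts, factors) {
  if (any(factors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(counts, 2L, factors, "/") + 1)
  attr(out, "transform") <- "log2p1_normalized"
  out
}

#' SVD batch-effect check
#'
#' Rows (bins) are centered, the singular value decomposition taken, and
#' the sample scores on the first two right singular vectors each tested
#' for association with library batch by one-way ANOVA. Sign ambiguity is
#' resolved by forcing the largest-magnitude loading of each component
#' positive. Degenerate components (zero variance) report `NA`.
#'
#' @param matrix transformed matrix (bins x samples).
#' @param batches batch labels per sample; >= 2 batches, each with >= 2
#'   samples.
#' @return list with `p` (ANOVA p for SV1, SV2), `var_explained`
#'   (fraction per component), `scores` (samples x 2).
#' @export
svd_batch_check <- function(matrix, batches) {
  batches <- as.factor(batches)
  if (nlevels(batches) < 2L) stop("need >= 2 batches")
  if (any(table(batches) < 2L)) stop("every batch needs >= 2 samples")
  x <- matrix - rowMeans(matrix)
  sv <- svd(x, nu = 0, nv = 2)
  scores <- sv$v[, 1:2, drop = FALSE] * rep(sv$d[1:2], each = nrow(sv$v))
  for (j in 1:2) if (scores[which.max(abs(scores[, j])), j] < 0) {
    scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(matrix)
  colnames(scores) <- c("SV1", "SV2")
  p <- vapply(1:2, function(j) {
    if (stats::sd(scores[, j]) == 0) return(NA_real_)
    stats::anova(stats::lm(scores[, j] ~ batches))[["Pr(>F)"]][1]
  }, numeric(1))
  names(p) <- c("SV1", "SV2")
  ve <- sv$d^2 / sum(sv$d^2)
  list(p = p, var_explained = ve[1:2], scores = scores)
}

#' Select the k most variable bins
#'
#' Row-wise sample variance over the selected samples; ties broken by bin
#' index (row order).
#'
#' @param counts matrix (bins x samples), rownames = bin ids.
#' @param k number of bins to keep (default 10000).
#' @return character vector of the selected bin ids, in decreasing
#'   variance order.
#' @export
top_variance_bins <- function(counts, k = 10000L) {
  if (k > nrow(counts)) stop("k exceeds the number of bins")
  v <- apply(counts, 1L, stats::var)
  ord <- order(-v, seq_along(v))
  rn <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  rn[ord[seq_len(k)]]
}

#' K-means clustering of samples with PCA coordinates
#'
#' Clusters the transposed matrix (samples as observations) with k-means,
#' keeping the best of `restarts` random initializations by within-cluster
#' sum of squares, and returns two PCA coordinates per sample for
#' plotting. PCA signs are fixed by forcing the largest-magnitude loading
#' of each component positive. Fully deterministic under `seed`.
#'
#' @param counts matrix (bins x samples); columns are clustered.
#' @param k number of clusters (default 2).
#' @param seed integer seed.
#' @param restarts random restarts (default 10).
#' @return list with `cluster` (named integer vector), `pca` (samples x
#'   PC1/PC2), `tot_withinss`.
#' @export
kmeans_cluster <- function(counts, k = 2L, seed = 1L, restarts = 10L) {
  x <- t(counts)
  if (nrow(x) < k) stop("k exceeds the number of samples")
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  sc <- pc$x[, 1:2, drop = FALSE]
  for (j in seq_len(ncol(sc))) {
    if (sc[which.max(abs(sc[, j])), j] < 0) sc[, j] <- -sc[, j]
  }
  cl <- km$cluster
  names(cl) <- colnames(counts)
  list(cluster = cl, pca = sc, tot_withinss = km$tot.withinss)
}

#' Row-scaled heatmap matrix for representative DMRs
#'
#' Extracts the representative bin of each gene from the filtered counts,
#' log2(x + 1)-transforms, and scales each row to mean 0 / SD 1. Sample
#' columns are ordered by diagnostic group (OC, benign, healthy), stable
#' by sample id within a group, and never clustered. Constant rows are
#' zeroed with a warning (they carry no contrast).
#'
#' @param counts filtered count matrix (bins x cfDNA samples).
#' @param representatives data frame with `gene_id` and `bin_id` (as from
#'   [map_dmrs_to_genes()] / [robustness_excluding()]).
#' @param sheet sample sheet with `sample_id`, `group`.
#' @param group_order column group order (default OC, benign, healthy).
#' @return numeric matrix (genes x samples) with attribute
#'   `column_groups`.
#' @export
heatmap_matrix <- function(counts, representatives, sheet,
                           group_order = c("OC", "benign", "healthy")) {
  miss <- setdiff(as.character(representatives$bin_id), rownames(counts))
  if (length(miss)) {
    stop("representative bin(s) absent from filtered counts for gene(s): ",
         paste(representatives$gene_id[match(miss, as.character(representatives$bin_id))],
               collapse = ", "))
  }
  grp <- sheet$group[match(colnames(counts), sheet$sample_id)]
  ord <- order(match(grp, group_order), colnames(counts))
  m <- log2(counts[as.character(representatives$bin_id), ord, drop = FALSE] + 1)
  rownames(m) <- representatives$gene_id
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning("constant row(s) zeroed: ",
            paste(rownames(m)[flat], collapse = ", "))
    sdv[flat] <- 1
  }
  z <- (m - mu) / sdv
  z[flat, ] <- 0
  attr(z, "column_groups") <- grp[ord]
  z
}
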