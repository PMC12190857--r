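#' Median-of-ratios size factors
#'
#' Sequencing-depth normalization for bin counts: each sample's factor is
#' the median, over reference bins, of its counts divided by the bin's
#' geometric mean across samples. Reference bins are by default the bins
#' with no zero count in any sample; with `fallback = TRUE` the reference
#' relaxes to bins positive in at least half the samples (geometric means
#' then taken over the positive entries only). Factors are rescaled to
#' geometric mean 1, so they are interpretable as relative depths.
#'
#' @param counts integer matrix, bins x samples (>= 2 samples).
#' @param fallback use the positive-in->=50%-of-samples pseudo-reference
#'   when no bin has all-positive counts.
#' @return numeric vector of positive size factors, one per sample, with
#'   attribute `reference_bins` (number used) and `fallback` (logical).
#' @export
size_factors <- function(counts, fallback = FALSE) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  lc <- log(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  used_fallback <- FALSE
  if (any(all_pos)) {
    loggeo <- rowMeans(lc[all_pos, , drop = FALSE])
    ref <- lc[all_pos, , drop = FALSE]
    logf <- apply(ref - loggeo, 2L, stats::median)
    n_ref <- sum(all_pos)
  } else {
    if (!fallback) {
      stop("no bin has positive counts in every sample; ",
           "re-run with fallback = TRUE to use a pseudo-reference of bins ",
           "positive in >= 50% of samples")
    }
    used_fallback <- TRUE
    half <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(half)) stop("no bin positive in >= 50% of samples")
    sub <- lc[half, , drop = FALSE]
    loggeo <- apply(sub, 1L, function(r) mean(r[is.finite(r)]))
    logf <- apply(sub - loggeo, 2L, function(r) stats::median(r[is.finite(r)]))
    n_ref <- sum(half)
  }
  f <- exp(logf - mean(logf))  # rescale to geometric mean 1
  names(f) <- colnames(counts)
  attr(f, "reference_bins") <- n_ref
  attr(f, "fallback") <- used_fallback
  f
}

#' Method-of-moments negative-binomial dispersion per bin
#'
#' Using depth-normalized counts, the within-group pooled variance `s2`
#' and overall mean `m` of each bin give `alpha = max((s2 - m) / m^2,
#' alpha_min)`. Group means are subtracted first so real group differences
#' do not inflate the dispersion. Bins with zero mean have undefined
#' dispersion and are returned as `NA` (flagged untested downstream).
#'
#' @param counts integer matrix, bins x samples.
#' @param factors size factors from [size_factors()].
#' @param groups character/factor vector of group labels per sample.
#' @param alpha_min dispersion floor (default 1e-8, effectively Poisson).
#' @return numeric vector of per-bin dispersions (NA where undefined).
#' @export
estimate_dispersion <- function(counts, factors, groups, alpha_min = 1e-8) {
  y <- sweep(counts, 2L, factors, "/")
  groups <- as.character(groups)
  n <- ncol(y); g <- length(unique(groups))
  if (n - g < 1L) stop("need more samples than groups to estimate dispersion")
  ss <- 0
  for (lv in unique(groups)) {
    idx <- which(groups == lv)
    gm <- rowMeans(y[, idx, drop = FALSE])
    ss <- ss + rowSums((y[, idx, drop = FALSE] - gm)^2)
  }
  s2 <- ss / (n - g)
  m <- rowMeans(y)
  alpha <- ifelse(m > 0, pmax((s2 - m) / m^2, alpha_min), NA_real_)
  alpha
}

# Per-group NB mean MLE at fixed dispersion, vectorized over bins.
# Model: y_bs ~ NB(mean = f_s * exp(theta_b), dispersion alpha_b).
# Newton-Raphson on theta with score
#   U = sum_s [ y - m (1 + a y) / (1 + a m) ],  m = f exp(theta),
# observed curvature H = -sum_s m (1 + a y) / (1 + a m)^2 (always < 0).
# Expected Fisher information I = sum_s m / (1 + a m) gives Var(theta).
fit_nb_group <- function(y, f, alpha, max_iter = 100L, tol = 1e-12) {
  nb <- nrow(y)
  theta <- var_theta <- rep(NA_real_, nb)
  pos <- rowSums(y) > 0 & !is.na(alpha)
  if (!any(pos)) return(list(theta = theta, var_theta = var_theta, tested = pos))
  Y <- y[pos, , drop = FALSE]
  a <- alpha[pos]
  th <- log(rowSums(Y) / sum(f))
  active <- rep(TRUE, length(th))
  for (it in seq_len(max_iter)) {
    M <- exp(th) %o% f
    A <- 1 + a * Y
    B <- 1 + a * M
    U <- rowSums(Y - M * A / B)
    H <- -rowSums(M * A / B^2)
    step <- pmax(pmin(U / H, 5), -5)
    th <- th - step
    if (max(abs(step)) < tol) break
  }
  M <- exp(th) %o% f
  I <- rowSums(M / (1 + a * M))
  theta[pos] <- th
  var_theta[pos] <- 1 / I
  list(theta = theta, var_theta = var_theta, tested = pos)
}

#' Negative-binomial Wald test for differential methylation
#'
#' Per bin, two group means are fitted by maximum likelihood under a
#' negative-binomial model with log link, per-sample size-factor offsets
#' and fixed per-bin dispersion. The Wald statistic is the log2 fold
#' change (case over reference) divided by its standard error from the
#' expected Fisher information; two-sided p-values come from the normal
#' approximation. Bins where either group has all-zero counts (or the
#' dispersion is undefined) are reported untested with `NA` statistics —
#' no pseudocounts are added.
#'
#' @param counts integer matrix (bins x samples), rownames = bin ids.
#' @param factors size factors.
#' @param dispersions per-bin dispersions.
#' @param groups two-level group labels per sample.
#' @param reference label of the reference (control) level; the log2 fold
#'   change is case relative to this level.
#' @return a `dmr_table` data frame: `bin_id`, `baseMean`, `log2FC`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`, `direction`, `tested`.
#' @export
wald_dmr_test <- function(counts, factors, dispersions, groups,
                          reference = "control") {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two group levels required, got: ",
                             paste(lv, collapse = ", "))
  if (!reference %in% lv) stop("reference level '", reference, "' not in groups")
  case <- setdiff(lv, reference)
  i_case <- groups == case
  i_ref <- groups == reference
  y <- sweep(counts, 2L, factors, "/")

  fit1 <- fit_nb_group(counts[, i_case, drop = FALSE], factors[i_case], dispersions)
  fit0 <- fit_nb_group(counts[, i_ref, drop = FALSE], factors[i_ref], dispersions)
  tested <- fit1$tested & fit0$tested
  lfc <- (fit1$theta - fit0$theta) / log(2)
  se <- sqrt(fit1$var_theta + fit0$var_theta) / log(2)
  stat <- ifelse(lfc == 0, 0, lfc / se)
  p <- 2 * stats::pnorm(-abs(stat))
  lfc[!tested] <- se[!tested] <- stat[!tested] <- p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  out <- data.frame(
    bin_id = as.integer(rownames(counts) %||% seq_len(nrow(counts))),
    baseMean = rowMeans(y),
    log2FC = lfc, lfcSE = se, stat = stat, pvalue = p, padj = padj,
    direction = ifelse(is.na(lfc) | lfc == 0, "none",
                       ifelse(lfc > 0, "hyper", "hypo")),
    tested = tested, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j >= i} m p_(j) / j`, capped
#' at 1. Untested entries must be excluded before calling.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call significant DMRs at an FDR threshold
#'
#' @param table a `dmr_table`.
#' @param alpha adjusted-p threshold; bins with `padj < alpha` (strict)
#'   are called.
#' @return list with `dmrs` (called subset), `n_hyper`, `n_hypo`
#'   (zero-fold-change bins counted in neither tally).
#' @export
call_dmrs <- function(table, alpha = 0.1) {
  sig <- table[!is.na(table$padj) & table$padj < alpha, , drop = FALSE]
  list(dmrs = sig,
       n_hyper = sum(sig$log2FC > 0),
       n_hypo = sum(sig$log2FC < 0))
}

#' Map called DMRs to overlapping genes
#'
#' A gene is included when at least one called DMR overlaps its body by
#' >= 1 bp. For each gene the representative DMR is the one with the
#' lowest adjusted p-value, ties broken by chromosome order then start.
#'
#' @param dmrs called `dmr_table` rows (needs `bin_id` and `padj`).
#' @param genes gene-model data frame with `gene_id`, `chrom`, `start`,
#'   `end` (gene bodies, 0-based half-open).
#' @param grid the `bin_grid` giving DMR coordinates.
#' @return data frame, one row per gene: `gene_id`, representative
#'   `bin_id`, `chrom`, `start`, `end`, `log2FC`, `padj`.
#' @export
map_dmrs_to_genes <- function(dmrs, genes, grid) {
  empty <- data.frame(gene_id = character(), bin_id = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      log2FC = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L || is.null(genes) || nrow(genes) == 0L) return(empty)
  iv <- bin_interval_of(grid, dmrs$bin_id)
  chrom_rank <- match(iv$chrom, grid$layout$chrom)
  rows <- lapply(seq_len(nrow(genes)), function(j) {
    hit <- which(iv$chrom == genes$chrom[j] & iv$start < genes$end[j] &
                   genes$start[j] < iv$end)
    if (!length(hit)) return(NULL)
    ord <- order(dmrs$padj[hit], chrom_rank[hit], iv$start[hit])
    k <- hit[ord[1]]
    data.frame(gene_id = genes$gene_id[j], bin_id = dmrs$bin_id[k],
               chrom = iv$chrom[k], start = iv$start[k], end = iv$end[k],
               log2FC = dmrs$log2FC[k], padj = dmrs$padj[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Full differential-methylation analysis on a filtered count matrix
#'
#' Composes normalization, dispersion estimation and the Wald test for a
#' case-vs-control contrast. Normalization and dispersion are estimated
#' on exactly the samples entering the contrast.
#'
#' @param counts filtered integer matrix (bins x cfDNA samples).
#' @param sheet sample sheet (`sample_id`, `group`).
#' @param case case group label (default "OC").
#' @param control control group labels to pool (default benign + healthy).
#' @param exclude optional sample ids to drop before every estimation
#'   step.
#' @param alpha FDR threshold for [call_dmrs()].
#' @param fallback passed to [size_factors()].
#' @return list with `table` (full `dmr_table`), `called` ([call_dmrs()]
#'   output), `factors`, `dispersions`, `samples` used.
#' @export
dmr_analysis <- function(counts, sheet, case = "OC",
                         control = c("benign", "healthy"), exclude = NULL,
                         alpha = 0.1, fallback = TRUE) {
  bad <- setdiff(control, c("benign", "healthy", "control"))
  if (length(bad)) stop("unknown control subset label(s): ", paste(bad, collapse = ", "))
  grp <- sheet$group[match(colnames(counts), sheet$sample_id)]
  keep <- grp %in% c(case, control) & !(colnames(counts) %in% exclude)
  if (!is.null(exclude)) {
    missing <- setdiff(exclude, colnames(counts))
    if (length(missing)) stop("excluded sample(s) not present: ",
                              paste(missing, collapse = ", "))
  }
  sub <- counts[, keep, drop = FALSE]
  g2 <- ifelse(grp[keep] == case, case, "control")
  if (!any(g2 == case) || !any(g2 == "control")) {
    stop("case or control group empty after selection/exclusion")
  }
  f <- size_factors(sub, fallback = fallback)
  a <- estimate_dispersion(sub, f, g2)
  tab <- wald_dmr_test(sub, f, a, g2, reference = "control")
  list(table = tab, called = call_dmrs(tab, alpha), factors = f,
       dispersions = a, samples = colnames(sub))
}

#' Subgroup contrast: OC against one control arm
#'
#' Re-runs the complete analysis (normalization included) on the selected
#' samples only.
#'
#' @inheritParams dmr_analysis
#' @param control_subset `"benign"`, `"healthy"` or `"both"`.
#' @return as [dmr_analysis()].
#' @export
subgroup_dmr <- function(counts, sheet, case = "OC",
                         control_subset = c("both", "benign", "healthy"),
                         alpha = 0.1) {
  control_subset <- match.arg(control_subset)
  ctrl <- switch(control_subset, both = c("benign", "healthy"),
                 benign = "benign", healthy = "healthy")
  dmr_analysis(counts, sheet, case = case, control = ctrl, alpha = alpha)
}

#' Leave-one-sample-out robustness of the DMR gene set
#'
#' Repeats the entire analysis (size factors, dispersions, test, gene
#' mapping) with one sample excluded and intersects the resulting gene
#' set with the full-cohort gene set. Genes present in both runs are the
#' robust set; each keeps its lowest-padj representative DMR from the
#' full analysis.
#'
#' @inheritParams dmr_analysis
#' @param exclude sample id to leave out (e.g. an over-sequenced outlier).
#' @param genes gene bodies for DMR-to-gene mapping.
#' @param grid the `bin_grid`.
#' @return list with `full_genes`, `reduced_genes`, `robust_genes`
#'   (character vectors), `representatives` (full-run representative DMR
#'   per robust gene), and the two analysis objects.
#' @export
robustness_excluding <- function(counts, sheet, exclude, genes, grid,
                                 case = "OC", control = c("benign", "healthy"),
                                 alpha = 0.1) {
  full <- dmr_analysis(counts, sheet, case = case, control = control,
                       alpha = alpha)
  reduced <- dmr_analysis(counts, sheet, case = case, control = control,
                          exclude = exclude, alpha = alpha)
  gf <- map_dmrs_to_genes(full$called$dmrs, genes, grid)
  gr <- map_dmrs_to_genes(reduced$called$dmrs, genes, grid)
  robust <- intersect(gf$gene_id, gr$gene_id)
  list(full_genes = gf$gene_id, reduced_genes = gr$gene_id,
       robust_genes = robust,
       representatives = gf[gf$gene_id %in% robust, , drop = FALSE],
       full = full, reduced = reduced)
}

#' Write a DMR table as TSV with 1-based printed coordinates
#'
#' @param table a `dmr_table`.
#' @param grid the `bin_grid`.
#' @param path output path.
#' @export
write_dmr_table <- function(table, grid, path) {
  iv <- to_one_based(bin_interval_of(grid, table$bin_id))
  df <- cbind(iv[, c("bin_id", "chrom", "start_1", "stop_1")],
              table[, setdiff(names(table), "bin_id"), drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
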