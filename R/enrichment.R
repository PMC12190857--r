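#' Randomize regions preserving length and chromosome
#'
#' Each region is independently re-placed uniformly on its own chromosome
#' with its length preserved: start is uniform on `[0, chrom_len - len]`.
#' Randomized regions may overlap each other and are not masked against
#' any track unless `mask` is given, in which case placements overlapping
#' the mask are rejected and redrawn (up to 1000 attempts per region).
#'
#' @param regions interval data frame.
#' @param layout a [genome_layout()].
#' @param mask optional interval data frame of excluded territory.
#' @return interval data frame of randomized placements (same chrom and
#'   width per row as the input).
#' @export
randomize_regions <- function(regions, layout, mask = NULL) {
  if (nrow(regions) == 0L) stop("no regions to randomize")
  len <- chrom_length(layout, regions$chrom)
  w <- regions$end - regions$start
  if (any(w > len)) stop("region longer than its chromosome")
  span <- len - w + 1  # number of admissible starts
  start <- floor(stats::runif(nrow(regions)) * span)
  start <- pmin(start, span - 1)  # guard the runif(1) == 1 edge
  out <- data.frame(chrom = regions$chrom, start = start, end = start + w,
                    name = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(mask) && nrow(mask) > 0L) {
    idx <- merged_index(mask)
    for (i in seq_len(nrow(out))) {
      tries <- 0L
      while (overlap_any(out$chrom[i], out$start[i], out$end[i], idx) &&
             tries < 1000L) {
        s <- min(floor(stats::runif(1) * span[i]), span[i] - 1)
        out$start[i] <- s; out$end[i] <- s + w[i]
        tries <- tries + 1L
      }
    }
  }
  out
}

# merged, sorted per-chromosome interval index for fast overlap queries
merged_index <- function(features) {
  lapply(split(features[c("start", "end")], features$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start; e <- d$end
    if (length(s) > 1L) {
      ms <- s[1]; me <- e[1]; out_s <- numeric(0); out_e <- numeric(0)
      for (i in 2:length(s)) {
        if (s[i] <= me) me <- max(me, e[i])
        else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
      }
      list(start = c(out_s, ms), end = c(out_e, me))
    } else list(start = s, end = e)
  })
}

overlap_any <- function(chrom, qs, qe, idx) {
  vapply(seq_along(qs), function(i) {
    f <- idx[[chrom[i]]]
    if (is.null(f)) return(FALSE)
    j <- findInterval(qs[i], f$start)
    (j >= 1L && f$end[j] > qs[i]) ||
      (j < length(f$start) && f$start[j + 1L] < qe[i])
  }, logical(1))
}

#' Count query regions overlapping a feature set
#'
#' Per-region counting: a query region contributes at most 1 however many
#' feature intervals it touches; >= 1 bp shared suffices.
#'
#' @param query,features interval data frames.
#' @return integer count of overlapping query regions.
#' @export
count_region_overlaps <- function(query, features) {
  if (nrow(query) == 0L || nrow(features) == 0L) return(0L)
  idx <- merged_index(features)
  sum(overlap_any(query$chrom, query$start, query$end, idx))
}

#' Permutation enrichment Z-score for region-feature overlap
#'
#' The observed number of regions overlapping the feature set is compared
#' to its null distribution over `n` independent length- and
#' chromosome-preserving randomizations ([randomize_regions()]). The
#' Z-score uses the null sample mean and SD (denominator n - 1); |Z| > 2
#' is read as strong evidence of enrichment (positive) or depletion
#' (negative). A degenerate null (SD = 0) yields verdict `undefined`.
#'
#' @param regions interval data frame (e.g. hypermethylated DMRs).
#' @param features interval data frame of the annotation being tested.
#' @param layout a [genome_layout()].
#' @param n number of permutations (default 1000).
#' @param seed integer seed for the randomization stream.
#' @param mask optional mask passed to [randomize_regions()].
#' @return data frame with `observed`, `null_mean`, `null_sd`, `z`,
#'   `n_perm`, `seed`, `verdict`.
#' @export
permutation_z <- function(regions, features, layout, n = 1000L, seed = 1L,
                          mask = NULL) {
  if (nrow(regions) == 0L) stop("no regions to test")
  if (n < 2L) stop("need at least 2 permutations")
  obs <- count_region_overlaps(regions, features)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n), function(i) {
    count_region_overlaps(randomize_regions(regions, layout, mask = mask),
                          features)
  }, integer(1))
  m <- mean(null); s <- stats::sd(null)
  z <- if (s > 0) (obs - m) / s else NA_real_
  verdict <- if (is.na(z)) "undefined" else if (z > 2) "enriched"
             else if (z < -2) "depleted" else "none"
  data.frame(observed = obs, null_mean = m, null_sd = s, z = z,
             n_perm = as.integer(n), seed = as.integer(seed),
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Permutation enrichment across a family of feature sets
#'
#' @param regions interval data frame.
#' @param feature_sets named list of interval data frames (e.g. the CpG
#'   context partition).
#' @inheritParams permutation_z
#' @return data frame, one row per feature set, with a `feature` column.
#' @export
permutation_enrichment <- function(regions, feature_sets, layout, n = 1000L,
                                   seed = 1L, mask = NULL) {
  rows <- lapply(names(feature_sets), function(nm) {
    r <- permutation_z(regions, feature_sets[[nm]], layout, n = n,
                       seed = seed + match(nm, names(feature_sets)), mask = mask)
    cbind(feature = nm, r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1], ": need term, description, >=1 gene")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

# Storey q-values with fixed lambda; falls back to BH when the pi0
# estimate is degenerate
storey_qvalue <- function(p, padj, lambda = 0.5) {
  pi0 <- mean(p > lambda) / (1 - lambda)
  if (!is.finite(pi0) || pi0 <= 0) return(padj)
  pi0 <- min(pi0, 1)
  pmin(pi0 * padj, 1)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least `k` query genes in a term of size `K` within a
#' universe of size `N`, given `n` tested query genes:
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`. Query and terms
#' are intersected with the universe first. Adjustment is
#' Benjamini-Hochberg over the tested terms, and a Storey q-value
#' (lambda = 0.5, BH fallback) is reported alongside. A term is called
#' significant iff both `padj` and `qvalue` fall below `cutoff`.
#'
#' @param query character vector of query genes (e.g. hypermethylated).
#' @param gene_sets named list of character vectors (as from [read_gmt()]).
#' @param universe character vector of all assayable genes.
#' @param cutoff significance cutoff applied to both padj and qvalue
#'   (default 0.1).
#' @return data frame with `term`, `k`, `K`, `n`, `N`, `gene_ratio`
#'   (numeric), `gene_ratio_txt` ("k/n"), `pvalue`, `padj`, `qvalue`,
#'   `significant`, `genes` (comma-joined hits).
#' @export
hypergeom_ora <- function(query, gene_sets, universe, cutoff = 0.1) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  q <- intersect(unique(query), universe)
  n <- length(q); N <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    hit <- intersect(q, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               gene_ratio = if (n > 0) k / n else NA_real_,
               gene_ratio_txt = paste0(k, "/", n),
               pvalue = p, genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$qvalue <- storey_qvalue(out$pvalue, out$padj)
  out$significant <- out$padj < cutoff & out$qvalue < cutoff
  rownames(out) <- NULL
  out
}
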