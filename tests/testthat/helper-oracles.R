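# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately avoid the package's own code paths.

# per-bp set-intersection overlap oracle
bp_overlap_oracle <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

# definition-based BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    padj_sorted[i] <- min(m * p[o][i:m] / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_term <- colSums(draws <= K)  # treat items 1..K as the term
  mean(in_term >= k)
}

# NB log-likelihood for one group at fixed dispersion, mean = f * mu
nb_loglik <- function(mu, y, f, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = f * mu, log = TRUE))
}

# grid-search NB mean MLE oracle (coarse-to-fine refinement)
nb_grid_mle <- function(y, f, alpha) {
  lo <- max(mean(y / f) / 20, 1e-3)
  hi <- max(mean(y / f) * 20, 1)
  for (round in 1:4) {
    grid <- exp(seq(log(lo), log(hi), length.out = 200))
    ll <- vapply(grid, nb_loglik, numeric(1), y = y, f = f, alpha = alpha)
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
  }
  grid[i]
}

# brute-force double-loop region-overlap counting oracle
overlap_count_oracle <- function(query, features) {
  n <- 0L
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(features))) {
      if (query$chrom[i] == features$chrom[j] &&
          query$start[i] < features$end[j] &&
          features$start[j] < query$end[i]) { hit <- TRUE; break }
    }
    n <- n + hit
  }
  n
}

# CpG scanning oracle on a character sequence (0-based position of each C)
cpg_positions_oracle <- function(seq_chr) {
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  which(chars[-length(chars)] == "C" & chars[-1] == "G") - 1L
}

# random valid intervals on a layout
random_intervals <- function(n, layout, max_width = 500) {
  ci <- sample(nrow(layout), n, replace = TRUE)
  w <- sample(max_width, n, replace = TRUE)
  w <- pmin(w, layout$length[ci])
  s <- floor(runif(n) * (layout$length[ci] - w + 1))
  gintervals(layout$chrom[ci], s, s + w)
}

# simulate a two-group NB count matrix with known parameters
sim_nb_matrix <- function(n_bins, n1, n2, mu = 20, alpha = 0.3, lfc = 0,
                          factors = NULL) {
  n <- n1 + n2
  if (is.null(factors)) factors <- rep(1, n)
  grp <- c(rep("case", n1), rep("control", n2))
  m <- matrix(0L, n_bins, n)
  for (s in seq_len(n)) {
    mu_s <- factors[s] * mu * if (grp[s] == "case") 2^lfc else 1
    m[, s] <- stats::rnbinom(n_bins, size = 1 / alpha, mu = mu_s)
  }
  rownames(m) <- as.character(seq_len(n_bins))
  colnames(m) <- paste0(grp, seq_len(n))
  list(counts = m, groups = grp, factors = factors)
}

# engineered 10-bin cascade fixture: one designated victim bin per stage.
# layout: one chromosome, 10 bins of 300 bp. CpG counts: bin 4 has zero.
# blacklist touches only bin 1 (1 bp). PBL: bin 2 has a 21-count sample
# (removed) and bin 7 has 20/20 (retained). cfDNA totals: bin 3 sums to 9
# (removed) and bin 8 sums to exactly 10 (retained).
cascade_fixture <- function() {
  layout <- genome_layout("chrA", 3000)
  grid <- build_bin_grid(layout, 300)
  sheet <- data.frame(sample_id = c("OC1", "OC2", "HC1", "PBL1", "PBL2"),
                      group = c("OC", "OC", "healthy", "PBL", "PBL"),
                      stringsAsFactors = FALSE)
  counts <- matrix(20L, nrow = 10, ncol = 5,
                   dimnames = list(as.character(1:10), sheet$sample_id))
  counts[, c("PBL1", "PBL2")] <- 0L
  counts[2, "PBL1"] <- 21L
  counts[7, c("PBL1", "PBL2")] <- 20L
  counts[3, c("OC1", "OC2", "HC1")] <- c(3L, 3L, 3L)   # total 9 -> removed
  counts[8, c("OC1", "OC2", "HC1")] <- c(4L, 3L, 3L)   # total 10 -> retained
  cpg <- rep(5L, 10); cpg[4] <- 0L
  blacklist <- gintervals("chrA", 299, 300)  # 1 bp into bin 1 only
  list(layout = layout, grid = grid, sheet = sheet, counts = counts,
       cpg = cpg, blacklist = blacklist)
}
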