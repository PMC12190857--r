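test_that("median-of-ratios size factors behave on canonical cases", {
  set.seed(14)
  base <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, 100, 2)
  counts <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  f <- size_factors(counts)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12,
               ignore_attr = TRUE)

  same <- cbind(a = base[, 1], b = base[, 1], c = base[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3), ignore_attr = TRUE)

  # invariance to bin permutation
  m <- cbind(a = base[, 1], b = base[, 2])
  expect_equal(size_factors(m), size_factors(m[sample(100), ]))

  # no all-positive bin: error, then fallback works
  z <- m; z[cbind(1:100, rep(1:2, 50))] <- 0L
  expect_error(size_factors(z), "fallback")
  expect_no_error(size_factors(z, fallback = TRUE))
})

test_that("size factors agree with the established median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(15)
  mu <- rnbinom(300, mu = 40, size = 3) + 5
  counts <- sapply(c(0.5, 1, 1.5, 2), function(d) rpois(300, d * mu))
  colnames(counts) <- paste0("s", 1:4)
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # both are defined up to a common scale; compare normalized versions
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("dispersion estimates recover the generative truth", {
  set.seed(16)
  # Poisson data: alpha should collapse to the floor for most bins
  pois <- sim_nb_matrix(400, 58, 58, mu = 30, alpha = 1e-9)
  f <- rep(1, 116)
  a_pois <- estimate_dispersion(pois$counts, f, pois$groups)
  expect_gte(mean(a_pois < 0.02), 0.90)

  # NB alpha = 0.5 at n = 116: median estimate lands near the truth
  nb <- sim_nb_matrix(400, 40, 76, mu = 30, alpha = 0.5)
  a_nb <- estimate_dispersion(nb$counts, f, nb$groups)
  expect_gt(stats::median(a_nb), 0.35)
  expect_lt(stats::median(a_nb), 0.65)

  # constant counts within groups -> floor
  const <- matrix(5L, 10, 6)
  a_c <- estimate_dispersion(const, rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(a_c, rep(1e-8, 10))
})

test_that("NB Wald MLE matches a grid-search likelihood oracle", {
  set.seed(17)
  rel_err <- numeric(0)
  for (i in 1:50) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    alpha <- runif(1, 0.05, 0.8)
    f <- exp(rnorm(n1 + n2, 0, 0.2))
    mu <- runif(1, 5, 60)
    lfc <- runif(1, -1.5, 1.5)
    y1 <- rnbinom(n1, size = 1 / alpha, mu = f[1:n1] * mu * 2^lfc)
    y0 <- rnbinom(n2, size = 1 / alpha, mu = f[n1 + 1:n2] * mu)
    if (sum(y1) == 0 || sum(y0) == 0) next
    counts <- matrix(c(y1, y0), nrow = 1)
    res <- wald_dmr_test(counts, f, alpha,
                         c(rep("case", n1), rep("control", n2)),
                         reference = "control")
    mu1_hat <- 2^res$log2FC * nb_grid_mle(y0, f[n1 + 1:n2], alpha)
    mu1_oracle <- nb_grid_mle(y1, f[1:n1], alpha)
    mu0_oracle <- nb_grid_mle(y0, f[n1 + 1:n2], alpha)
    lfc_oracle <- log2(mu1_oracle / mu0_oracle)
    rel_err <- c(rel_err, abs(res$log2FC - lfc_oracle) / max(abs(lfc_oracle), 1))
  }
  expect_gt(length(rel_err), 40)
  expect_lt(max(rel_err), 1e-3)
})

test_that("degenerate and symmetric cases behave exactly", {
  # identical groups with identical counts: lfc 0, p 1
  counts <- matrix(rep(c(5L, 5L, 5L, 5L), 3), nrow = 3, byrow = TRUE)
  res <- wald_dmr_test(counts, rep(1, 4), rep(0.3, 3),
                       c("case", "case", "control", "control"), "control")
  expect_equal(res$log2FC, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  expect_equal(res$direction, rep("none", 3))

  # swapping case/control labels negates the fold change
  set.seed(18)
  sim <- sim_nb_matrix(20, 5, 5, mu = 25, alpha = 0.2, lfc = 1)
  a <- estimate_dispersion(sim$counts, sim$factors, sim$groups)
  r1 <- wald_dmr_test(sim$counts, sim$factors, a, sim$groups, "control")
  r2 <- wald_dmr_test(sim$counts, sim$factors, a, sim$groups, "case")
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-8)

  # all-zero group -> untested, no pseudocount invention
  z <- sim$counts; z[1, sim$groups == "case"] <- 0L
  rz <- wald_dmr_test(z, sim$factors, a, sim$groups, "control")
  expect_false(rz$tested[1])
  expect_true(is.na(rz$log2FC[1]))

  # column order invariance
  perm <- sample(10)
  rp <- wald_dmr_test(sim$counts[, perm], sim$factors[perm], a,
                      sim$groups[perm], "control")
  expect_equal(rp$log2FC, r1$log2FC, tolerance = 1e-10)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("DMR calling uses a strict padj threshold and tallies direction", {
  tab <- data.frame(bin_id = 1:4, log2FC = c(1, -1, 2, 0),
                    padj = c(0.1, 0.05, 0.01, 0.01))
  called <- call_dmrs(tab, 0.1)
  expect_equal(called$dmrs$bin_id, c(2L, 3L, 4L))  # padj == 0.1 not called
  expect_equal(called$n_hyper, 1L)
  expect_equal(called$n_hypo, 1L)                  # lfc == 0 in neither tally
  expect_equal(call_dmrs(data.frame(bin_id = 1, log2FC = 1, padj = 1))$dmrs,
               data.frame(bin_id = 1, log2FC = 1, padj = 1)[0, ])
})

test_that("DMR-to-gene mapping picks the lowest-padj representative", {
  grid <- build_bin_grid(genome_layout("chrA", 3000), 300)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrA",
                      start = c(0, 250), end = c(600, 900))
  dmrs <- data.frame(bin_id = c(1L, 2L), log2FC = c(1, 2),
                     padj = c(0.04, 0.01))
  m <- map_dmrs_to_genes(dmrs, genes, grid)
  # bin 2 [300,600) overlaps both genes and has the lower padj
  expect_equal(m$gene_id, c("g1", "g2"))
  expect_equal(m$bin_id, c(2L, 2L))
  expect_equal(m$padj, c(0.01, 0.01))
  expect_equal(nrow(map_dmrs_to_genes(dmrs[0, ], genes, grid)), 0)
})

test_that("subgroup contrast with both control arms equals the main analysis", {
  set.seed(20)
  cfg <- sim_config(n_chrom = 2L, chrom_length = 30000L, n_oc = 10L,
                    n_benign = 8L, n_healthy = 8L, n_pbl = 4L,
                    n_spikes = 8L, seed = 55L)
  g <- simulate_genome(cfg)
  grid <- build_bin_grid(g$layout, cfg$bin_width)
  sim <- simulate_counts(cfg, grid, bin_cpg_counts(grid, g$genome))
  filt <- run_filter_cascade(sim$counts, sim$sheet, grid,
                             g$annotation$blacklist,
                             bin_cpg_counts(grid, g$genome))
  main <- dmr_analysis(filt$counts, sim$sheet)
  both <- subgroup_dmr(filt$counts, sim$sheet, control_subset = "both")
  expect_equal(both$table, main$table)
  expect_error(subgroup_dmr(filt$counts, sim$sheet, control_subset = "tumor"))
  ben <- subgroup_dmr(filt$counts, sim$sheet, control_subset = "benign")
  expect_true(all(ben$samples %in%
    sim$sheet$sample_id[sim$sheet$group %in% c("OC", "benign")]))
})
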