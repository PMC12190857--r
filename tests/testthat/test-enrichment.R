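test_that("randomization preserves chromosome and length, uniformly placed", {
  layout <- genome_layout("chrA", 1000)
  reg <- gintervals("chrA", 0, 300)

  # forced placement when the region fills the chromosome
  full <- gintervals("chrA", 0, 1000)
  set.seed(1)
  r <- randomize_regions(full, layout)
  expect_equal(r$start, 0)

  expect_error(randomize_regions(gintervals("chrA", 0, 300),
                                 genome_layout("chrA", 200)), "longer")

  # seeded determinism
  set.seed(7); a <- randomize_regions(reg[rep(1, 20), ], layout)
  set.seed(7); b <- randomize_regions(reg[rep(1, 20), ], layout)
  expect_identical(a, b)

  # uniform over the 701 admissible starts (chi-square on 7 equal buckets)
  set.seed(8)
  many <- randomize_regions(reg[rep(1, 50000), ], layout)
  expect_true(all(many$start >= 0 & many$start <= 700))
  expect_equal(many$end - many$start, rep(300, 50000))
  buckets <- table(cut(many$start, breaks = seq(-0.5, 700.5, length.out = 8)))
  expect_gt(stats::chisq.test(buckets)$p.value, 0.001)
})

test_that("per-region overlap counting matches a brute-force double loop", {
  layout <- genome_layout(c("c1", "c2"), c(5000, 3000))
  q <- gintervals("c1", c(0, 100, 400), c(50, 200, 500))
  expect_equal(count_region_overlaps(q, q), 3L)               # query subset of features
  expect_equal(count_region_overlaps(q, gintervals("c2", 0, 3000)), 0L)
  # one query overlapping 3 features contributes exactly 1
  f3 <- gintervals("c1", c(0, 10, 20), c(5, 15, 25))
  expect_equal(count_region_overlaps(gintervals("c1", 0, 30), f3), 1L)

  set.seed(26)
  for (rep in 1:5) {
    qq <- random_intervals(30, layout, max_width = 300)
    ff <- random_intervals(20, layout, max_width = 300)
    expect_equal(count_region_overlaps(qq, ff), overlap_count_oracle(qq, ff))
  }
})

test_that("permutation Z handles exact and degenerate situations", {
  layout <- genome_layout("chrA", 10000)
  # feature covering the whole genome: every permutation overlaps, SD = 0
  res <- permutation_z(gintervals("chrA", 0, 100), gintervals("chrA", 0, 10000),
                       layout, n = 50, seed = 3)
  expect_equal(res$null_sd, 0)
  expect_equal(res$verdict, "undefined")
  expect_error(permutation_z(gintervals("chrA", 0, 1)[0, ],
                             gintervals("chrA", 0, 10), layout), "no regions")
  expect_error(permutation_z(gintervals("chrA", 0, 100),
                             gintervals("chrA", 0, 10), layout, n = 1),
               "at least 2")
})

test_that("permutation Z matches the closed-form uniform-placement oracle", {
  # toy genome 1 x 10 kb, feature = [0, 5000), 20 regions of 100 bp.
  # a region overlaps iff start < 5000; admissible starts 0..9900, so
  # p = 5000/9901 per region and the observed/expected counts are Binomial.
  layout <- genome_layout("chrA", 10000)
  regions <- gintervals("chrA", seq(0, 4750, length.out = 20),
                        seq(0, 4750, length.out = 20) + 100)
  feature <- gintervals("chrA", 0, 5000)
  n_perm <- 4000
  res <- permutation_z(regions, feature, layout, n = n_perm, seed = 11)
  p <- 5000 / 9901
  expect_equal(res$observed, 20L)  # all placed inside the feature
  analytic_mean <- 20 * p
  analytic_sd <- sqrt(20 * p * (1 - p))
  z_analytic <- (20 - analytic_mean) / analytic_sd
  # null-mean MC standard error = sd / sqrt(n); allow 3 of them, propagated
  expect_lt(abs(res$null_mean - analytic_mean),
            3 * analytic_sd / sqrt(n_perm))
  expect_lt(abs(res$z - z_analytic), 3 * z_analytic / sqrt(2 * (n_perm - 1)) +
              3 / sqrt(n_perm))
})

test_that("null feature placement keeps |Z| > 2 rare", {
  layout <- genome_layout("chrA", 20000)
  set.seed(27)
  features <- random_intervals(15, layout, max_width = 400)
  regions <- random_intervals(25, layout, max_width = 200)
  z <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    r <- randomize_regions(regions, layout)  # null: regions random too
    permutation_z(r, features, layout, n = 120, seed = s)$z
  }, numeric(1))
  expect_lte(mean(abs(z) > 2, na.rm = TRUE), 0.10)
})

test_that("hypergeometric ORA matches combinatorics and enumeration", {
  sets <- list(t1 = paste0("g", 1:5))
  universe <- paste0("g", 1:20)
  res <- hypergeom_ora(paste0("g", 1:5), sets, universe)
  expect_equal(res$pvalue, 1 / choose(20, 5))
  expect_equal(res$gene_ratio_txt, "5/5")

  # k = 0 and term = universe give p = 1
  res0 <- hypergeom_ora(paste0("g", 10:14), list(t = paste0("g", 1:5)),
                        paste0("g", 1:20))
  expect_equal(res0$k, 0L)
  expect_equal(res0$pvalue, 1)
  resU <- hypergeom_ora(paste0("g", 1:4), list(t = paste0("g", 1:12)),
                        paste0("g", 1:12))
  expect_equal(resU$pvalue, 1)

  # exhaustive enumeration for N <= 12
  set.seed(28)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- paste0("g", 1:N)
    term <- list(t = uni[1:K])
    q <- sample(uni, n)
    res <- hypergeom_ora(q, term, uni)
    expect_equal(res$pvalue, hyper_oracle(res$k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_ora("g1", sets, character(0)), "empty universe")
})

test_that("ORA significance requires both padj and qvalue below the cutoff", {
  set.seed(29)
  uni <- paste0("g", 1:200)
  sets <- c(list(hit = uni[1:20]),
            lapply(1:10, function(i) sample(uni, 20)))
  names(sets) <- c("hit", paste0("rand", 1:10))
  res <- hypergeom_ora(uni[1:15], sets, uni)
  expect_true(res$significant[res$term == "hit"])
  expect_true(all(res$padj[res$significant] < 0.1 &
                    res$qvalue[res$significant] < 0.1))
})

test_that("GMT parsing returns named gene sets and flags bad lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg2"), p)
  sets <- read_gmt(p)
  expect_equal(sets, list(term1 = c("g1", "g2", "g3"), term2 = "g2"))
  writeLines("term1\tdesc", p)
  expect_error(read_gmt(p), "line 1")
})
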