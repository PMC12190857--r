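test_that("CpG context derivation follows the 2 kb / 2-4 kb conventions", {
  layout <- genome_layout("chrA", 50000)
  ctx <- derive_cpg_context(gintervals("chrA", 10000, 10200), layout)
  expect_equal(ctx$shore$start, c(8000, 10200))
  expect_equal(ctx$shore$end, c(10000, 12200))
  expect_equal(ctx$shelf$start, c(6000, 12200))
  expect_equal(ctx$shelf$end, c(8000, 14200))

  # no islands -> whole genome open sea
  none <- derive_cpg_context(gintervals("chrA", 0, 1)[0, ], layout)
  expect_equal(none$open_sea[, c("start", "end")],
               data.frame(start = 0, end = 50000))

  # two islands 1 kb apart: the gap is entirely shore
  two <- derive_cpg_context(gintervals("chrA", c(10000, 11200), c(10200, 11400)),
                            layout)
  gap_hit <- classify_cpg(gintervals("chrA", 10200, 11200), two, layout)
  expect_equal(unname(gap_hit[1, ]), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("island/shore/shelf/open-sea partition the genome exactly", {
  set.seed(23)
  layout <- genome_layout(c("c1", "c2"), c(40000, 25000))
  for (rep in 1:3) {
    islands <- random_intervals(sample(2:6, 1), layout, max_width = 800)
    ctx <- derive_cpg_context(islands, layout)
    total <- sum(vapply(ctx, function(s) sum(s$end - s$start), numeric(1)))
    expect_equal(total, sum(layout$length))  # bp accounting: covers genome
    # pairwise disjoint
    sets <- names(ctx)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j && nrow(ctx[[i]]) && nrow(ctx[[j]])) {
        expect_equal(count_region_overlaps(ctx[[i]], ctx[[j]]), 0L)
      }
    }
  }
})

test_that("context derivation copes with categories that vanish entirely", {
  # island flanks swallow the whole chromosome: no open sea left
  layout <- genome_layout("chrA", 5000)
  ctx <- derive_cpg_context(gintervals("chrA", 2000, 3000), layout)
  expect_equal(nrow(ctx$open_sea), 0)
  total <- sum(vapply(ctx, function(s) sum(s$end - s$start), numeric(1)))
  expect_equal(total, 5000)
})

test_that("regions report every CpG category they touch", {
  layout <- genome_layout("chrA", 50000)
  ctx <- derive_cpg_context(gintervals("chrA", 10000, 10600), layout)
  inside <- classify_cpg(gintervals("chrA", 10100, 10400), ctx, layout)
  expect_equal(unname(inside[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  straddle <- classify_cpg(gintervals("chrA", 10500, 10800), ctx, layout)
  expect_equal(unname(straddle[1, ]), c(TRUE, TRUE, FALSE, FALSE))
  far <- classify_cpg(gintervals("chrA", 40000, 40300), ctx, layout)
  expect_equal(unname(far[1, ]), c(FALSE, FALSE, FALSE, TRUE))
})

toy_annotation <- function() {
  # one + strand gene [20000, 28000), TSS 20000, exons at both ends plus a
  # middle one; UTRs in the terminal exons
  genes <- data.frame(gene_id = "g1", chrom = "chrA", start = 20000,
                      end = 28000, strand = "+", tss = 20000)
  exons <- data.frame(gene_id = "g1", chrom = "chrA",
                      start = c(20000, 23000, 27000),
                      end = c(20500, 23400, 28000))
  structure(list(genes = genes, exons = exons,
                 utr5 = data.frame(gene_id = "g1", chrom = "chrA",
                                   start = 20000, end = 20100),
                 utr3 = data.frame(gene_id = "g1", chrom = "chrA",
                                   start = 27900, end = 28000)),
            class = "annotation_db")
}

test_that("gene-feature classification is strand-aware around the TSS", {
  layout <- genome_layout("chrA", 50000)
  ann <- toy_annotation()
  hit <- function(iv) {
    h <- classify_gene_feature(iv, ann, layout)
    colnames(h)[h[1, ]]
  }
  expect_equal(hit(gintervals("chrA", 19450, 19550)),  # 500 bp upstream
               "promoter")
  expect_setequal(hit(gintervals("chrA", 16900, 17100)),  # 3 kb upstream
                  "upstream_1to5kb")
  expect_setequal(hit(gintervals("chrA", 40000, 40300)), "intergenic")
  expect_setequal(hit(gintervals("chrA", 21000, 21200)), "intron")
  expect_setequal(hit(gintervals("chrA", 23100, 23200)), "exon")
  expect_setequal(hit(gintervals("chrA", 20050, 20200)), c("exon", "utr5"))

  # minus-strand gene: promoter sits to the right of the TSS
  ann2 <- ann
  ann2$genes$strand <- "-"; ann2$genes$tss <- 28000
  h2 <- classify_gene_feature(gintervals("chrA", 28200, 28400), ann2, layout)
  expect_true(h2[1, "promoter"])
  h3 <- classify_gene_feature(gintervals("chrA", 31000, 31500), ann2, layout)
  expect_true(h3[1, "upstream_1to5kb"])
})

test_that("repeat classification reports all touched classes or none", {
  layout <- genome_layout("chrA", 10000)
  reps <- data.frame(chrom = "chrA", start = c(1000, 1500, 4000),
                     end = c(1600, 2000, 4500),
                     name = c("LINE", "SINE", "LTR"))
  h <- classify_repeat(gintervals("chrA", c(1100, 1550, 8000),
                                  c(1200, 1650, 8300)), reps, layout)
  expect_equal(unname(h[1, ]), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(h[2, ]), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(h[3, ]), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  bad <- reps; bad$name[1] <- "Alu"
  expect_error(classify_repeat(gintervals("chrA", 0, 10), bad, layout),
               "unknown repeat class")
})

test_that("feature distributions count assignments and sum to 100", {
  h <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), ncol = 2,
              dimnames = list(NULL, c("intron", "exon")))
  d <- feature_distribution(h)
  expect_equal(d$percent[d$category == "intron"], 100)

  h2 <- matrix(c(TRUE, TRUE), 1, dimnames = list(NULL, c("island", "shore")))
  d2 <- feature_distribution(h2)
  expect_equal(d2$percent, c(50, 50))
  expect_error(feature_distribution(h[0, , drop = FALSE]), "no regions")

  # random fixture: percentages match a per-region brute-force reclassification
  set.seed(24)
  layout <- genome_layout("chrA", 30000)
  islands <- gintervals("chrA", c(5000, 15000), c(5400, 15600))
  ctx <- derive_cpg_context(islands, layout)
  q <- random_intervals(60, layout, max_width = 400)
  hits <- classify_cpg(q, ctx, layout)
  d3 <- feature_distribution(hits)
  brute <- sapply(names(ctx), function(nm) {
    sum(vapply(seq_len(nrow(q)), function(i) {
      any(vapply(seq_len(nrow(ctx[[nm]])), function(j) {
        bp_overlap_oracle(q[i, ], ctx[[nm]][j, ])
      }, logical(1)))
    }, logical(1)))
  })
  expect_equal(d3$count, unname(as.integer(brute)))
  expect_equal(sum(d3$percent), 100, tolerance = 0.1)
})

test_that("classification is invariant to track fragmentation", {
  layout <- genome_layout("chrA", 20000)
  whole <- data.frame(chrom = "chrA", start = 3000, end = 5000, name = "LINE")
  split2 <- data.frame(chrom = "chrA", start = c(3000, 4000),
                       end = c(4000, 5000), name = "LINE")
  q <- gintervals("chrA", c(3500, 4500, 10000), c(3600, 4600, 10100))
  expect_equal(classify_repeat(q, whole, layout),
               classify_repeat(q, split2, layout))
})
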