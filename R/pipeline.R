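#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates every stage end to end on a simulated cohort: genome and
#' track generation, count simulation, ddPCR QC, the four-stage filter
#' cascade, the negative-binomial Wald DMR analysis with the
#' leave-outlier-out robustness intersection, feature annotation of the
#' hypermethylated DMRs, permutation enrichment over the CpG context,
#' gene-set over-representation, and the exploratory SVD/k-means/heatmap
#' outputs. All stage outputs are written as plain-text tables under
#' `out_dir` together with a JSON manifest recording the configuration
#' hash, seeds and per-stage row counts; re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [sim_config()]; its `seed` drives every stochastic
#'   stage.
#' @param out_dir output directory (created if needed).
#' @param n_perm permutations for the enrichment stage (default 200 here;
#'   raise for production-style runs).
#' @param alpha FDR threshold for DMR calling (default 0.1).
#' @param top_k most-variable bins for the staging k-means (default 2000,
#'   capped at the number of surviving bins).
#' @return (invisibly) a list with every in-memory stage result plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, n_perm = 200L,
                         alpha = 0.1, top_k = 2000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  stage_rows <- list()

  # 1. genome + tracks
  gen <- simulate_genome(config)
  grid <- build_bin_grid(gen$layout, config$bin_width)
  cpg <- bin_cpg_counts(grid, gen$genome)
  write_chrom_sizes(gen$layout, pth("genome.chrom.sizes"))
  write_genome_fasta(gen$genome, pth("genome.fa"))
  write_bed(gen$annotation$blacklist, pth("blacklist.bed"))
  if (nrow(gen$annotation$cpg_islands)) {
    write_bed(gen$annotation$cpg_islands, pth("cpg_islands.bed"))
  }
  write_bed(gen$annotation$repeats, pth("repeats.bed"))
  utils::write.table(gen$annotation$genes, pth("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_rows$genome <- grid$n_bins

  # 2. counts + truth
  sim <- simulate_counts(config, grid, cpg, gen$annotation)
  write_count_table(sim$counts, grid, pth("counts.tsv"))
  utils::write.table(sim$sheet, pth("sample_sheet.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(bin_id = sim$truth$spike_bins,
                         true_log2FC = sim$truth$spike_lfc)
  utils::write.table(truth_df, pth("truth_spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_rows$counts <- ncol(sim$counts)

  # 3. ddPCR QC
  wells <- simulate_ddpcr_wells(config)
  utils::write.table(wells, pth("ddpcr_wells.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  qc <- qc_report(wells, out = pth("qc_report.tsv"))
  stage_rows$qc <- nrow(qc)

  # 4. filter cascade
  filt <- run_filter_cascade(sim$counts, sim$sheet, grid,
                             gen$annotation$blacklist, cpg)
  write_count_table(filt$counts, grid, pth("filtered_counts.tsv"))
  utils::write.table(filt$report, pth("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_rows$filter <- nrow(filt$counts)

  # 5. DMR analysis + robustness
  rob <- robustness_excluding(filt$counts, sim$sheet,
                              exclude = sim$truth$outlier_sample,
                              genes = gen$annotation$genes, grid = grid,
                              alpha = alpha)
  write_dmr_table(rob$full$table, grid, pth("dmr_table.tsv"))
  utils::write.table(rob$representatives, pth("robust_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_rows$dmr_called <- nrow(rob$full$called$dmrs)
  stage_rows$robust_genes <- length(rob$robust_genes)

  # 6. annotation distributions of hypermethylated DMRs
  hyper <- rob$full$called$dmrs
  hyper <- hyper[hyper$log2FC > 0, , drop = FALSE]
  ann_results <- NULL
  if (nrow(hyper) > 0) {
    regions <- bin_interval_of(grid, hyper$bin_id)
    ctx <- derive_cpg_context(gen$annotation$cpg_islands, gen$layout)
    dist_cpg <- feature_distribution(classify_cpg(regions, ctx, gen$layout))
    dist_gene <- feature_distribution(
      classify_gene_feature(regions, gen$annotation, gen$layout))
    dist_rep <- feature_distribution(
      classify_repeat(regions, gen$annotation$repeats, gen$layout))
    utils::write.table(dist_cpg, pth("distribution_cpg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dist_gene, pth("distribution_gene.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dist_rep, pth("distribution_repeat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    # 7. permutation enrichment over CpG context
    perm <- permutation_enrichment(regions, ctx, gen$layout, n = n_perm,
                                   seed = stage_seed(config$seed, "perm"))
    utils::write.table(perm, pth("permutation_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    # 8. ORA on synthetic terms (per-chromosome gene groups)
    universe <- gen$annotation$genes$gene_id
    terms <- split(universe, gen$annotation$genes$chrom)
    names(terms) <- paste0("genes_of_", names(terms))
    hyper_genes <- map_dmrs_to_genes(hyper, gen$annotation$genes, grid)$gene_id
    ora <- hypergeom_ora(hyper_genes, terms, universe)
    utils::write.table(ora, pth("ora.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ann_results <- list(cpg = dist_cpg, gene = dist_gene, repeat_ = dist_rep,
                        perm = perm, ora = ora)
    stage_rows$hyper_dmrs <- nrow(hyper)
  }

  # 9. exploration: batch check, staging k-means, heatmap
  fsub <- size_factors(filt$counts, fallback = TRUE)
  v <- vst_transform(filt$counts, fsub)
  batches <- sim$sheet$batch[match(colnames(filt$counts), sim$sheet$sample_id)]
  batch <- svd_batch_check(v, batches)
  jsonlite::write_json(list(p = as.list(batch$p),
                            var_explained = batch$var_explained),
                       pth("batch_check.json"), auto_unbox = TRUE, digits = NA)
  oc_cols <- colnames(filt$counts)[
    sim$sheet$group[match(colnames(filt$counts), sim$sheet$sample_id)] == "OC"]
  oc <- filt$counts[, oc_cols, drop = FALSE]
  k_use <- min(top_k, nrow(oc))
  top <- top_variance_bins(oc, k_use)
  km <- kmeans_cluster(oc[top, , drop = FALSE], k = 2L,
                       seed = stage_seed(config$seed, "kmeans"))
  utils::write.table(data.frame(sample_id = names(km$cluster),
                                cluster = km$cluster, km$pca),
                     pth("kmeans_clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- NULL
  if (nrow(rob$representatives) > 0) {
    reps <- rob$representatives[
      as.character(rob$representatives$bin_id) %in% rownames(filt$counts), ,
      drop = FALSE]
    if (nrow(reps) > 0) {
      hm <- heatmap_matrix(filt$counts, reps, sim$sheet)
      utils::write.table(data.frame(gene_id = rownames(hm), hm,
                                    check.names = FALSE),
                         pth("heatmap_matrix.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  # 10. manifest
  cfg_txt <- paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n")
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  cfg_file <- pth(".config.txt")
  writeLines(cfg_txt, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stage_rows = stage_rows,
    output_md5 = as.list(tools::md5sum(file.path(out_dir, sort(outputs)))))
  file.remove(cfg_file)
  names(manifest$output_md5) <- sort(outputs)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(layout = gen$layout, grid = grid, annotation = gen$annotation,
                 cpg = cpg, sim = sim, qc = qc, filtered = filt,
                 robustness = rob, annotation_results = ann_results,
                 batch_check = batch, kmeans = km, heatmap = hm,
                 manifest = manifest))
}
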