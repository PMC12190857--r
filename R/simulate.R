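#' Configuration for the synthetic cfMeDIP-seq cohort
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: negative-binomial bin counts whose baseline mean
#' grows with bin CpG content, log-normal per-sample depth factors,
#' group-specific hypermethylation spikes in the ovarian-cancer (OC)
#' group, a peripheral-blood-leukocyte (PBL) high-background bin set, and
#' one over-sequenced OC outlier sample. Cohort sizes default to 40 OC,
#' 38 benign, 38 healthy and 20 PBL samples; spike effect sizes default to
#' log2 fold changes uniform on [0.9, 1.9].
#'
#' @param n_chrom,chrom_length number and length (bp) of synthetic
#'   chromosomes.
#' @param bin_width tiling width in bp (default 300).
#' @param n_oc,n_benign,n_healthy,n_pbl group sizes.
#' @param mu_base baseline NB mean for a CpG-free bin at depth factor 1.
#' @param beta_cpg CpG-density link slope: mu0(c) = mu_base * (1 + beta_cpg * c),
#'   reflecting that MeDIP enrichment scales with methylatable CpG content.
#' @param dispersion shared NB dispersion alpha (variance = mu + alpha mu^2).
#' @param depth_log_sd SD of log depth factors (log-normal, mean 1).
#' @param n_spikes number of hypermethylated spike bins.
#' @param lfc_range range of spike log2 fold changes (uniform draw).
#' @param n_hypo_spikes hypomethylated spikes (default 0; the OC signal is
#'   overwhelmingly hypermethylation).
#' @param hypo_lfc_range magnitude range for hypomethylation spikes.
#' @param pbl_background_fraction fraction of bins given a strong PBL
#'   (hematopoietic) background signal.
#' @param pbl_background_mu NB mean of PBL samples on background bins.
#' @param pbl_depth_scale depth of the PBL panel relative to the cfDNA
#'   libraries (the background panel comes from an external, shallower
#'   dataset; the 20-read filter threshold lives on its count scale).
#' @param outlier_multiplier depth multiplier of the single over-sequenced
#'   OC sample (0 or 1 disables the outlier).
#' @param cpg_free_fraction fraction of the genome laid down without
#'   cytosines, producing zero-CpG bins for the presence filter.
#' @param islands_per_chrom,island_width CpG-island placement density and
#'   width (bp) in the synthetic genome.
#' @param genes_per_chrom gene models placed per chromosome.
#' @param repeats_per_chrom repeat elements placed per chromosome.
#' @param n_batches library-preparation batches; samples of every group
#'   are interleaved across batches.
#' @param seed integer seed; all generator stages derive their streams
#'   from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 4L, chrom_length = 150000L, bin_width = 300L,
                       n_oc = 40L, n_benign = 38L, n_healthy = 38L, n_pbl = 20L,
                       mu_base = 8, beta_cpg = 0.04, dispersion = 0.3,
                       depth_log_sd = 0.25,
                       n_spikes = 100L, lfc_range = c(0.9, 1.9),
                       n_hypo_spikes = 0L, hypo_lfc_range = c(0.9, 1.9),
                       pbl_background_fraction = 0.05, pbl_background_mu = 40,
                       pbl_depth_scale = 0.3,
                       outlier_multiplier = 10,
                       cpg_free_fraction = 0.02,
                       islands_per_chrom = 10L, island_width = 600L,
                       genes_per_chrom = 10L, repeats_per_chrom = 60L,
                       n_batches = 8L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length >= 1, cfg$bin_width >= 1,
            cfg$n_oc >= 1, cfg$n_benign >= 1, cfg$n_healthy >= 1, cfg$n_pbl >= 0,
            cfg$mu_base > 0, cfg$dispersion >= 0, cfg$n_spikes >= 0,
            all(cfg$lfc_range > 0), cfg$pbl_background_fraction >= 0,
            cfg$pbl_background_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Independent sub-seeds per generator stage, all < 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10000L +
    match(stage, c("genome", "counts", "ddpcr", "perm", "kmeans")) * 101L
}

random_dna <- function(n, p_acgt) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p_acgt),
        collapse = "")
}

place_nonoverlapping <- function(n, width, chrom_len, min_gap = 200L, max_try = 200L) {
  # greedy rejection placement; returns 0-based starts, sorted
  starts <- integer(0)
  for (i in seq_len(n)) {
    for (try in seq_len(max_try)) {
      s <- sample.int(chrom_len - width + 1L, 1L) - 1L
      if (!length(starts) ||
          all(s + width + min_gap <= starts | starts + width + min_gap <= s)) {
        starts <- c(starts, s); break
      }
    }
  }
  sort(starts)
}

#' Generate a synthetic genome with annotation tracks
#'
#' Produces a genome layout, a FASTA-ready sequence set with CpG-rich
#' islands and CpG-free deserts, and the annotation tracks the pipeline
#' consumes: an artifact blacklist, CpG islands, stranded gene models with
#' exon/UTR structure, and classified repeat elements. All intervals fall
#' within the layout; exons are contained in gene bodies and UTRs in
#' exons.
#'
#' @param config a [sim_config()].
#' @return a list with `layout`, `genome` (DNAStringSet), and `annotation`
#'   (an `annotation_db` list: `blacklist`, `cpg_islands`, `genes`,
#'   `exons`, `utr5`, `utr3`, `repeats`).
#' @export
simulate_genome <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  L <- genome_layout(paste0("chr", seq_len(config$n_chrom)),
                     rep(config$chrom_length, config$n_chrom))
  min_gene <- 2000L
  if (config$chrom_length < min_gene + 200L && config$genes_per_chrom > 0) {
    stop("chromosome too short to hold one gene model")
  }
  seqs <- character(config$n_chrom)
  islands <- blacklist <- repeats <- genes <- exons <- utr5 <- utr3 <- list()
  for (ci in seq_len(config$n_chrom)) {
    chrom <- L$chrom[ci]; len <- L$length[ci]
    base <- strsplit(random_dna(len, c(.3, .2, .2, .3)), "")[[1]]

    # CpG-free deserts: A/T/G only, so no CG can occur inside
    n_desert <- max(0L, round(config$cpg_free_fraction * len / 900) )
    if (n_desert > 0) {
      ds <- place_nonoverlapping(n_desert, 900L, len)
      for (s in ds) {
        base[(s + 1):(s + 900L)] <-
          sample(c("A", "T", "G"), 900L, replace = TRUE, prob = c(.4, .4, .2))
      }
    }

    # CpG islands: overwrite with CG-dense sequence
    isl_s <- place_nonoverlapping(config$islands_per_chrom, config$island_width, len,
                                  min_gap = 4500L)
    for (s in isl_s) {
      w <- config$island_width
      blk <- strsplit(random_dna(w, c(.15, .35, .35, .15)), "")[[1]]
      cg_at <- seq(1L, w - 1L, by = 6L)
      blk[cg_at] <- "C"; blk[cg_at + 1L] <- "G"
      base[(s + 1):(s + w)] <- blk
    }
    if (length(isl_s)) {
      islands[[ci]] <- data.frame(chrom = chrom, start = isl_s,
                                  end = isl_s + config$island_width,
                                  name = NA_character_)
    }

    # blacklist: a few artifact intervals
    bl_s <- place_nonoverlapping(2L, 500L, len, min_gap = 10000L)
    blacklist[[ci]] <- data.frame(chrom = chrom, start = bl_s, end = bl_s + 500L,
                                  name = "blacklist")

    # gene models
    if (config$genes_per_chrom > 0) {
      g_len <- sample(seq(min_gene, min(8000L, len %/% 4), by = 100L),
                      config$genes_per_chrom, replace = TRUE)
      g_s <- place_nonoverlapping(config$genes_per_chrom, max(g_len), len,
                                  min_gap = 1500L)
      ng <- length(g_s)
      g_len <- g_len[seq_len(ng)]
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      gid <- sprintf("%s_gene%d", chrom, seq_len(ng))
      genes[[ci]] <- data.frame(gene_id = gid, chrom = chrom, start = g_s,
                                end = g_s + g_len, strand = strand,
                                tss = ifelse(strand == "+", g_s, g_s + g_len),
                                stringsAsFactors = FALSE)
      ex <- lapply(seq_len(ng), function(j) {
        n_ex <- sample(3:5, 1L)
        # split the body into 2*n_ex-1 alternating exon/intron blocks
        cuts <- sort(sample(seq(g_s[j] + 150L, g_s[j] + g_len[j] - 150L, by = 50L),
                            2L * n_ex - 2L))
        bounds <- c(g_s[j], cuts, g_s[j] + g_len[j])
        ss <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
        ee <- bounds[seq(2L, length(bounds), by = 2L)]
        data.frame(gene_id = gid[j], chrom = chrom, start = ss, end = ee,
                   stringsAsFactors = FALSE)
      })
      exons[[ci]] <- do.call(rbind, ex)
      u5 <- u3 <- vector("list", ng)
      for (j in seq_len(ng)) {
        e <- ex[[j]]
        first <- e[which.min(e$start), ]; last <- e[which.max(e$end), ]
        if (strand[j] == "-") { tmp <- first; first <- last; last <- tmp }
        w5 <- min(100L, first$end - first$start)
        w3 <- min(100L, last$end - last$start)
        u5[[j]] <- if (strand[j] == "+") {
          data.frame(gene_id = gid[j], chrom = chrom, start = first$start,
                     end = first$start + w5)
        } else {
          data.frame(gene_id = gid[j], chrom = chrom, start = first$end - w5,
                     end = first$end)
        }
        u3[[j]] <- if (strand[j] == "+") {
          data.frame(gene_id = gid[j], chrom = chrom, start = last$end - w3,
                     end = last$end)
        } else {
          data.frame(gene_id = gid[j], chrom = chrom, start = last$start,
                     end = last$start + w3)
        }
      }
      utr5[[ci]] <- do.call(rbind, u5)
      utr3[[ci]] <- do.call(rbind, u3)
    }

    # repeats
    if (config$repeats_per_chrom > 0) {
      r_w <- sample(seq(200L, 1200L, by = 50L), config$repeats_per_chrom,
                    replace = TRUE)
      r_s <- place_nonoverlapping(config$repeats_per_chrom, max(r_w), len,
                                  min_gap = 100L)
      nr <- length(r_s)
      repeats[[ci]] <- data.frame(chrom = chrom, start = r_s,
                                  end = r_s + r_w[seq_len(nr)],
                                  name = sample(c("LINE", "SINE", "LTR", "other"),
                                                nr, replace = TRUE,
                                                prob = c(.3, .3, .15, .25)),
                                  stringsAsFactors = FALSE)
    }
    seqs[ci] <- paste(base, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- L$chrom
  ann <- structure(list(
    blacklist = do.call(rbind, blacklist),
    cpg_islands = if (length(islands)) do.call(rbind, islands) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character()),
    genes = do.call(rbind, genes),
    exons = do.call(rbind, exons),
    utr5 = do.call(rbind, utr5),
    utr3 = do.call(rbind, utr3),
    repeats = do.call(rbind, repeats)), class = "annotation_db")
  for (nm in names(ann)) if (!is.null(ann[[nm]])) rownames(ann[[nm]]) <- NULL
  list(layout = L, genome = genome, annotation = ann)
}

#' Simulate a bin x sample cfMeDIP count matrix with ground truth
#'
#' Counts follow `count[b, s] ~ NB(mean = d_s * mu0(c_b) * 2^(lfc_b * [s in OC]),
#' dispersion alpha)` where `d_s` is a log-normal depth factor, `c_b` the
#' bin's CpG count and `mu0(c) = mu_base * (1 + beta_cpg * c)`. A chosen
#' fraction of bins carries a strong hematopoietic background signal in
#' the PBL samples; one OC sample receives a depth multiplier, emulating a
#' flow-cell loading error. Spike identities, true effect sizes, the genes
#' they overlap, the PBL background bins and the outlier sample id are
#' returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param grid a `bin_grid` over the synthetic layout.
#' @param cpg integer per-bin CpG counts (as from [bin_cpg_counts()]).
#' @param annotation optional `annotation_db`; when given, spike bins are
#'   mapped to overlapping gene bodies for the truth record.
#' @return list with `counts` (integer matrix, rownames = bin ids),
#'   `sheet` (sample_id, group, batch) and `truth` (spike_bins, spike_lfc,
#'   hypo_bins, pbl_bins, outlier_sample, spike_genes).
#' @export
simulate_counts <- function(config, grid, cpg, annotation = NULL) {
  set.seed(stage_seed(config$seed, "counts"))
  nb <- grid$n_bins
  if (length(cpg) != nb) stop("cpg vector length must equal number of bins")
  sheet <- data.frame(
    sample_id = c(sprintf("OC%d", seq_len(config$n_oc)),
                  sprintf("BEN%d", seq_len(config$n_benign)),
                  sprintf("HC%d", seq_len(config$n_healthy)),
                  if (config$n_pbl > 0) sprintf("PBL%d", seq_len(config$n_pbl))),
    group = c(rep("OC", config$n_oc), rep("benign", config$n_benign),
              rep("healthy", config$n_healthy),
              rep("PBL", config$n_pbl)),
    stringsAsFactors = FALSE)
  # interleave groups across library batches, as in mixed library runs
  sheet$batch <- unlist(lapply(c(config$n_oc, config$n_benign, config$n_healthy,
                                 config$n_pbl), function(n) {
    if (n == 0) integer(0) else ((seq_len(n) - 1L) %% config$n_batches) + 1L
  }))
  ns <- nrow(sheet)

  d <- stats::rlnorm(ns, meanlog = -config$depth_log_sd^2 / 2,
                     sdlog = config$depth_log_sd)
  outlier <- NA_character_
  if (config$outlier_multiplier > 1 && config$n_oc > 0) {
    # pin the outlier at multiplier x the typical depth (not x its own
    # random draw) so its library lands at ~multiplier x the cohort median
    outlier <- sprintf("OC%d", config$n_oc)
    d[match(outlier, sheet$sample_id)] <-
      config$outlier_multiplier * exp(-config$depth_log_sd^2 / 2)
  }

  # PBL background bins, then hyper/hypo spikes among the remaining
  # CpG-bearing bins
  pbl_bins <- sort(sample.int(nb, round(config$pbl_background_fraction * nb)))
  eligible <- setdiff(which(cpg > 0), pbl_bins)
  n_spk <- config$n_spikes + config$n_hypo_spikes
  if (n_spk > length(eligible)) stop("spike set larger than eligible bin set")
  spk <- if (n_spk > 0) sort(sample(eligible, n_spk)) else integer(0)
  hyper <- if (config$n_spikes > 0) sort(sample(spk, config$n_spikes)) else integer(0)
  hypo <- setdiff(spk, hyper)
  lfc <- numeric(nb)
  lfc[hyper] <- stats::runif(length(hyper), config$lfc_range[1], config$lfc_range[2])
  lfc[hypo] <- -stats::runif(length(hypo), config$hypo_lfc_range[1],
                             config$hypo_lfc_range[2])

  mu0 <- config$mu_base * (1 + config$beta_cpg * cpg)
  is_oc <- sheet$group == "OC"
  is_pbl <- sheet$group == "PBL"
  counts <- matrix(0L, nrow = nb, ncol = ns,
                   dimnames = list(as.character(seq_len(nb)), sheet$sample_id))
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (s in seq_len(ns)) {
    mu <- d[s] * mu0
    if (is_oc[s]) mu <- mu * 2^lfc
    if (is_pbl[s]) {
      mu <- mu * config$pbl_depth_scale
      mu[pbl_bins] <- d[s] * config$pbl_background_mu
    }
    counts[, s] <- if (is.finite(size)) stats::rnbinom(nb, size = size, mu = mu)
                   else stats::rpois(nb, mu)
  }

  spike_genes <- character(0)
  if (!is.null(annotation) && length(hyper) && !is.null(annotation$genes)) {
    b <- bin_interval_of(grid, hyper)
    hit <- outer(seq_len(nrow(b)), seq_len(nrow(annotation$genes)),
                 function(i, j) b$chrom[i] == annotation$genes$chrom[j] &
                   b$start[i] < annotation$genes$end[j] &
                   annotation$genes$start[j] < b$end[i])
    spike_genes <- sort(unique(annotation$genes$gene_id[colSums(hit) > 0]))
  }

  list(counts = counts, sheet = sheet,
       truth = list(spike_bins = hyper, spike_lfc = lfc[hyper],
                    hypo_bins = hypo, pbl_bins = pbl_bins,
                    outlier_sample = outlier, depth_factors = d,
                    spike_genes = spike_genes))
}

#' Simulate ddPCR QC wells spanning pass/warn/fail regimes
#'
#' Generates technical-duplicate well records whose derived contamination
#' percentage and integrity ratio fall squarely inside a requested regime
#' (pass: contamination < 0.5% and integrity < 0.4; warn: between the
#' published bounds; fail: contamination > 2% or integrity > 0.7), plus a
#' `lowdroplet` regime whose wells fall below the 10,000
#' accepted-droplet minimum. Regimes are drawn away from the thresholds so
#' classification is unambiguous.
#'
#' @param config a [sim_config()] (only its seed is used).
#' @param n_per_regime samples per regime.
#' @param regimes subset of `c("pass", "warn", "fail", "lowdroplet")`.
#' @return well-record data frame (columns of [merge_replicates()] plus
#'   `regime`).
#' @export
simulate_ddpcr_wells <- function(config, n_per_regime = 5L,
                                 regimes = c("pass", "warn", "fail", "lowdroplet")) {
  set.seed(stage_seed(config$seed, "ddpcr"))
  rows <- list()
  ranges <- list(pass = list(cont = c(0.05, 0.40), integ = c(0.05, 0.35)),
                 warn = list(cont = c(0.60, 1.90), integ = c(0.45, 0.65)),
                 fail = list(cont = c(2.20, 5.00), integ = c(0.75, 1.20)),
                 lowdroplet = list(cont = c(0.05, 0.40), integ = c(0.05, 0.35)))
  k <- 0L
  for (rg in regimes) {
    rr <- ranges[[rg]]
    for (i in seq_len(n_per_regime)) {
      k <- k + 1L
      sid <- sprintf("S%02d_%s", k, rg)
      for (rep_id in 1:2) {
        cont <- stats::runif(1, rr$cont[1], rr$cont[2])
        integ <- stats::runif(1, rr$integ[1], rr$integ[2])
        rpp30 <- stats::runif(1, 500, 2000)
        short <- stats::runif(1, 200, 1000)
        droplets <- if (rg == "lowdroplet") sample(1000:9999, 1)
                    else sample(12000:20000, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, replicate = rep_id, regime = rg,
          pbc = cont * rpp30 / 100, rpp30 = rpp30,
          long = integ * short, short = short,
          accepted_droplets = droplets, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
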