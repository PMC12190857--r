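#' ddPCR cfDNA quality-control arithmetic
#'
#' Plasma cfDNA is screened for high-molecular-weight (leukocyte) DNA
#' contamination and fragment-integrity problems with a multiplex droplet
#' digital PCR assay before library preparation. Two derived metrics are
#' used:
#'
#' * contamination percentage = (PBC copies / RPP30 copies) x 100,
#'   comparing a lymphocyte-specific target against a total-cfDNA
#'   reference; below 0.5% is acceptable, above 2% is contaminated.
#' * integrity ratio = long-amplicon copies / short-amplicon copies;
#'   below 0.4 is acceptable, above 0.7 indicates contamination.
#'
#' Both published rules define only the pass and fail inequalities; values
#' in between (including the boundary values themselves) are flagged
#' `warn`. A well contributes only if it recorded at least 10,000 accepted
#' droplets.
#'
#' @name sample_qc
NULL

qc_flag <- function(value, pass_below, fail_above) {
  ifelse(is.na(value), "invalid",
         ifelse(value < pass_below, "pass",
                ifelse(value > fail_above, "fail", "warn")))
}

#' @param pbc,rpp30 copies/uL of the PBC (lymphocyte) and RPP30 (total
#'   cfDNA reference) assays.
#' @return `contamination_pct`: data frame with `value` (percentage) and
#'   `flag` in pass/warn/fail/invalid.
#' @rdname sample_qc
#' @examples
#' contamination_pct(1, 1000)   # 0.1%, pass
#' contamination_pct(30, 1000)  # 3%, fail
#' @export
contamination_pct <- function(pbc, rpp30) {
  value <- ifelse(rpp30 > 0, pbc / rpp30 * 100, NA_real_)
  data.frame(value = value, flag = qc_flag(value, 0.5, 2))
}

#' @param long,short copies/uL of the long and short amplicons.
#' @return `integrity_ratio`: data frame with `value` (ratio) and `flag`.
#' @rdname sample_qc
#' @export
integrity_ratio <- function(long, short) {
  value <- ifelse(short > 0, long / short, NA_real_)
  data.frame(value = value, flag = qc_flag(value, 0.4, 0.7))
}

#' @param accepted_droplets accepted droplet count of a well.
#' @return `well_admissible`: logical, TRUE iff >= 10,000 (inclusive).
#' @rdname sample_qc
#' @export
well_admissible <- function(accepted_droplets) {
  accepted_droplets >= 10000
}

#' Merge technical-replicate ddPCR wells per sample
#'
#' Wells failing the 10,000 accepted-droplet gate are discarded first;
#' copies are then averaged over the remaining wells of each sample. A
#' sample with no admissible well gets an `invalid` verdict.
#'
#' @param wells data frame with columns `sample_id`, `replicate`,
#'   `pbc`, `rpp30`, `long`, `short` (copies/uL) and `accepted_droplets`.
#' @return one row per sample: merged copies, `n_wells_used`,
#'   `contamination_pct`, `contamination_flag`, `integrity_ratio`,
#'   `integrity_flag`, `droplet_ok`.
#' @export
merge_replicates <- function(wells) {
  need <- c("sample_id", "pbc", "rpp30", "long", "short", "accepted_droplets")
  if (!all(need %in% names(wells))) {
    stop("wells must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(wells, wells$sample_id), function(w) {
    ok <- well_admissible(w$accepted_droplets)
    if (!any(ok)) {
      return(data.frame(sample_id = w$sample_id[1], n_wells_used = 0L,
                        pbc = NA_real_, rpp30 = NA_real_, long = NA_real_,
                        short = NA_real_, contamination_pct = NA_real_,
                        contamination_flag = "invalid",
                        integrity_ratio = NA_real_, integrity_flag = "invalid",
                        droplet_ok = FALSE, stringsAsFactors = FALSE))
    }
    w <- w[ok, , drop = FALSE]
    m <- vapply(w[c("pbc", "rpp30", "long", "short")], mean, numeric(1))
    cc <- contamination_pct(m[["pbc"]], m[["rpp30"]])
    ir <- integrity_ratio(m[["long"]], m[["short"]])
    data.frame(sample_id = w$sample_id[1], n_wells_used = nrow(w),
               pbc = m[["pbc"]], rpp30 = m[["rpp30"]], long = m[["long"]],
               short = m[["short"]], contamination_pct = cc$value,
               contamination_flag = cc$flag, integrity_ratio = ir$value,
               integrity_flag = ir$flag, droplet_ok = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run QC over a ddPCR well table
#'
#' Convenience wrapper: reads a wells CSV (columns as in
#' [merge_replicates()]), merges replicates, and optionally writes the
#' per-sample report as TSV.
#'
#' @param wells data frame or CSV path of well records.
#' @param out optional TSV path for the per-sample report.
#' @return the per-sample QC report data frame, invisibly when `out` is
#'   given.
#' @export
qc_report <- function(wells, out = NULL) {
  if (is.character(wells)) wells <- utils::read.csv(wells, stringsAsFactors = FALSE)
  rep <- merge_replicates(wells)
  if (!is.null(out)) {
    utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
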