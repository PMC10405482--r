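#' Per-subject leakage quantification
#'
#' Runs the full measurement chain on one subject: signal-to-concentration
#' conversion of both dynamic sequences, dual-time merging, VIF extraction
#' from the sinus mask, voxel-wise Patlak fitting over NAWM and WMH from
#' bolus arrival to the end of the slow sequence, and the mirror-subtract
#' histogram summary per tissue.
#'
#' @param subject a `synthetic_subject` or the list returned by
#'   [read_subject()] (fields `dce_fast`, `dce_slow`, `t1map`, `masks`).
#' @param protocol an [acquisition_protocol()].
#' @param bin_width histogram bin width, min^-1 (default 1e-4, i.e.
#'   0.1 x 10^-3 min^-1).
#' @param hematocrit optional blood-to-plasma correction (default off).
#' @param method signal inversion method, see [signal_to_concentration()].
#' @return one-row data frame: `ki_nawm`, `ki_wmh` (10^-3 min^-1),
#'   `vl_nawm`, `vl_wmh`, `wmh_rel_volume`, voxel counts. Tissue columns are
#'   `NA` when the tissue mask is empty.
#' @export
fit_subject <- function(subject, protocol, bin_width = 1e-4,
                        hematocrit = NULL, method = "spgr") {
  conc_fast <- signal_to_concentration(subject$dce_fast, subject$t1map,
                                       protocol, method)
  conc_slow <- signal_to_concentration(subject$dce_slow, subject$t1map,
                                       protocol, method)
  merged <- merge_dual_time(conc_fast, conc_slow)
  vif <- extract_vif(merged, subject$masks$vif, hematocrit)
  window <- c(protocol$bolus_arrival / 60, Inf)

  out <- data.frame(ki_nawm = NA_real_, vl_nawm = NA_real_,
                    ki_wmh = NA_real_, vl_wmh = NA_real_,
                    wmh_rel_volume = sum(subject$masks$wmh) /
                      prod(dim(subject$t1map)),
                    n_nawm = sum(subject$masks$nawm),
                    n_wmh = sum(subject$masks$wmh))
  tissue_mask <- subject$masks$nawm | subject$masks$wmh
  if (!any(tissue_mask)) return(out)
  kimap <- patlak_fit_map(merged, vif, tissue_mask, window)
  for (tissue in c("nawm", "wmh")) {
    m <- subject$masks[[tissue]] & kimap$valid
    if (!any(m)) next
    s <- leakage_summary(kimap$ki[m], bin_width, toupper(tissue))
    out[[paste0("ki_", tissue)]] <- 1e3 * s$mean_ki
    out[[paste0("vl_", tissue)]] <- s$v_l
  }
  out
}

#' Fit every subject of a cohort
#'
#' Accepts either the in-memory cohort from `simulate_cohort(..., out_dir =
#' NULL)` or a `cohort_manifest` / cohort directory written to disk. Appends
#' the leakage summary columns to the covariate table (`vegfa_pg_ml` is
#' renamed `vegfa` for the statistics layer).
#'
#' @param cohort in-memory cohort list, `cohort_manifest`, or directory
#'   path.
#' @param protocol an [acquisition_protocol()].
#' @param ... passed to [fit_subject()].
#' @return data frame of complete subject records, one row per subject.
#' @export
fit_cohort <- function(cohort, protocol, ...) {
  if (is.character(cohort)) cohort <- read_manifest(cohort)
  if (inherits(cohort, "cohort_manifest")) {
    base <- utils::read.csv(file.path(cohort$path, "cohort.csv"),
                            stringsAsFactors = FALSE)
    subjects <- lapply(cohort$subjects, function(e) {
      read_subject(file.path(cohort$path, e$dir))
    })
  } else {
    base <- cohort$cohort
    subjects <- cohort$subjects
  }
  fits <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    message(sprintf("fit_cohort: subject %d/%d", i, length(subjects)))
    fit_subject(subjects[[i]], protocol, ...)
  }))
  out <- cbind(base, fits)
  names(out)[names(out) == "vegfa_pg_ml"] <- "vegfa"
  out
}

#' Write the group and VEGFA association reports
#'
#' Runs [run_table1()] and [run_table2()] on a fitted cohort table and
#' writes `table1.csv`, `table1_means.csv` and `table2.csv` (plus a plain
#' text `report.txt`) to `out_dir`. When the cohort lacks a `vegfa` column
#' the VEGFA report is skipped with a warning.
#'
#' @param cohort fitted subject-record data frame.
#' @param out_dir output directory (created if missing).
#' @param group_filter group for the VEGFA analysis (default patients).
#' @return invisibly, list with the two report objects.
#' @export
write_reports <- function(cohort, out_dir, group_filter = "patient") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- run_table1(cohort)
  utils::write.csv(t1$associations, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(t1$means, file.path(out_dir, "table1_means.csv"),
                   row.names = FALSE)
  t2 <- NULL
  if ("vegfa" %in% names(cohort)) {
    t2 <- run_table2(cohort, group_filter)
    utils::write.csv(t2$associations, file.path(out_dir, "table2.csv"),
                     row.names = FALSE)
  } else {
    warning("cohort lacks a 'vegfa' column; VEGFA report skipped")
  }
  txt <- c(
    "Leakage association report",
    "coding: group control=0/patient=1, sex male=0/female=1;",
    "quartiles: linear interpolation (type 7); outlier rule: > Q3 + 1.5*IQR on VEGFA",
    "", "Group means +/- SEM:",
    utils::capture.output(print(t1$means, row.names = FALSE)),
    "", "Group associations (standardized beta):",
    utils::capture.output(print(t1$associations, row.names = FALSE))
  )
  if (!is.null(t2)) {
    txt <- c(txt, "",
             sprintf("VEGFA associations in %ss (%d outlier(s) removed):",
                     t2$group, t2$n_outliers),
             utils::capture.output(print(t2$associations, row.names = FALSE)))
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(list(table1 = t1, table2 = t2))
}
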