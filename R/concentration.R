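## Longitudinal cfDNA concentration analytics.
##
## Time points follow the study design: T1 = before treatment, T2 = day 1
## after the first chemotherapy cycle, T3 = before the second cycle, T4 =
## after two cycles, up to T14. The cfDNA ratio T2/T1 is the early response
## readout: a post-treatment spike that fails to resolve marks poor response.

TIME_POINTS <- paste0("T", 1:14)
CONFOUNDER_FLAGS <- c("infection", "bone_marrow_depression", "other_confounder")

#' Read a long-format concentration table
#'
#' Tab-separated columns `patient_id`, `time_point` (T1..T14), `ng_per_ml`,
#' and optional `flags` (semicolon-separated confounder flags).
#'
#' @param path file path.
#' @return data.frame with those columns (`flags` as character, "" if none).
#' @export
read_concentration_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("patient_id", "time_point", "ng_per_ml") %in% names(dt))) {
    stop("concentration table needs columns patient_id, time_point, ng_per_ml",
         call. = FALSE)
  }
  if (is.null(dt$flags)) dt$flags <- ""
  dt$flags[is.na(dt$flags)] <- ""
  bad <- setdiff(unique(dt$time_point), TIME_POINTS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown time point label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(dt$ng_per_ml <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  dt
}

#' One patient's concentration series
#'
#' @param patient_id patient label.
#' @param values named numeric vector (names from T1..T14, values in ng/mL,
#'   all positive).
#' @param flags character vector of confounder flags (subset of
#'   `infection`, `bone_marrow_depression`, `other_confounder`).
#' @return list of class `concentration_series`.
#' @export
concentration_series <- function(patient_id, values, flags = character(0)) {
  bad <- setdiff(names(values), TIME_POINTS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown time point label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(values <= 0) || anyNA(values)) {
    stop("concentrations must be positive and non-missing", call. = FALSE)
  }
  bad <- setdiff(flags, CONFOUNDER_FLAGS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown confounder flag(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, values = values, flags = flags),
            class = "concentration_series")
}

#' The cfDNA ratio (T2 / T1)
#'
#' Concentration on day 1 after the first chemotherapy cycle divided by the
#' pretreatment concentration. Computed even for confounder-flagged patients
#' (exclusion is a cohort-level decision); the flags are carried on the
#' result as the `flags` attribute.
#'
#' @param series a [concentration_series()] or a named numeric vector with
#'   `T1` and `T2` entries.
#' @return the ratio (numeric scalar, confounder flags as attribute).
#' @export
cfdna_ratio <- function(series) {
  if (inherits(series, "concentration_series")) {
    values <- series$values
    flags <- series$flags
  } else {
    values <- series
    flags <- character(0)
  }
  miss <- setdiff(c("T1", "T2"), names(values))
  if (length(miss) > 0L) {
    stop(sprintf("cfdna_ratio: missing time point(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (values[["T1"]] <= 0) stop("cfdna_ratio: T1 must be positive",
                                call. = FALSE)
  out <- unname(values[["T2"]] / values[["T1"]])
  attr(out, "flags") <- flags
  out
}

#' Group a cfDNA ratio at the clinical threshold of 2
#'
#' @param ratio numeric cfDNA ratio(s).
#' @param threshold grouping cutpoint (default 2; the boundary value goes to
#'   the low group).
#' @return character vector `"<= 2"` / `"> 2"` (with the given threshold).
#' @export
cfdna_ratio_group <- function(ratio, threshold = 2) {
  ifelse(ratio > threshold, sprintf("> %g", threshold),
         sprintf("<= %g", threshold))
}

#' cfDNA ratios for every patient in a long concentration table
#'
#' @param conc data.frame as from [read_concentration_table()].
#' @param exclude_confounded drop patients with any confounder flag.
#' @return data.frame `patient_id`, `ratio`, `flags`, `excluded`.
#' @export
cfdna_ratio_table <- function(conc, exclude_confounded = FALSE) {
  patients <- unique(conc$patient_id)
  rows <- lapply(patients, function(p) {
    sub <- conc[conc$patient_id == p, ]
    values <- setNames(sub$ng_per_ml, sub$time_point)
    flags <- unique(unlist(strsplit(sub$flags[nzchar(sub$flags)], ";",
                                    fixed = TRUE)))
    ratio <- if (all(c("T1", "T2") %in% names(values))) {
      unname(values[["T2"]] / values[["T1"]])
    } else NA_real_
    data.frame(patient_id = p, ratio = ratio,
               flags = paste(flags, collapse = ";"),
               excluded = length(flags) > 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (exclude_confounded) out <- out[!out$excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon test between two time points
#'
#' Two-sided Wilcoxon signed-rank on patients with both time points present;
#' incomplete patients are dropped and counted.
#'
#' @param conc long concentration data.frame.
#' @param tp_a,tp_b time point labels (e.g. `"T1"`, `"T2"`).
#' @return list with `n_pairs`, `n_dropped`, `V`, `p`.
#' @export
paired_timepoint_test <- function(conc, tp_a, tp_b) {
  patients <- unique(conc$patient_id)
  get_tp <- function(p, tp) {
    v <- conc$ng_per_ml[conc$patient_id == p & conc$time_point == tp]
    if (length(v) >= 1L) v[1] else NA_real_
  }
  a <- vapply(patients, get_tp, numeric(1), tp = tp_a)
  b <- vapply(patients, get_tp, numeric(1), tp = tp_b)
  complete <- !(is.na(a) | is.na(b))
  if (sum(complete) < 2L) {
    stop("paired_timepoint_test: need >= 2 complete pairs", call. = FALSE)
  }
  w <- wilcoxon_signed_rank(b[complete], a[complete])
  list(n_pairs = sum(complete), n_dropped = sum(!complete),
       V = w$V, p = w$p)
}

#' SCC-Ag parameter panel
#'
#' From the three serum SCC-Ag levels (pretreatment, after one cycle, after
#' two cycles) derives the comparison parameters: ratio1 = scc2/scc1,
#' ratio2 = scc3/scc1, diff1 = scc2 - scc1, diff2 = scc3 - scc1. Missing
#' levels propagate to the derived fields that need them.
#'
#' @param scc1,scc2,scc3 SCC-Ag levels in ng/mL (`NA` allowed for scc2/scc3).
#' @return list with the three levels and four derived parameters.
#' @export
scc_ag_panel <- function(scc1, scc2 = NA_real_, scc3 = NA_real_) {
  if (!is.na(scc1) && scc1 <= 0 && (!is.na(scc2) || !is.na(scc3))) {
    stop("scc_ag_panel: scc1 must be positive for the ratio parameters",
         call. = FALSE)
  }
  list(scc1 = scc1, scc2 = scc2, scc3 = scc3,
       ratio1 = scc2 / scc1, ratio2 = scc3 / scc1,
       diff1 = scc2 - scc1, diff2 = scc3 - scc1)
}
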