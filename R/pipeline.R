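## End-to-end orchestration: simulate (or load) -> filter -> motif / TSS /
## concentration features -> response labels -> ROC evaluation, with a
## reproducible JSON + markdown report.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()]; its seed is overridden by `seed`.
#' @param filter a [filter_config()].
#' @param motif_lfc,motif_alpha differential-motif gates (defaults 0.04 /
#'   0.05, strict inequalities).
#' @param tss_lfc,tss_alpha differential-TSS gates (defaults 0.5 / 0.05,
#'   closed fold-change inequalities).
#' @param n_boot bootstrap resamples for AUC confidence intervals.
#' @param seed master seed for the run.
#' @param discovery_fraction when non-NULL (e.g. 0.5), the cohort is split
#'   stratified by label into a discovery set, on which differential motif /
#'   TSS sets and the clinical classifier are learned, and a validation set
#'   on which every feature is evaluated. NULL (default) evaluates in-sample
#'   on the whole cohort with a warning, matching the single-cohort design.
#' @param out_dir optional output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            filter = filter_config(),
                            motif_lfc = 0.04, motif_alpha = 0.05,
                            tss_lfc = 0.5, tss_alpha = 0.05,
                            n_boot = 2000L, seed = 1L,
                            discovery_fraction = NULL,
                            out_dir = NULL) {
  if (!is.null(discovery_fraction)) {
    stopifnot_scalar_number(discovery_fraction, "discovery_fraction",
                            lower = 0.1, upper = 0.9)
  }
  synthetic$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, filter = filter,
                 motif_lfc = motif_lfc, motif_alpha = motif_alpha,
                 tss_lfc = tss_lfc, tss_alpha = tss_alpha,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 discovery_fraction = discovery_fraction,
                 out_dir = out_dir),
            class = "pipeline_config")
}

## Stratified deterministic split of sample ids by label.
split_cohort <- function(ids, responder, fraction, seed) {
  with_seed(seed, {
    disc <- unlist(lapply(c(TRUE, FALSE), function(g) {
      pool <- ids[responder == g]
      n_disc <- max(2L, round(length(pool) * fraction))
      n_disc <- min(n_disc, length(pool) - 2L)
      if (n_disc < 2L) {
        stop("split_cohort: arms too small for a discovery/validation split",
             call. = FALSE)
      }
      sample(pool, n_disc)
    }))
    list(discovery = disc, validation = setdiff(ids, disc))
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, applies the retention filters, computes per-sample
#' end-motif profiles and TSS scores, calls differential motifs and genes
#' between RECIST-labelled responders and non-responders, computes motif
#' ratios and cfDNA ratios, fits the clinical classifier, and evaluates
#' every feature by ROC analysis (positive class: non-responder). When the
#' differential-motif gate calls no motifs in one direction, the
#' effect-size-ranked top candidates are used as a fallback set (warning).
#' Re-running with the same configuration reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` (also written as `report.json` /
#'   `report.md` plus tables when `config$out_dir` is set): contains filter
#'   stats, motif sets and differential tables, motif/cfDNA ratios, labels,
#'   and an `auc` table with one row per feature.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$synthetic)
  ids <- cohort$labels$sample_id

  ## --- filtering -----------------------------------------------------
  filtered <- lapply(cohort$samples, filter_fragments, cfg = config$filter)
  frags <- lapply(filtered, `[[`, "retained")
  filter_stats <- lapply(filtered, `[[`, "stats")

  ## --- response labels (RECIST from the clinical table) ---------------
  labels_df <- recist_label_table(cohort$clinical)
  responder <- setNames(labels_df$responder, labels_df$patient_id)[ids]

  ## --- discovery / validation split -----------------------------------
  if (is.null(config$discovery_fraction)) {
    warning(paste("single-cohort mode: differential sets and the classifier",
                  "are learned and evaluated in-sample"), call. = FALSE)
    disc_ids <- val_ids <- ids
  } else {
    sp <- split_cohort(ids, responder, config$discovery_fraction,
                       derive_seed(config$seed, 3L))
    disc_ids <- sp$discovery
    val_ids <- sp$validation
  }

  ## --- end-motif features ----------------------------------------------
  idx <- cohort$reference$index
  profiles <- lapply(ids, function(sid) {
    extract_end_motifs(frags[[sid]], cohort$reference$genome,
                       sample_id = sid, index = idx)
  })
  names(profiles) <- ids
  diff_motifs <- differential_motifs(
    profiles[disc_ids[responder[disc_ids]]],
    profiles[disc_ids[!responder[disc_ids]]],
    lfc_threshold = config$motif_lfc, alpha = config$motif_alpha)
  inc_set <- diff_motifs$motif[diff_motifs$direction == "increased"]
  dec_set <- diff_motifs$motif[diff_motifs$direction == "decreased"]
  motif_sets_fallback <- FALSE
  if (length(inc_set) == 0L || length(dec_set) == 0L) {
    warning(paste("no significant motifs in one direction;",
                  "falling back to effect-size-ranked candidate sets"),
            call. = FALSE)
    motif_sets_fallback <- TRUE
    ord <- order(diff_motifs$log2_fold_change, decreasing = TRUE)
    if (length(inc_set) == 0L) {
      inc_set <- diff_motifs$motif[head(ord, config$synthetic$n_increased_motifs)]
    }
    if (length(dec_set) == 0L) {
      dec_set <- setdiff(diff_motifs$motif[tail(ord,
                          config$synthetic$n_decreased_motifs + length(inc_set))],
                         inc_set)
      dec_set <- tail(dec_set, config$synthetic$n_decreased_motifs)
    }
  }
  motif_ratios <- vapply(ids, function(sid) {
    motif_ratio(profiles[[sid]], inc_set, dec_set)$ratio
  }, numeric(1))

  ## --- TSS features ----------------------------------------------------
  scores <- tss_score_matrix(frags, cohort$reference$tss,
                             cohort$reference$chrom_lengths)
  diff_tss <- differential_tss(
    scores[, disc_ids[responder[disc_ids]], drop = FALSE],
    scores[, disc_ids[!responder[disc_ids]], drop = FALSE],
    lfc_threshold = config$tss_lfc, alpha = config$tss_alpha)

  ## --- concentration features ------------------------------------------
  ratios <- cfdna_ratio_table(cohort$concentration)
  cf_ratio <- setNames(ratios$ratio, ratios$patient_id)[ids]

  ## --- clinical features and classifier --------------------------------
  clin_bin <- binarize_clinical(cohort$clinical)
  rownames(clin_bin) <- cohort$clinical$patient_id
  clf <- suppressWarnings(
    fit_clinical_classifier(clin_bin[disc_ids, , drop = FALSE],
                            !responder[disc_ids]))
  clf_prob <- setNames(predict(clf, clin_bin), rownames(clin_bin))

  ## --- evaluation (positive class: non-responder) ----------------------
  pos <- !responder[val_ids]
  feature_scores <- list(
    cfdna_ratio = cf_ratio[val_ids],
    motif_ratio = motif_ratios[val_ids],
    clinical_classifier = clf_prob[val_ids],
    age = clin_bin[val_ids, "age_gt50"],
    stage = clin_bin[val_ids, "stage_ge_iib"],
    tumor_size = clin_bin[val_ids, "size_ge_4cm"],
    scc_ag = clin_bin[val_ids, "scc_ag"])
  roc <- lapply(seq_along(feature_scores), function(i) {
    roc_auc(feature_scores[[i]], pos,
            feature_name = names(feature_scores)[i],
            n_boot = config$n_boot,
            seed = derive_seed(config$seed, 10L + i))
  })
  names(roc) <- names(feature_scores)
  auc_table <- data.frame(
    feature = names(roc),
    auc = vapply(roc, `[[`, numeric(1), "auc"),
    ci_low = vapply(roc, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(roc, `[[`, numeric(1), "ci_high"),
    n_pos = vapply(roc, `[[`, numeric(1), "n_pos"),
    n_neg = vapply(roc, `[[`, numeric(1), "n_neg"),
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    seed = config$seed,
    n_samples = length(ids),
    discovery_ids = sort(disc_ids),
    validation_ids = sort(val_ids),
    filter_stats = filter_stats,
    labels = labels_df,
    motif_sets = list(increased = inc_set, decreased = dec_set,
                      fallback = motif_sets_fallback),
    differential_motifs = diff_motifs,
    motif_ratios = data.frame(sample_id = ids, motif_ratio = motif_ratios,
                              row.names = NULL, stringsAsFactors = FALSE),
    differential_tss = diff_tss,
    tss_scores = scores,
    cfdna_ratios = ratios,
    classifier = list(intercept = clf$intercept,
                      coefficients = as.list(clf$coefficients),
                      separation = clf$separation),
    auc = auc_table,
    ground_truth = cohort$ground_truth),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config, config$out_dir)
  report
}

## Serialise the report bundle; numeric JSON at full precision so identical
## runs are byte-identical.
write_report <- function(report, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_out <- config
  cfg_out$out_dir <- NULL
  jsonlite::write_json(
    lapply(unclass(cfg_out), function(x) if (is.list(x)) unclass(x) else x),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  json_report <- report[c("seed", "n_samples", "motif_sets", "cfdna_ratios",
                          "motif_ratios", "classifier", "auc")]
  json_report$differential_motif_calls <-
    as.list(table(report$differential_motifs$direction))
  json_report$differential_tss_calls <-
    as.list(table(report$differential_tss$direction))
  jsonlite::write_json(json_report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  data.table::fwrite(report$differential_motifs,
                     file.path(dir, "differential_motifs.tsv"), sep = "\t")
  data.table::fwrite(report$differential_tss,
                     file.path(dir, "differential_tss.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene_id = rownames(report$tss_scores),
                                report$tss_scores, check.names = FALSE),
                     file.path(dir, "tss_scores.tsv"), sep = "\t")
  md <- c(
    "# cfrag pipeline report", "",
    sprintf("- seed: %d", report$seed),
    sprintf("- samples: %d (%d validation)", report$n_samples,
            length(report$validation_ids)),
    sprintf("- differential motifs: %d increased / %d decreased%s",
            sum(report$differential_motifs$direction == "increased"),
            sum(report$differential_motifs$direction == "decreased"),
            if (report$motif_sets$fallback) " (fallback sets used)" else ""),
    sprintf("- differential TSS genes: %d increased / %d decreased",
            sum(report$differential_tss$direction == "increased"),
            sum(report$differential_tss$direction == "decreased")),
    "", "## AUC (positive class: non-responder)", "",
    "| feature | AUC | 95% CI |", "|---|---|---|",
    sprintf("| %s | %.3f | %.3f-%.3f |", report$auc$feature,
            report$auc$auc, report$auc$ci_low, report$auc$ci_high))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples, seed %d\n", x$n_samples, x$seed))
  print(x$auc, row.names = FALSE)
  invisible(x)
}
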