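## Tumour response labelling (single-lesion RECIST abridgement) and the
## immunohistochemistry expression score.
##
## The RECIST variant implemented is the study's own restatement for a
## single measurable lesion assessed between baseline and after two
## chemotherapy cycles: CR = complete resolution, PR = shrinkage of at least
## 30% of the largest diameter, PD = new lesions or growth of at least 20%
## (against baseline), SD = everything else. Responders = CR + PR. New
## lesions dominate every size-based call.

#' RECIST-style classification of one tumour measurement
#'
#' @param initial_diameter baseline largest diameter (cm, > 0).
#' @param post_diameter diameter after two cycles (cm, >= 0).
#' @param new_lesions logical; new measurable lesions appeared.
#' @return list with `category` (`CR`/`PR`/`SD`/`PD`), `responder`
#'   (CR or PR), and `reduction_pct` (negative = growth).
#' @export
recist_classify <- function(initial_diameter, post_diameter,
                            new_lesions = FALSE) {
  stopifnot_scalar_number(initial_diameter, "initial_diameter",
                          lower = .Machine$double.eps)
  stopifnot_scalar_number(post_diameter, "post_diameter", lower = 0)
  reduction <- 100 * (initial_diameter - post_diameter) / initial_diameter
  eps <- 1e-9   # keep the >= 30% / >= 20% boundaries exact under FP rounding
  category <- if (isTRUE(new_lesions)) {
    "PD"
  } else if (post_diameter == 0) {
    "CR"
  } else if (reduction <= -20 + eps) {
    "PD"
  } else if (reduction >= 30 - eps) {
    "PR"
  } else {
    "SD"
  }
  list(category = category, responder = category %in% c("CR", "PR"),
       reduction_pct = reduction)
}

#' RECIST labels for a clinical table
#'
#' @param clinical data.frame with columns `patient_id`, `initial_diameter`,
#'   `post_cycle2_diameter`, and optional logical `new_lesions`.
#' @return data.frame `patient_id`, `category`, `responder`, `reduction_pct`.
#' @export
recist_label_table <- function(clinical) {
  nl <- clinical$new_lesions %||% rep(FALSE, nrow(clinical))
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    r <- recist_classify(clinical$initial_diameter[i],
                         clinical$post_cycle2_diameter[i], nl[i])
    data.frame(patient_id = clinical$patient_id[i], category = r$category,
               responder = r$responder, reduction_pct = r$reduction_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immunohistochemistry expression score
#'
#' Staining intensity score (0-3) multiplied by the staining area score,
#' where the area score is 0 for no staining, 1 for up to 30% stained area,
#' 2 for 30-70%, and 3 above 70%. Samples are classed `high` at a score
#' cutoff of 3 (high iff score >= 3).
#'
#' @param intensity integer staining intensity in 0..3.
#' @param area_fraction stained area fraction in \[0, 1\].
#' @return list with `intensity`, `area` (score 0-3), `score` (0-9), and
#'   `expression_class` (`"high"`/`"low"`).
#' @export
ihc_score <- function(intensity, area_fraction) {
  stopifnot_scalar_number(intensity, "intensity", lower = 0, upper = 3,
                          integerish = TRUE)
  stopifnot_scalar_number(area_fraction, "area_fraction", lower = 0, upper = 1)
  area <- if (area_fraction == 0) 0L
          else if (area_fraction <= 0.30) 1L
          else if (area_fraction <= 0.70) 2L
          else 3L
  score <- as.integer(intensity) * area
  list(intensity = as.integer(intensity), area = area, score = score,
       expression_class = if (score >= 3L) "high" else "low")
}
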