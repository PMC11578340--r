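## Discrimination analysis: ROC/AUC with bootstrap confidence intervals and
## the multiple-logistic clinical classifier. The positive class is the
## non-responder throughout (early detection of patients unlikely to
## respond); higher cfDNA ratio / motif ratio orient positive.

## Coerce labels to logical "is positive (non-responder)".
normalise_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  l <- tolower(as.character(labels))
  out <- rep(NA, length(l))
  out[l %in% c("non-responder", "nonresponder", "non_responder", "nr",
               "positive", "1", "true")] <- TRUE
  out[l %in% c("responder", "r", "negative", "0", "false")] <- FALSE
  if (anyNA(out[!is.na(labels)])) {
    stop("labels must be logical, 0/1, or responder/non-responder strings",
         call. = FALSE)
  }
  out
}

## AUC by the rank (Mann-Whitney) formulation; ties contribute 1/2.
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC analysis of a score against binary response labels
#'
#' AUC by the rank (Mann-Whitney) formulation with ties contributing 1/2,
#' a stratified-bootstrap 95% confidence interval (resampling within each
#' class, seeded), and the full ROC curve points.
#'
#' @param scores numeric scores (higher = more non-responder-like unless the
#'   scores themselves say otherwise; no orientation flipping is done here).
#' @param labels class labels; `TRUE`/`"non-responder"` is the positive class.
#' @param feature_name label carried into the result.
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 disables).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return list of class `roc_result`: `feature_name`, `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `orientation`, `curve` (data.frame with
#'   `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels, feature_name = "score", n_boot = 2000L,
                    conf = 0.95, seed = 1L) {
  positive <- normalise_labels(labels)
  keep <- !(is.na(scores) | is.na(positive))
  scores <- as.numeric(scores)[keep]
  positive <- positive[keep]
  auc <- auc_rank(scores, positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ipos <- which(positive); ineg <- which(!positive)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- c(sample(ipos, n_pos, replace = TRUE),
                sample(ineg, n_neg, replace = TRUE))
        auc_rank(scores[bi], c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
      }, numeric(1))
    })
    alpha2 <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha2, 1 - alpha2), type = 7))
  }
  ## ROC curve: sweep thresholds from +Inf down
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & positive) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !positive) / n_neg,
                numeric(1))
  structure(
    list(feature_name = feature_name, auc = auc,
         ci_low = ci[1], ci_high = ci[2], n_pos = n_pos, n_neg = n_neg,
         orientation = "higher score = non-responder",
         curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$feature_name, x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

## Ordered FIGO 2018 stage vocabulary; rank is used for the >= IIB cutpoint.
FIGO_STAGES <- c("IA1", "IA2", "IB1", "IB2", "IB3",
                 "IIA1", "IIA2", "IIB",
                 "IIIA", "IIIB", "IIIC1", "IIIC2", "IVA", "IVB")

figo_stage_rank <- function(stage) {
  r <- match(toupper(as.character(stage)), FIGO_STAGES)
  if (anyNA(r)) {
    stop(sprintf("unknown FIGO stage label(s): %s",
                 paste(unique(stage[is.na(r)]), collapse = ", ")),
         call. = FALSE)
  }
  r
}

#' Binarise clinical covariates at the study cutpoints
#'
#' Age is encoded 1 when > 50 years; FIGO stage 1 when >= IIB; initial
#' tumour size 1 when >= 4 cm; the pretreatment SCC-Ag level is carried as a
#' continuous value (a >= 5 ng/mL threshold mode is available).
#'
#' @param clinical data.frame with columns `age`, `stage`, `tumor_size_cm`,
#'   `scc1`.
#' @param scc_threshold optional; when non-NULL, SCC-Ag is binarised at this
#'   cutoff (>= threshold -> 1) instead of being carried continuously.
#' @return data.frame with columns `age_gt50`, `stage_ge_iib`,
#'   `size_ge_4cm` (0/1) and `scc_ag`.
#' @export
binarize_clinical <- function(clinical, scc_threshold = NULL) {
  needed <- c("age", "stage", "tumor_size_cm", "scc1")
  miss <- setdiff(needed, names(clinical))
  if (length(miss) > 0L) {
    stop(sprintf("binarize_clinical: missing covariate column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  na_rows <- !complete.cases(clinical[needed])
  if (any(na_rows)) {
    stop(sprintf("binarize_clinical: missing values in row(s) %s",
                 paste(which(na_rows), collapse = ", ")), call. = FALSE)
  }
  scc <- clinical$scc1
  if (!is.null(scc_threshold)) scc <- as.integer(scc >= scc_threshold)
  data.frame(
    age_gt50 = as.integer(clinical$age > 50),
    stage_ge_iib = as.integer(figo_stage_rank(clinical$stage) >=
                                match("IIB", FIGO_STAGES)),
    size_ge_4cm = as.integer(clinical$tumor_size_cm >= 4),
    scc_ag = scc)
}

#' Fit the multiple-logistic clinical classifier
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, at most 100
#' iterations) of non-responder status on the binarised clinical features.
#' Constant features are dropped with a warning. Perfect separation is
#' flagged; the fit is still returned with coefficient magnitudes capped.
#'
#' @param features numeric data.frame/matrix of predictors (rows = patients).
#' @param labels response labels (`TRUE`/`"non-responder"` positive).
#' @param coef_cap cap on |coefficient| applied when separation is detected
#'   (default 15).
#' @return list of class `clinical_classifier` with `coefficients`,
#'   `intercept`, `features`, `separation`, `fitted` (in-sample
#'   probabilities), `converged`.
#' @export
fit_clinical_classifier <- function(features, labels, coef_cap = 15) {
  y <- normalise_labels(labels)
  X <- as.data.frame(features)
  if (length(unique(y)) < 2L) {
    stop("fit_clinical_classifier: both classes must be present",
         call. = FALSE)
  }
  const <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(names(X)[const], collapse = ", ")))
    X <- X[!const]
  }
  if (ncol(X) == 0L) {
    stop("fit_clinical_classifier: no non-constant features", call. = FALSE)
  }
  dat <- cbind(X, .y = as.integer(y))
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  probs <- unname(fit$fitted.values)
  separation <- any(probs > 1 - 1e-8) || any(probs < 1e-8) ||
    any(abs(coef(fit)[-1]) > coef_cap)
  beta <- coef(fit)
  if (separation) {
    warning("possible perfect separation; coefficients capped")
    beta <- pmin(pmax(beta, -coef_cap), coef_cap)
    eta <- beta[1] + as.matrix(X) %*% beta[-1]
    probs <- as.numeric(1 / (1 + exp(-eta)))
  }
  structure(
    list(coefficients = beta[-1], intercept = unname(beta[1]),
         features = names(X), separation = separation, fitted = probs,
         converged = fit$converged),
    class = "clinical_classifier")
}

#' Predicted non-responder probabilities from a clinical classifier
#'
#' @param object a `clinical_classifier`.
#' @param newdata data.frame containing the classifier's feature columns.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.clinical_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0L) {
    stop(sprintf("predict: missing feature column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(newdata)[object$features])
  eta <- object$intercept + X %*% object$coefficients
  as.numeric(1 / (1 + exp(-eta)))
}
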