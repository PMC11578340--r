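## Promoter (TSS) coverage scores from fragment depth.
##
## The TSS score of a gene in a sample is the ratio of the mean per-base
## fragment depth in the 500 bp core window around the transcription start
## site (TSS +/- 250 bp) to the mean depth in the two 250 bp flanking windows
## (250-500 bp upstream and downstream). Depth counts whole fragment spans.
## High score = nucleosome-protected, lowly expressed promoter; low score =
## depleted, highly expressed promoter.

#' Read a TSS annotation table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `tss` (0-based position),
#' `strand`; `#`-prefixed header lines allowed. BED6 input (chrom, start,
#' end, name, score, strand) is auto-detected and collapsed to its start
#' coordinate.
#'
#' @param path annotation file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(parts) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0)))
  }
  if (all(nf >= 6L) &&
      !anyNA(suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L))))) {
    ## BED6: name field carries the gene id
    out <- data.frame(
      gene_id = vapply(parts, `[`, character(1), 4L),
      chrom = vapply(parts, `[`, character(1), 1L),
      tss = as.integer(vapply(parts, `[`, character(1), 2L)),
      strand = vapply(parts, `[`, character(1), 6L),
      stringsAsFactors = FALSE)
  } else {
    if (any(nf < 4L)) {
      stop(sprintf("read_tss_annotation: line %d has fewer than 4 fields",
                   which(nf < 4L)[1]), call. = FALSE)
    }
    out <- data.frame(
      gene_id = vapply(parts, `[`, character(1), 1L),
      chrom = vapply(parts, `[`, character(1), 2L),
      tss = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L))),
      strand = vapply(parts, `[`, character(1), 4L),
      stringsAsFactors = FALSE)
  }
  if (anyNA(out$tss)) stop("read_tss_annotation: non-integer TSS position",
                           call. = FALSE)
  out
}

#' Per-base fragment depth over a window
#'
#' Position `i` of the result counts the retained fragments whose interval
#' covers base `start + i - 1` (0-based genome coordinates, half-open
#' window). Whole fragment spans are counted.
#'
#' @param fragments fragment table.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window; `end` may not exceed the
#'   chromosome length when `chrom_length` is supplied.
#' @param chrom_length optional chromosome length for bounds checking.
#' @return integer vector of length `end - start`.
#' @export
depth_profile <- function(fragments, chrom, start, end, chrom_length = NULL) {
  if (!(start >= 0 && start < end)) {
    stop("depth_profile: require 0 <= start < end", call. = FALSE)
  }
  if (!is.null(chrom_length) && end > chrom_length) {
    stop("depth_profile: window exceeds chromosome length", call. = FALSE)
  }
  sel <- fragments$chrom == chrom
  if (!any(sel)) return(integer(end - start))
  ir <- IRanges::IRanges(start = fragments$start[sel] + 1L,
                         end = fragments$end[sel])
  cov <- IRanges::coverage(ir, width = max(end, max(IRanges::end(ir))))
  as.integer(IRanges::Views(cov, start = start + 1L, end = end)[[1]])
}

## Internal: mean depths over a set of windows using one coverage pass.
window_means <- function(cov, starts0, ends0) {
  len <- length(cov)
  ok <- starts0 >= 0 & ends0 <= len & starts0 < ends0
  out <- rep(NA_real_, length(starts0))
  if (any(ok)) {
    v <- IRanges::Views(cov, start = starts0[ok] + 1L, end = ends0[ok])
    out[ok] <- IRanges::viewMeans(v)
  }
  out
}

#' TSS scores for all annotated genes in one sample
#'
#' Core window `[tss - core_halfwidth, tss + core_halfwidth)`; flanks
#' `[tss - flank_outer, tss - flank_inner)` and
#' `[tss + flank_inner, tss + flank_outer)`. Score = core mean depth / flank
#' mean depth. Genes whose windows exceed the chromosome are flagged
#' unscorable (NA, `status = "unscorable"`); genes with zero flank depth get
#' NA score with `status = "zero_flank"`.
#'
#' @param fragments fragment table (post-filter).
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param chrom_lengths named integer vector of chromosome lengths; inferred
#'   from the fragment extent when NULL (windows are then only checked
#'   against zero on the left).
#' @param core_halfwidth,flank_inner,flank_outer window geometry in bp
#'   (defaults 250 / 250 / 500).
#' @return data.frame with `gene_id`, `core_mean_depth`, `flank_mean_depth`,
#'   `score`, `status`.
#' @export
tss_score_sample <- function(fragments, annotation, chrom_lengths = NULL,
                             core_halfwidth = 250L, flank_inner = 250L,
                             flank_outer = 500L) {
  if (flank_inner < core_halfwidth) {
    stop("tss_score_sample: flank_inner must be >= core_halfwidth",
         call. = FALSE)
  }
  out <- data.frame(gene_id = annotation$gene_id,
                    core_mean_depth = NA_real_,
                    flank_mean_depth = NA_real_,
                    score = NA_real_,
                    status = "unscorable",
                    stringsAsFactors = FALSE)
  for (ch in unique(annotation$chrom)) {
    asel <- annotation$chrom == ch
    tss <- annotation$tss[asel]
    L <- if (!is.null(chrom_lengths)) {
      if (!ch %in% names(chrom_lengths)) {
        stop(sprintf("tss_score_sample: chromosome %s absent from chrom_lengths", ch),
             call. = FALSE)
      }
      chrom_lengths[[ch]]
    } else {
      max(c(fragments$end[fragments$chrom == ch], tss + flank_outer))
    }
    fsel <- fragments$chrom == ch
    cov <- if (any(fsel)) {
      IRanges::coverage(IRanges::IRanges(start = fragments$start[fsel] + 1L,
                                         end = fragments$end[fsel]),
                        width = L)
    } else {
      IRanges::Rle(0L, L)
    }
    scorable <- tss - flank_outer >= 0 & tss + flank_outer <= L
    core <- window_means(cov, tss - core_halfwidth, tss + core_halfwidth)
    fl_up <- window_means(cov, tss - flank_outer, tss - flank_inner)
    fl_dn <- window_means(cov, tss + flank_inner, tss + flank_outer)
    flank <- (fl_up + fl_dn) / 2
    score <- ifelse(flank > 0, core / flank, NA_real_)
    status <- ifelse(!scorable, "unscorable",
                     ifelse(is.na(flank) | flank == 0, "zero_flank", "ok"))
    core[!scorable] <- NA_real_
    flank[!scorable] <- NA_real_
    score[status != "ok"] <- NA_real_
    out$core_mean_depth[asel] <- core
    out$flank_mean_depth[asel] <- flank
    out$score[asel] <- score
    out$status[asel] <- status
  }
  out
}

#' TSS score for a single gene
#'
#' Convenience wrapper over [tss_score_sample()] for one annotation row.
#'
#' @inheritParams tss_score_sample
#' @param annotation single-row data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @return one-row data.frame as in [tss_score_sample()].
#' @export
tss_score <- function(fragments, annotation, chrom_lengths = NULL,
                      core_halfwidth = 250L, flank_inner = 250L,
                      flank_outer = 500L) {
  tss_score_sample(fragments, annotation[1, , drop = FALSE], chrom_lengths,
                   core_halfwidth, flank_inner, flank_outer)
}

#' TSS score matrix over a set of samples
#'
#' @param fragment_sets named list of fragment tables (one per sample).
#' @inheritParams tss_score_sample
#' @return numeric matrix genes x samples (NA where unscorable/zero-flank).
#' @export
tss_score_matrix <- function(fragment_sets, annotation, chrom_lengths = NULL,
                             core_halfwidth = 250L, flank_inner = 250L,
                             flank_outer = 500L) {
  cols <- lapply(fragment_sets, function(fr) {
    tss_score_sample(fr, annotation, chrom_lengths, core_halfwidth,
                     flank_inner, flank_outer)$score
  })
  m <- do.call(cbind, cols)
  rownames(m) <- annotation$gene_id
  colnames(m) <- names(fragment_sets)
  m
}

#' Differential TSS-score calling between response groups
#'
#' Per gene: two-sided Mann-Whitney U on per-sample scores and the log2 fold
#' change of group means, non-responders (`scores_b`) over responders
#' (`scores_a`). Direction uses closed thresholds (`>= lfc_threshold` /
#' `<= -lfc_threshold`, unlike the strict motif gate) with `p < alpha`.
#' Genes with fewer than two defined scores in either group are excluded and
#' listed in the `excluded` attribute.
#'
#' @param scores_a,scores_b numeric matrices genes x samples (shared
#'   rownames), responders and non-responders respectively.
#' @param lfc_threshold log2 fold-change gate (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return data.frame `gene_id`, `log2_fold_change`, `p_value`, `q_value`,
#'   `direction`; excluded gene ids in `attr(, "excluded")`.
#' @export
differential_tss <- function(scores_a, scores_b, lfc_threshold = 0.5,
                             alpha = 0.05) {
  if (ncol(scores_a) < 2L || ncol(scores_b) < 2L) {
    stop("differential_tss: need >= 2 samples per group", call. = FALSE)
  }
  if (!identical(rownames(scores_a), rownames(scores_b))) {
    stop("differential_tss: score matrices must share gene rownames",
         call. = FALSE)
  }
  genes <- rownames(scores_a)
  ok_a <- rowSums(!is.na(scores_a)) >= 2L
  ok_b <- rowSums(!is.na(scores_b)) >= 2L
  usable <- ok_a & ok_b
  res <- lapply(which(usable), function(i) {
    a <- scores_a[i, ]; a <- a[!is.na(a)]
    b <- scores_b[i, ]; b <- b[!is.na(b)]
    lfc <- log2(mean(b) / mean(a))
    p <- mann_whitney_u(a, b)$p
    c(lfc = lfc, p = p)
  })
  lfc <- vapply(res, `[[`, numeric(1), "lfc")
  pvals <- vapply(res, `[[`, numeric(1), "p")
  qvals <- p.adjust(pvals, method = "BH")
  direction <- rep("none", length(lfc))
  direction[lfc >= lfc_threshold & pvals < alpha] <- "increased"
  direction[lfc <= -lfc_threshold & pvals < alpha] <- "decreased"
  out <- data.frame(gene_id = genes[usable], log2_fold_change = lfc,
                    p_value = pvals, q_value = qvals, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- genes[!usable]
  out
}

#' Intersection of a differential gene set with a reference gene list
#'
#' Exact, case-sensitive set intersection on normalised (whitespace-trimmed)
#' gene symbols, with the counts needed for a two-set Venn diagram.
#'
#' @param differential_genes character vector of called gene ids.
#' @param reference_list character vector (e.g. a drug-resistance gene list).
#' @return list with `overlap`, `n_overlap`, `n_differential_only`,
#'   `n_reference_only`.
#' @export
gene_set_overlap <- function(differential_genes, reference_list) {
  a <- unique(trimws(as.character(differential_genes)))
  b <- unique(trimws(as.character(reference_list)))
  ov <- intersect(a, b)
  list(overlap = sort(ov), n_overlap = length(ov),
       n_differential_only = length(setdiff(a, b)),
       n_reference_only = length(setdiff(b, a)))
}

#' Discriminative AUC of one gene's TSS scores
#'
#' AUC for discriminating non-responders from responders by the gene's
#' per-sample score. Because promoters can discriminate in either direction,
#' the reported AUC is `max(AUC, 1 - AUC)` together with the direction flag
#' (`"high in non-responders"` / `"low in non-responders"`).
#'
#' @param scores per-sample numeric scores for one gene.
#' @param labels parallel vector; `TRUE`/`"non-responder"` marks the positive
#'   class.
#' @return list with `auc` (oriented), `raw_auc` (non-responder-high), and
#'   `direction`.
#' @export
per_gene_auc <- function(scores, labels) {
  pos <- normalise_labels(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("per_gene_auc: need >= 2 samples in each class", call. = FALSE)
  }
  raw <- auc_rank(scores, pos)
  if (raw >= 0.5) {
    list(auc = raw, raw_auc = raw, direction = "high in non-responders")
  } else {
    list(auc = 1 - raw, raw_auc = raw, direction = "low in non-responders")
  }
}
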