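## 4-mer 5' end-motif profiling of cfDNA fragments.
##
## The end motif of a fragment is the k-mer of *reference* sequence at its 5'
## terminus: on the plus strand the bases [start, start+k) and on the minus
## strand the reverse complement of [end-k, end) (0-based half-open
## coordinates throughout). Reference bases are used instead of read bases so
## that sequencing errors do not contaminate the motif spectrum. Both 5' ends
## of every fragment are counted by default.

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all k-mers over the DNA alphabet in canonical order
#'
#' The canonical order is lexicographic over A < C < G < T and coincides with
#' the integer encoding used internally (base-4 digits, first base most
#' significant). For k = 4 this is the 256-category motif space.
#'
#' @param k motif length (default 4).
#' @return character vector of length `4^k`.
#' @export
all_motifs <- function(k = 4L) {
  stopifnot_scalar_number(k, "k", lower = 1, upper = 12, integerish = TRUE)
  k <- as.integer(k)
  idx <- 0:(4L^k - 1L)
  out <- character(length(idx))
  rem <- idx
  chars <- matrix("", nrow = length(idx), ncol = k)
  for (pos in k:1) {
    chars[, pos] <- DNA_BASES[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(chars, 1L, paste0, collapse = "")
}

## Map an ASCII sequence string to integer base codes 0..3 (A,C,G,T), NA for
## anything else (case-insensitive).
encode_bases <- function(seq_string) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut[utf8ToInt(seq_string) + 1L]
}

## k-mer integer ids (0-based) at every start position 1..(L-k+1); NA where
## the window contains a non-ACGT base.
kmer_id_track <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ids <- numeric(n)
  for (j in seq_len(k)) {
    ids <- ids * 4 + as.numeric(codes[j:(j + n - 1L)])
  }
  as.integer(ids)
}

## Lookup table: reverse-complement k-mer id for each id 0..4^k-1.
revcomp_id_table <- function(k) {
  idx <- 0:(4L^k - 1L)
  rem <- idx
  rc <- numeric(length(idx))
  ## digit at position p (from the right) becomes complement at position
  ## k-1-p from the right
  for (p in 0:(k - 1L)) {
    digit <- rem %% 4L
    rem <- rem %/% 4L
    rc <- rc + (3L - digit) * 4^(k - 1L - p)
  }
  as.integer(rc)
}

#' Precompute a k-mer index for a reference genome
#'
#' Builds per-chromosome integer k-mer tracks plus the reverse-complement
#' lookup used by [extract_end_motifs()] and the synthetic fragment
#' generator. Computing this once and passing it to repeated profile calls
#' avoids re-encoding the genome.
#'
#' @param reference a named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param k motif length.
#' @return object of class `motif_index`.
#' @export
motif_index <- function(reference, k = 4L) {
  seqs <- reference_as_character(reference)
  ids <- lapply(seqs, function(s) kmer_id_track(encode_bases(s), k))
  structure(
    list(k = as.integer(k), ids = ids,
         lengths = vapply(seqs, nchar, integer(1)),
         rc = revcomp_id_table(k)),
    class = "motif_index"
  )
}

reference_as_character <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
  } else if (is.list(reference) && !is.null(reference$genome)) {
    return(reference_as_character(reference$genome))
  } else {
    stop("reference must be a DNAStringSet or named character vector",
         call. = FALSE)
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("reference sequences must be named by chromosome", call. = FALSE)
  }
  seqs
}

#' Extract the 5' end-motif profile of a fragment set
#'
#' For each fragment the plus-strand 5' motif is the reference k-mer at
#' `[start, start+k)` and the minus-strand 5' motif is the reverse complement
#' of the reference k-mer at `[end-k, end)`. Fragments lying within `k` bases
#' of a chromosome edge are skipped and tallied; ends whose window contains a
#' non-ACGT base are skipped and tallied.
#'
#' @param fragments a fragment table (see [read_fragments()]) with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param reference named [Biostrings::DNAStringSet] or character vector.
#' @param k motif length (default 4, the 256-category space).
#' @param both_ends count both 5' ends (default) or only the plus-strand end.
#' @param sample_id label stored in the profile.
#' @param index optional precomputed [motif_index()] for `reference`.
#' @return object of class `motif_profile`: list with `sample_id`, `counts`
#'   (named integer vector over all `4^k` motifs), `frequencies`,
#'   `ends_counted`, `skipped_edge`, `skipped_ambiguous`.
#' @export
extract_end_motifs <- function(fragments, reference, k = 4L,
                               both_ends = TRUE, sample_id = "sample",
                               index = NULL) {
  if (is.null(index)) index <- motif_index(reference, k = k)
  k <- index$k
  motifs <- all_motifs(k)
  counts <- integer(length(motifs))
  skipped_edge <- 0L
  skipped_ambiguous <- 0L
  if (nrow(fragments) > 0L) {
    bad <- setdiff(unique(fragments$chrom), names(index$ids))
    if (length(bad) > 0L) {
      stop(sprintf("chromosome absent from reference: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (ch in unique(fragments$chrom)) {
      sel <- fragments$chrom == ch
      st <- fragments$start[sel]
      en <- fragments$end[sel]
      L <- index$lengths[[ch]]
      track <- index$ids[[ch]]
      in_bounds <- st >= 0L & en <= L & (st + k) <= L & (en - k) >= 0L
      skipped_edge <- skipped_edge + sum(!in_bounds)
      st <- st[in_bounds]; en <- en[in_bounds]
      plus_ids <- track[st + 1L]
      if (both_ends) {
        minus_ids <- index$rc[track[en - k + 1L] + 1L]
        ids <- c(plus_ids, minus_ids)
      } else {
        ids <- plus_ids
      }
      skipped_ambiguous <- skipped_ambiguous + sum(is.na(ids))
      ids <- ids[!is.na(ids)]
      if (length(ids) > 0L) {
        counts <- counts + tabulate(ids + 1L, nbins = length(motifs))
      }
    }
  }
  names(counts) <- motifs
  ends_counted <- sum(counts)
  freqs <- if (ends_counted > 0L) counts / ends_counted else
    setNames(rep(NA_real_, length(motifs)), motifs)
  structure(
    list(sample_id = sample_id, counts = counts, frequencies = freqs,
         ends_counted = ends_counted, k = k,
         skipped_edge = skipped_edge, skipped_ambiguous = skipped_ambiguous),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> sample %s: %d ends over %d %d-mer categories\n",
              x$sample_id, x$ends_counted, length(x$counts), x$k))
  invisible(x)
}

#' Differential end-motif calling between two response groups
#'
#' Per motif, a two-sided Mann-Whitney U test on per-sample frequencies and
#' the log2 fold change of group mean (or median) frequencies, non-responder
#' (`group_b`) over responder (`group_a`). A motif is called `increased` when
#' `log2fc > lfc_threshold` and `p < alpha` (strict inequalities), `decreased`
#' symmetrically, otherwise `none`. When a group centre is exactly zero a
#' pseudo-frequency of `0.5 / mean(ends_counted)` is added to both centres to
#' keep the fold change finite. Benjamini-Hochberg q-values are reported for
#' transparency but play no part in the direction call, matching the raw
#' p + fold-change gate.
#'
#' @param group_a list of `motif_profile` (responders).
#' @param group_b list of `motif_profile` (non-responders).
#' @param lfc_threshold log2 fold-change gate (default 0.04).
#' @param alpha significance level (default 0.05).
#' @param centre `"mean"` (default) or `"median"` group summary.
#' @return data.frame with columns `motif`, `log2_fold_change`, `p_value`,
#'   `q_value`, `direction`, one row per motif category.
#' @export
differential_motifs <- function(group_a, group_b, lfc_threshold = 0.04,
                                alpha = 0.05, centre = c("mean", "median")) {
  centre <- match.arg(centre)
  check_profile_group <- function(g, nm) {
    if (length(g) < 2L) {
      stop(sprintf("differential_motifs: %s needs >= 2 samples", nm),
           call. = FALSE)
    }
    if (any(vapply(g, function(p) p$ends_counted, numeric(1)) <= 0)) {
      stop(sprintf("differential_motifs: %s contains an empty profile", nm),
           call. = FALSE)
    }
  }
  check_profile_group(group_a, "group_a")
  check_profile_group(group_b, "group_b")
  freq_mat <- function(g) do.call(cbind, lapply(g, function(p) p$frequencies))
  fa <- freq_mat(group_a)
  fb <- freq_mat(group_b)
  motifs <- rownames(fa)
  centre_fun <- if (centre == "mean") rowMeans else
    function(m) apply(m, 1L, median)
  ca <- centre_fun(fa)
  cb <- centre_fun(fb)
  pseudo <- 0.5 / mean(c(vapply(group_a, function(p) p$ends_counted, numeric(1)),
                         vapply(group_b, function(p) p$ends_counted, numeric(1))))
  zero <- ca == 0 | cb == 0
  ca[zero] <- ca[zero] + pseudo
  cb[zero] <- cb[zero] + pseudo
  lfc <- log2(cb / ca)
  pvals <- vapply(seq_along(motifs), function(i) {
    mann_whitney_u(fa[i, ], fb[i, ])$p
  }, numeric(1))
  qvals <- p.adjust(pvals, method = "BH")
  direction <- rep("none", length(motifs))
  direction[lfc > lfc_threshold & pvals < alpha] <- "increased"
  direction[lfc < -lfc_threshold & pvals < alpha] <- "decreased"
  data.frame(motif = motifs, log2_fold_change = lfc, p_value = pvals,
             q_value = qvals, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Motif-ratio statistic of a sample
#'
#' The ratio between the accumulated frequency of the significantly increased
#' motifs and that of the significantly decreased motifs, a per-sample scalar
#' used to discriminate non-responders.
#'
#' @param profile a `motif_profile`.
#' @param increased_set,decreased_set disjoint, non-empty character vectors of
#'   motifs.
#' @return list with `sample_id`, `numerator`, `denominator`, `ratio`.
#' @export
motif_ratio <- function(profile, increased_set, decreased_set) {
  if (length(increased_set) == 0L || length(decreased_set) == 0L) {
    stop("motif_ratio: both motif sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(increased_set, decreased_set)) > 0L) {
    stop("motif_ratio: increased and decreased sets must be disjoint",
         call. = FALSE)
  }
  missing <- setdiff(c(increased_set, decreased_set), names(profile$frequencies))
  if (length(missing) > 0L) {
    stop(sprintf("motif_ratio: unknown motif(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (profile$ends_counted <= 0L) {
    stop("motif_ratio: profile has no counted ends", call. = FALSE)
  }
  num <- sum(profile$frequencies[increased_set])
  den <- sum(profile$frequencies[decreased_set])
  if (den <= 0) {
    stop("motif_ratio: denominator (decreased-set frequency) is zero",
         call. = FALSE)
  }
  list(sample_id = profile$sample_id, increased_set = increased_set,
       decreased_set = decreased_set, numerator = num, denominator = den,
       ratio = num / den)
}

#' Fraction of fragment ends starting with a given base
#'
#' Sum of the frequencies of the `4^(k-1)` motifs whose first character is
#' `base`, e.g. the C-terminal-end proportion tracked as a readout of
#' DNASE1L3 nuclease activity.
#'
#' @param profile a `motif_profile` with counted ends.
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return a number in \[0, 1\].
#' @export
terminal_base_fraction <- function(profile, base) {
  base <- match.arg(base, DNA_BASES)
  if (profile$ends_counted <= 0L) {
    stop("terminal_base_fraction: empty profile", call. = FALSE)
  }
  sel <- startsWith(names(profile$frequencies), base)
  sum(profile$frequencies[sel])
}

#' Write / read a motif profile as a tab-separated table
#'
#' 256-row table with columns `motif`, `count`, `frequency`; sample id and
#' ends counted stored on `#`-prefixed header lines.
#'
#' @param profile a `motif_profile`.
#' @param path output file path.
#' @return `write_motif_profile` returns `path` invisibly;
#'   `read_motif_profile` returns a `motif_profile`.
#' @export
write_motif_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s ends_counted=%d k=%d",
                     profile$sample_id, profile$ends_counted, profile$k), con)
  writeLines("#motif\tcount\tfrequency", con)
  freqs <- profile$frequencies
  freqs[is.na(freqs)] <- 0
  writeLines(sprintf("%s\t%d\t%.10g", names(profile$counts),
                     profile$counts, freqs), con)
  invisible(path)
}

#' @rdname write_motif_profile
#' @export
read_motif_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  sample_id <- sub(".*sample_id=(\\S+).*", "\\1", meta)
  k <- as.integer(sub(".*k=(\\d+).*", "\\1", meta))
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  motifs <- vapply(parts, `[`, character(1), 1L)
  counts <- as.integer(vapply(parts, `[`, character(1), 2L))
  expected <- all_motifs(k)
  if (!identical(sort(motifs), sort(expected))) {
    stop("read_motif_profile: motif categories do not cover the k-mer space",
         call. = FALSE)
  }
  counts <- setNames(counts, motifs)[expected]
  ends_counted <- sum(counts)
  freqs <- if (ends_counted > 0) counts / ends_counted else
    setNames(rep(NA_real_, length(counts)), expected)
  structure(
    list(sample_id = sample_id, counts = counts, frequencies = freqs,
         ends_counted = ends_counted, k = k,
         skipped_edge = NA_integer_, skipped_ambiguous = NA_integer_),
    class = "motif_profile"
  )
}
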