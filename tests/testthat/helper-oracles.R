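## Independent brute-force / enumeration oracles used across the suite.
## These deliberately avoid the package's own code paths.

BASES <- c("A", "C", "G", "T")

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

rand_genome <- function(n_chrom = 2L, L = 2000L) {
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
  seqs
}

rand_fragments <- function(n, seqs, min_len = 20L, max_len = 400L) {
  chrom <- sample(names(seqs), n, replace = TRUE)
  L <- nchar(seqs)[chrom]
  len <- sample(min_len:max_len, n, replace = TRUE)
  len <- pmin(len, L)
  start <- floor(runif(n) * (L - len + 1))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             mapq = sample(30:60, n, replace = TRUE),
             mismatches = sample(0:3, n, replace = TRUE),
             proper_pair = TRUE, duplicate = FALSE, multimapped = FALSE,
             stringsAsFactors = FALSE)
}

## Brute-force end-motif recount by string slicing, fragment by fragment.
brute_motif_counts <- function(fragments, seqs, k = 4L, both_ends = TRUE) {
  counts <- setNames(integer(length(all_motifs(k))), all_motifs(k))
  for (i in seq_len(nrow(fragments))) {
    s <- seqs[[fragments$chrom[i]]]
    st <- fragments$start[i]; en <- fragments$end[i]
    if (st < 0 || en > nchar(s) || st + k > nchar(s) || en - k < 0) next
    plus <- substr(s, st + 1, st + k)
    ends <- plus
    if (both_ends) ends <- c(ends, revcomp_str(substr(s, en - k + 1, en)))
    for (m in ends) {
      if (grepl("^[ACGT]+$", m)) counts[m] <- counts[m] + 1L
    }
  }
  counts
}

## Brute-force per-base interval membership count.
brute_depth <- function(fragments, chrom, start, end) {
  vapply(start:(end - 1L), function(p) {
    sum(fragments$chrom == chrom & fragments$start <= p & p < fragments$end)
  }, numeric(1))
}

## Exact two-sided Mann-Whitney p by enumerating all group assignments.
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2L, u_of)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

## Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign flips.
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1L, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

## AUC by enumerating all positive/negative pairs.
enum_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (x in sp) for (y in sn) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}

## Build a motif_profile with prescribed frequencies (for test fixtures).
make_profile <- function(freqs, sample_id = "s", total = 1e6L) {
  motifs <- all_motifs(4L)
  counts <- setNames(integer(256L), motifs)
  counts[names(freqs)] <- as.integer(round(freqs * total))
  rest <- total - sum(counts)
  spare <- setdiff(motifs, names(freqs))
  if (rest != 0L && length(spare) > 0L) {
    counts[spare[1]] <- counts[spare[1]] + rest
  }
  structure(list(sample_id = sample_id, counts = counts,
                 frequencies = counts / sum(counts),
                 ends_counted = sum(counts), k = 4L,
                 skipped_edge = 0L, skipped_ambiguous = 0L),
            class = "motif_profile")
}

## Small, fast synthetic configuration for structural tests.
tiny_config <- function(...) {
  args <- modifyList(
    list(seed = 1, n_chromosomes = 1L, chromosome_length = 60000L,
         n_genes = 10L, n_responders = 3L, n_nonresponders = 3L,
         fragments_per_sample = 5000L, n_expressed_genes = 3L),
    list(...))
  do.call(synthetic_config, args)
}
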