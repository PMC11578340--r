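uniform_frags <- function(depth, L = 1200L, chrom = "chr1") {
  data.frame(chrom = chrom, start = 0L, end = L, strand = "+", mapq = 60L,
             mismatches = 0L, proper_pair = TRUE, duplicate = FALSE,
             multimapped = FALSE)[rep(1L, depth), ]
}

window_frags <- function(start, end, n, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = "+",
             mapq = 60L, mismatches = 0L, proper_pair = TRUE,
             duplicate = FALSE, multimapped = FALSE)[rep(1L, n), ]
}

anno <- data.frame(gene_id = "G1", chrom = "chr1", tss = 600L, strand = "+",
                   stringsAsFactors = FALSE)

test_that("depth_profile matches brute-force interval counting", {
  ## no fragments
  expect_equal(depth_profile(uniform_frags(1)[0, ], "chr1", 0, 50),
               integer(50))
  ## single fragment [100, 200) queried on [150, 160)
  fr <- window_frags(100L, 200L, 1L)
  expect_equal(depth_profile(fr, "chr1", 150, 160), rep(1L, 10))
  ## random fixtures vs brute force
  withr::with_seed(31, {
    for (rep in 1:10) {
      seqs <- rand_genome(2, 1000)
      fr <- rand_fragments(50, seqs, min_len = 10, max_len = 300)
      ch <- sample(names(seqs), 1)
      w <- sort(sample(0:1000, 2))
      if (w[1] == w[2]) w[2] <- w[2] + 1L
      expect_equal(depth_profile(fr, ch, w[1], w[2]),
                   as.integer(brute_depth(fr, ch, w[1], w[2])))
    }
  })
  expect_error(depth_profile(fr, "chr1", -5, 10), "start")
  expect_error(depth_profile(fr, "chr1", 0, 5000, chrom_length = 1000),
               "exceeds")
})

test_that("TSS score is core mean over flank mean with exact window geometry", {
  ## uniform coverage -> score exactly 1
  sc <- tss_score(uniform_frags(3), anno, chrom_lengths = c(chr1 = 1200L))
  expect_equal(sc$score, 1)
  expect_equal(sc$status, "ok")

  ## core depth 2, flank depth 4 -> score 0.5
  fr <- rbind(window_frags(350L, 850L, 2L),     # core [350, 850)
              window_frags(100L, 350L, 4L),     # upstream flank
              window_frags(850L, 1100L, 4L))    # downstream flank
  sc <- tss_score(fr, anno, chrom_lengths = c(chr1 = 1200L))
  expect_equal(sc$core_mean_depth, 2)
  expect_equal(sc$flank_mean_depth, 4)
  expect_equal(sc$score, 0.5)

  ## invariant under uniform depth scaling
  sc3 <- tss_score(fr[rep(seq_len(nrow(fr)), 3), ], anno,
                   chrom_lengths = c(chr1 = 1200L))
  expect_equal(sc3$score, 0.5)

  ## invariant under strand flip of the annotation
  anno_m <- anno; anno_m$strand <- "-"
  expect_equal(tss_score(fr, anno_m, chrom_lengths = c(chr1 = 1200L))$score,
               0.5)

  ## window accounting: core and flanks are disjoint and 500 bp each in total
  expect_equal((600 + 250) - (600 - 250), 500)
  expect_equal(((600 - 250) - (600 - 500)) + ((600 + 500) - (600 + 250)), 500)

  ## unscorable near the chromosome edge: flagged, not thrown
  edge <- data.frame(gene_id = "G2", chrom = "chr1", tss = 300L, strand = "+")
  sc <- tss_score(uniform_frags(2), edge, chrom_lengths = c(chr1 = 1200L))
  expect_equal(sc$status, "unscorable")
  expect_true(is.na(sc$score))

  ## zero flank depth: flagged per sample
  sc <- tss_score(window_frags(400L, 700L, 2L), anno,
                  chrom_lengths = c(chr1 = 1200L))
  expect_equal(sc$status, "zero_flank")
})

test_that("differential TSS calling excludes under-observed genes", {
  withr::with_seed(13, {
    a <- matrix(rnorm(40, 1, 0.05), nrow = 4,
                dimnames = list(paste0("G", 1:4), NULL))
    b <- a + matrix(rnorm(40, 0, 0.05), nrow = 4)
  })
  ## identical groups: all none
  res <- differential_tss(a, a)
  expect_true(all(res$direction == "none"))
  expect_true(all(res$log2_fold_change == 0))

  ## a gene defined in fewer than 2 samples per group is excluded and listed
  b2 <- b; b2["G3", seq_len(9)] <- NA
  res <- differential_tss(a, b2)
  expect_false("G3" %in% res$gene_id)
  expect_equal(attr(res, "excluded"), "G3")

  expect_error(differential_tss(a[, 1, drop = FALSE], b), ">= 2 samples")
})

test_that("gene-set overlap is an exact intersection", {
  expect_equal(gene_set_overlap(c("A", "B"), c("C", "D"))$n_overlap, 0L)
  expect_equal(gene_set_overlap(c("A", "B", "C"), c("B", "C"))$overlap,
               c("B", "C"))
  ov <- gene_set_overlap(c("INPP4B", "PIK3CA", "TP53"),
                         c("PIK3CA", "INPP4B", "STK11"))
  expect_equal(ov$overlap, c("INPP4B", "PIK3CA"))
  expect_equal(ov$n_overlap, 2L)

  ## against the shipped resistance gene list
  ref_path <- system.file("extdata", "nact_resistance_genes.tsv",
                          package = "cfrag")
  ref_genes <- read.delim(ref_path, comment.char = "#", header = FALSE)$V1
  expect_length(ref_genes, 20L)
  ov <- gene_set_overlap(c("INPP4B", "UNC45A", "NOTAGENE"), ref_genes)
  expect_equal(ov$n_overlap, 2L)
})

test_that("per-gene AUC reports the better orientation with a direction flag", {
  ## perfectly separated
  r <- per_gene_auc(c(1, 2, 3, 10, 11, 12),
                    c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(r$auc, 1)
  expect_equal(r$direction, "high in non-responders")

  ## non-responders score lower: raw AUC 0, reported 1 with flipped direction
  r <- per_gene_auc(c(0.2, 0.4, 0.5, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$raw_auc, 0)
  expect_equal(r$auc, 1)
  expect_equal(r$direction, "low in non-responders")

  ## permutation null: oriented AUC has mean just above 0.5
  withr::with_seed(99, {
    aucs <- replicate(20, {
      per_gene_auc(rnorm(40), sample(rep(c(TRUE, FALSE), each = 20)))$auc
    })
  })
  expect_lt(mean(aucs), 0.65)
  expect_gte(min(aucs), 0.5)

  expect_error(per_gene_auc(1:4, rep(TRUE, 4)), "class")
})
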