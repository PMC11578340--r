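test_that("motif category space is the full 4-mer alphabet", {
  m <- all_motifs(4)
  expect_length(m, 256L)
  expect_false(any(duplicated(m)))
  expect_true(all(grepl("^[ACGT]{4}$", m)))
})

test_that("end motifs are extracted from both 5' fragment ends", {
  seqs <- c(chr1 = "ACGTACGTAC")
  fr <- data.frame(chrom = "chr1", start = 0L, end = 8L, strand = "+",
                   mapq = 60L, mismatches = 0L, proper_pair = TRUE,
                   duplicate = FALSE, multimapped = FALSE)
  p <- extract_end_motifs(fr, seqs)
  ## plus end ACGT; minus end = revcomp(ACGT) = ACGT
  expect_equal(unname(p$counts[["ACGT"]]), 2L)
  expect_equal(p$ends_counted, 2L)

  ## single-end mode counts only the plus-strand end
  p1 <- extract_end_motifs(fr, seqs, both_ends = FALSE)
  expect_equal(p1$ends_counted, 1L)

  ## empty input
  p0 <- extract_end_motifs(fr[0, ], seqs)
  expect_equal(p0$ends_counted, 0L)
  expect_true(all(p0$counts == 0L))

  ## unknown chromosome is an error naming it
  fr2 <- fr; fr2$chrom <- "chrX"
  expect_error(extract_end_motifs(fr2, seqs), "chrX")

  ## edge fragments and ambiguous bases are skipped and tallied
  seqs2 <- c(chr1 = "NNACGTACGTACGTAGGC")
  fr3 <- data.frame(chrom = "chr1",
                    start = c(0L, 16L, 4L), end = c(8L, 18L, 12L),
                    strand = "+", mapq = 60L, mismatches = 0L,
                    proper_pair = TRUE, duplicate = FALSE,
                    multimapped = FALSE)
  p3 <- extract_end_motifs(fr3, seqs2)
  expect_equal(p3$skipped_edge, 1L)       # [16,18) too close to the edge
  expect_equal(p3$skipped_ambiguous, 1L)  # plus end of [0,8) contains N
  expect_equal(p3$ends_counted, 3L)
})

test_that("extraction matches a brute-force recount on random fixtures", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      seqs <- rand_genome(2, 1500)
      fr <- rand_fragments(sample(1:1000, 1), seqs, min_len = 4)
      p <- extract_end_motifs(fr, seqs)
      expect_identical(p$counts, brute_motif_counts(fr, seqs))
    }
  })
})

test_that("profiles are invariant under reference strand flip", {
  withr::with_seed(55, {
    seqs <- rand_genome(1, 3000)
    fr <- rand_fragments(300, seqs)
  })
  p <- extract_end_motifs(fr, seqs)
  flipped <- setNames(revcomp_str(seqs[[1]]), names(seqs))
  fr2 <- fr
  L <- nchar(seqs[[1]])
  fr2$start <- L - fr$end
  fr2$end <- L - fr$start
  p2 <- extract_end_motifs(fr2, flipped)
  expect_identical(p$counts, p2$counts)
})

test_that("differential motif calling applies the fold-change and p gates", {
  p1 <- make_profile(c(AAAA = 0.01), "a1")
  p2 <- make_profile(c(AAAA = 0.012), "a2")
  res <- differential_motifs(list(p1, p2), list(p1, p2))
  expect_true(all(res$direction == "none"))
  expect_true(all(res$log2_fold_change == 0))
  expect_equal(nrow(res), 256L)

  ## 2v2 exact Mann-Whitney floor: p = 1/3, never significant at 0.05
  ga <- list(make_profile(c(CCCA = 0.001), "a1", total = 1e6),
             make_profile(c(CCCA = 0.002), "a2", total = 1e6))
  gb <- list(make_profile(c(CCCA = 0.003), "b1", total = 1e6),
             make_profile(c(CCCA = 0.004), "b2", total = 1e6))
  res <- differential_motifs(ga, gb)
  row <- res[res$motif == "CCCA", ]
  expect_equal(row$p_value, 1 / 3)
  expect_equal(row$direction, "none")
  expect_gt(row$log2_fold_change, 0.04)

  expect_error(differential_motifs(list(p1), list(p1, p2)), ">= 2")
})

test_that("motif ratio is the accumulated increased/decreased frequency ratio", {
  prof <- make_profile(c(AAAA = 0.07, AAAC = 0.06, CCCA = 0.04, CCCC = 0.06),
                       total = 1e6)
  r <- motif_ratio(prof, c("AAAA", "AAAC"), c("CCCA", "CCCC"))
  expect_equal(r$ratio, 1.3)
  expect_equal(r$numerator, 0.13)

  ## uniform profile: ratio = |increased| / |decreased|
  uni <- structure(list(sample_id = "u",
                        counts = setNames(rep(1L, 256), all_motifs(4)),
                        frequencies = setNames(rep(1 / 256, 256), all_motifs(4)),
                        ends_counted = 256L, k = 4L,
                        skipped_edge = 0L, skipped_ambiguous = 0L),
                   class = "motif_profile")
  inc <- all_motifs(4)[1:11]; dec <- all_motifs(4)[12:23]
  expect_equal(motif_ratio(uni, inc, dec)$ratio, 11 / 12)

  expect_error(motif_ratio(uni, inc, inc), "disjoint")
  zero <- make_profile(c(AAAA = 1), total = 100L)
  expect_error(motif_ratio(zero, "AAAA", "CCCC"), "denominator")
})

test_that("terminal-base fractions partition the profile", {
  uni <- make_profile(setNames(rep(1 / 256, 256), all_motifs(4)), total = 256000L)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(terminal_base_fraction(uni, b), 0.25)
  }
  only_c <- make_profile(c(CCCA = 1), total = 1000L)
  expect_equal(terminal_base_fraction(only_c, "C"), 1)
  expect_equal(terminal_base_fraction(only_c, "A"), 0)

  withr::with_seed(77, {
    seqs <- rand_genome(1, 2000)
    fr <- rand_fragments(200, seqs)
    p <- extract_end_motifs(fr, seqs)
    expect_equal(sum(vapply(c("A", "C", "G", "T"), terminal_base_fraction,
                            numeric(1), profile = p)), 1)
  })
})

test_that("motif profile tables round-trip", {
  withr::with_seed(5, {
    seqs <- rand_genome(1, 2000)
    fr <- rand_fragments(150, seqs)
  })
  p <- extract_end_motifs(fr, seqs, sample_id = "S7")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_profile(p, path)
  back <- read_motif_profile(path)
  expect_identical(back$counts, p$counts)
  expect_equal(back$sample_id, "S7")
  expect_equal(back$ends_counted, p$ends_counted)
})
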