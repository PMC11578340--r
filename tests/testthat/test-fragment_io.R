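make_frag <- function(chrom = "chr1", start = 100L, end = 300L,
                      strand = "+", mapq = 60L, mismatches = 0L,
                      proper_pair = TRUE, duplicate = FALSE,
                      multimapped = FALSE) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             mapq = mapq, mismatches = mismatches, proper_pair = proper_pair,
             duplicate = duplicate, multimapped = multimapped,
             stringsAsFactors = FALSE)
}

test_that("fragment-table dialect parses, validates, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\tstrand\tmapq\tmismatches\tproper_pair\tduplicate\tmultimapped",
               "chr1\t10\t180\t+\t60\t0\t1\t0\t0",
               "chr1\t500\t700\t-\t45\t2\t1\t0\t0",
               "chr2\t0\t167\t+\t30\t5\t1\t1\t0"), path)
  fr <- read_fragments(path)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$end - fr$start, c(170L, 200L, 167L))
  expect_true(fr$duplicate[3])

  ## start >= end is a parse error naming the line
  writeLines(c("chr1\t100\t100\t+\t60\t0\t1\t0\t0"), path)
  expect_error(read_fragments(path), "line 1.*start >= end")

  ## round trip on random records
  withr::with_seed(9, {
    seqs <- rand_genome(2, 5000)
    fr <- fragment_table(rand_fragments(100, seqs))
    fr$mapq <- sample(0:255, 100, replace = TRUE)
    fr$mismatches <- sample(0:10, 100, replace = TRUE)
    fr$duplicate <- runif(100) < 0.2
    fr$proper_pair <- runif(100) < 0.8
  })
  out <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, out)
  back <- read_fragments(out)
  expect_equal(as.data.frame(back), as.data.frame(fr))

  ## empty set serialises to a header-only file
  write_fragments(fr[0, ], out)
  expect_equal(length(readLines(out)), 1L)
  expect_equal(nrow(read_fragments(out)), 0L)

  ## tabs in chromosome names cannot be serialised
  bad <- make_frag(chrom = "chr\t1")
  expect_error(write_fragments(bad, out), "tab")
})

test_that("retention filters reproduce the study thresholds exactly", {
  frs <- rbind(
    make_frag(start = 0L, end = 167L),                       # clean
    make_frag(start = 10L, end = 300L, mapq = 29L),          # low mapq
    make_frag(start = 10L, end = 300L, mapq = 30L),          # boundary: kept
    make_frag(start = 10L, end = 300L, mismatches = 6L),     # too many NM
    make_frag(start = 10L, end = 300L, mismatches = 5L),     # boundary: kept
    make_frag(start = 0L, end = 600L),                       # insert 600: out
    make_frag(start = 0L, end = 599L),                       # insert 599: kept
    make_frag(start = 10L, end = 300L, proper_pair = FALSE),
    make_frag(start = 10L, end = 300L, duplicate = TRUE),
    make_frag(start = 10L, end = 300L, multimapped = TRUE))
  res <- filter_fragments(frs, filter_config())
  expect_equal(res$stats$input_count, 10L)
  expect_equal(res$stats$retained_count, 4L)
  expect_equal(res$stats$removed_by_rule,
               list(duplicate = 1L, multimapped = 1L, mapq = 1L,
                    mismatches = 1L, proper_pair = 1L, insert = 1L))
})

test_that("filter accounting sums exactly and charges the first failing rule", {
  ## a fragment failing several rules is charged once, in the fixed order
  fr <- make_frag(mapq = 5L, mismatches = 9L, duplicate = TRUE)
  res <- filter_fragments(fr)
  expect_equal(res$stats$removed_by_rule$duplicate, 1L)
  expect_equal(sum(unlist(res$stats$removed_by_rule)), 1L)

  withr::with_seed(21, {
    seqs <- rand_genome(1, 5000)
    fr <- rand_fragments(500, seqs, min_len = 100, max_len = 900)
    fr$mapq <- sample(0:60, 500, replace = TRUE)
    fr$mismatches <- sample(0:8, 500, replace = TRUE)
    fr$proper_pair <- runif(500) < 0.9
    fr$duplicate <- runif(500) < 0.1
    fr$multimapped <- runif(500) < 0.1
  })
  res <- filter_fragments(fr)
  expect_equal(res$stats$input_count,
               res$stats$retained_count + sum(unlist(res$stats$removed_by_rule)))

  ## monotonicity: relaxing any single threshold never loses fragments
  base <- filter_fragments(fr, filter_config())$stats$retained_count
  relaxed <- list(
    filter_config(min_mapq = 20),
    filter_config(max_mismatches = 8),
    filter_config(max_insert = 1000),
    filter_config(require_proper_pair = FALSE),
    filter_config(drop_duplicates = FALSE),
    filter_config(drop_multimapped = FALSE))
  for (cfg in relaxed) {
    expect_gte(filter_fragments(fr, cfg)$stats$retained_count, base)
  }
})

test_that("alignment dialect collapses pairs and counts orphans", {
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000")
  recs <- character(0)
  starts <- seq(100L, 1000L, by = 100L)           # 10 pairs
  for (i in seq_along(starts)) {
    p <- starts[i]
    q <- sprintf("frag%02d", i)
    recs <- c(recs,
      sprintf("%s\t99\tchr1\t%d\t60\t50M\t=\t%d\t150\t%s\t*\tNM:i:1",
              q, p, p + 100L, strrep("A", 50)),
      sprintf("%s\t147\tchr1\t%d\t60\t50M\t=\t%d\t-150\t%s\t*\tNM:i:2",
              q, p + 100L, p, strrep("A", 50)))
  }
  recs <- c(recs,
    sprintf("orphan1\t99\tchr1\t5000\t60\t50M\t=\t5100\t150\t%s\t*\tNM:i:0",
            strrep("A", 50)))
  writeLines(c(hdr, recs), sam)
  fr <- read_fragments(sam, dialect = "alignment")
  expect_equal(nrow(fr), 10L)
  expect_equal(attr(fr, "orphan_count"), 1L)
  expect_equal(fr$start, starts - 1L)          # 1-based -> 0-based
  expect_equal(fr$end - fr$start, rep(150L, 10L))
  expect_true(all(fr$proper_pair))
  expect_equal(fr$mismatches, rep(2L, 10L))    # max of the two reads' NM
})
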