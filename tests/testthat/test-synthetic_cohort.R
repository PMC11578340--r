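test_that("reference simulation respects placement constraints and determinism", {
  cfg <- synthetic_config(seed = 4, n_chromosomes = 1L,
                          chromosome_length = 100000L, n_genes = 20L,
                          n_expressed_genes = 5L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$tss), 20L)
  expect_true(all(ref$tss$tss >= 500 & ref$tss$tss <= 99500))
  spacing <- diff(sort(ref$tss$tss))
  expect_true(all(spacing >= 1000))

  ## identical config + seed: byte-identical genome and annotation
  ref2 <- simulate_reference(cfg)
  expect_identical(as.character(ref$genome), as.character(ref2$genome))
  expect_identical(ref$tss, ref2$tss)
  expect_identical(ref$ground_truth, ref2$ground_truth)

  ## infeasible sizing: 200 genes cannot fit in 10 kb at 1 kb spacing
  cfg_bad <- synthetic_config(n_chromosomes = 1L, chromosome_length = 10000L,
                              n_genes = 200L, n_expressed_genes = 5L)
  expect_error(simulate_reference(cfg_bad), "at most")

  ## ground-truth motif structure mirrors the nuclease biology
  expect_true(all(startsWith(ref$ground_truth$increased_motif_set, "A") |
                    startsWith(ref$ground_truth$increased_motif_set, "G")))
  expect_true(all(startsWith(ref$ground_truth$decreased_motif_set, "C")))
  expect_length(intersect(ref$ground_truth$increased_motif_set,
                          ref$ground_truth$decreased_motif_set), 0L)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_increased_motifs = 200,
                                n_decreased_motifs = 100), "256")
  expect_error(synthetic_config(tss_depletion_depth_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(fragments_per_sample = 0), "fragments_per_sample")
  expect_error(synthetic_config(n_expressed_genes = 100, n_genes = 50),
               "n_expressed_genes")
})

test_that("fragment simulation is deterministic and respects the length model", {
  cfg <- tiny_config()
  ref <- simulate_reference(cfg)
  s1 <- simulate_fragments(ref, "non-responder", cfg, sample_seed = 77)
  s2 <- simulate_fragments(ref, "non-responder", cfg, sample_seed = 77)
  expect_identical(s1$fragments, s2$fragments)
  expect_equal(nrow(s1$fragments), cfg$fragments_per_sample)

  len <- s1$fragments$end - s1$fragments$start
  oversize <- len >= 600
  ## only the injected insert-rule violators exceed the truncation bound
  expect_true(all(len[!oversize] >= 50 & len[!oversize] <= 599))
  expect_lt(mean(oversize), 0.02)
  expect_true(all(s1$fragments$start >= 0))
  expect_true(all(s1$fragments$end <=
                    ref$chrom_lengths[s1$fragments$chrom]))

  ## a configurable minority fails each retention rule
  st <- filter_fragments(s1$fragments)$stats
  expect_true(all(unlist(st$removed_by_rule) > 0L))
})

test_that("null effects make the two groups generatively identical", {
  cfg <- tiny_config(motif_effect_log2fc = 0, tss_depletion_depth_fraction = 1)
  ref <- simulate_reference(cfg)
  r <- simulate_fragments(ref, "responder", cfg, sample_seed = 5)
  n <- simulate_fragments(ref, "non-responder", cfg, sample_seed = 5)
  expect_identical(r$fragments, n$fragments)
})

test_that("neutral depletion keeps core and flank depths equal", {
  cfg <- tiny_config(tss_depletion_depth_fraction = 1,
                     fragments_per_sample = 60000L,
                     filter_fail_rates = list())
  ref <- simulate_reference(cfg)
  s <- simulate_fragments(ref, "non-responder", cfg, sample_seed = 2)
  sc <- tss_score_sample(s$fragments, ref$tss, ref$chrom_lengths)
  expect_true(all(sc$status == "ok"))
  expect_equal(mean(sc$score), 1, tolerance = 0.05)
})

test_that("planted motif effect is recovered at its stated magnitude", {
  ## group mean frequencies pooled over replicates at the stated depth;
  ## per-motif log2 fold changes must sit in the [0.05, 0.15] band
  cfg <- synthetic_config(seed = 12, fragments_per_sample = 200000L)
  ref <- simulate_reference(cfg)
  gt <- ref$ground_truth
  n_rep <- 4L
  freq_of <- function(group, i) {
    s <- simulate_fragments(ref, group, cfg,
                            sample_seed = 500L + 2L * i +
                              (group == "responder"))
    extract_end_motifs(s$fragments, ref$genome, index = ref$index)$frequencies
  }
  fa <- rowMeans(vapply(seq_len(n_rep), function(i) freq_of("responder", i),
                        numeric(256)))
  fb <- rowMeans(vapply(seq_len(n_rep), function(i) freq_of("non-responder", i),
                        numeric(256)))
  lfc <- log2(fb / fa)
  inc <- lfc[gt$increased_motif_set]
  dec <- lfc[gt$decreased_motif_set]
  expect_gte(sum(inc >= 0.05 & inc <= 0.15), 9L)
  expect_gte(sum(dec <= -0.05 & dec >= -0.15), 10L)
  ## realizability: planted motifs observed in both groups
  expect_true(all(fa[c(gt$increased_motif_set, gt$decreased_motif_set)] > 0))
  expect_true(all(fb[c(gt$increased_motif_set, gt$decreased_motif_set)] > 0))
})

test_that("planted TSS depletion realises the target score fold", {
  cfg <- synthetic_config(seed = 8, tss_depletion_depth_fraction = 0.5,
                          fragments_per_sample = 200000L,
                          filter_fail_rates = list())
  ref <- simulate_reference(cfg)
  expr <- ref$tss$gene_id %in% ref$ground_truth$expressed_gene_set
  folds <- vapply(1:3, function(i) {
    s <- simulate_fragments(ref, "non-responder", cfg, sample_seed = 900L + i)
    sc <- tss_score_sample(s$fragments, ref$tss, ref$chrom_lengths)
    mean(sc$score[expr]) / mean(sc$score[!expr])
  }, numeric(1))
  expect_equal(mean(folds), 0.5, tolerance = 0.1)
})

test_that("cohort bundle is consistent, labelled, and reproducible on disk", {
  cfg <- tiny_config(fragments_per_sample = 2000L)
  co <- simulate_cohort(cfg)
  expect_length(co$samples, 6L)
  expect_equal(sort(names(co$ground_truth$per_sample_labels)),
               sort(co$labels$sample_id))

  ## constructed responders are always RECIST responders (PR or CR)
  lab <- recist_label_table(co$clinical)
  resp_ids <- co$labels$sample_id[co$labels$group == "responder"]
  expect_true(all(lab$category[lab$patient_id %in% resp_ids] %in%
                    c("PR", "CR")))
  nonresp_ids <- co$labels$sample_id[co$labels$group == "non-responder"]
  expect_true(all(lab$category[lab$patient_id %in% nonresp_ids] %in%
                    c("SD", "PD")))

  ## concentrations positive at all four time points
  expect_true(all(co$concentration$ng_per_ml > 0))
  expect_setequal(unique(co$concentration$time_point),
                  c("T1", "T2", "T3", "T4"))

  ## byte-identical outputs across two writes of two independent runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the cfDNA-ratio spike separates the groups downstream", {
  ## spike folds 3.0 vs 1.2 with moderate noise: ROC above 0.8 in >= 9/10 seeds
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(seed = s, n_responders = 8L, n_nonresponders = 8L,
                       fragments_per_sample = 200L)
    co <- simulate_cohort(cfg)
    tab <- cfdna_ratio_table(co$concentration)
    pos <- co$labels$group[match(tab$patient_id, co$labels$sample_id)] ==
      "non-responder"
    roc_auc(tab$ratio, pos, n_boot = 0)$auc > 0.8
  }, logical(1))
  expect_gte(sum(hits), 9L)
})
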