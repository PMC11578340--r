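# cfrag

Cell-free DNA (cfDNA) fragmentomics for predicting response to neoadjuvant
chemotherapy (NACT), implemented as a tested, reproducible R pipeline.

## The problem

Some cervical-cancer patients respond to platinum-based NACT (tumour
shrinkage ≥ 30% after two cycles; RECIST CR/PR) and some do not. Waiting two
cycles to find out costs non-responders toxicity and time. Plasma cfDNA
carries earlier signals:

- **cfDNA ratio** — the concentration one day after the first cycle (T2)
  divided by the pretreatment level (T1). Chemotherapy causes a transient
  cfDNA spike; in non-responders the spike is larger.
- **End motifs** — the 4-mer of genomic sequence at each fragment's 5'
  terminus, a readout of nuclease (DNASE1L3) cleavage preference. Across the
  256 motif categories, non-responders show increased A/G-starting and
  decreased C-starting motifs; the **motif ratio** (accumulated frequency of
  significantly increased over significantly decreased motifs) summarises
  this per sample.
- **TSS scores** — per-gene ratio of mean fragment depth in the 500 bp core
  window around the transcription start site to the mean depth in the
  250–500 bp flanks. Expressed promoters are nucleosome-depleted and lose
  cfDNA coverage, so the score is inversely related to expression;
  differential TSS scores between response groups point at
  resistance-associated genes.

Features are compared by two-sided Mann–Whitney U tests with log2
fold-change gates (|log2FC| > 0.04 for motifs, ≥ 0.5 for TSS scores,
p < 0.05), and their discriminative value is measured by ROC AUC (positive
class: non-responder) with stratified-bootstrap confidence intervals, against
a multiple-logistic baseline on clinical variables (age > 50,
FIGO stage ≥ IIB, tumour size ≥ 4 cm, SCC-Ag).

Because the underlying patient data are not publicly deposited, the package
ships a synthetic cohort generator with known ground truth (planted motif
effects, promoter depletion, concentration spikes, RECIST-consistent tumour
measurements) so that every stage is testable end to end. See the methods
vignette (`vignettes/cfrag-methods.Rmd`) for the model, defaults, and what a
green test does and does not establish.

## Worked example

```r
library(cfrag)

cfg <- pipeline_config(
  synthetic = synthetic_config(n_responders = 8L, n_nonresponders = 6L,
                               fragments_per_sample = 50000L,
                               n_genes = 30L, n_expressed_genes = 8L),
  seed = 42, n_boot = 1000L)
report <- run_pipeline(cfg)
print(report)
```

```
<pipeline_report> 14 samples, seed 42
             feature       auc    ci_low   ci_high n_pos n_neg
         cfdna_ratio 1.0000000 1.0000000 1.0000000     6     8
         motif_ratio 1.0000000 1.0000000 1.0000000     6     8
 clinical_classifier 0.8750000 0.6250000 1.0000000     6     8
                 age 0.7916667 0.5625000 1.0000000     6     8
               stage 0.4375000 0.2083333 0.6880208     6     8
          tumor_size 0.3541667 0.1250000 0.6250000     6     8
              scc_ag 0.6041667 0.2500000 0.8760417     6     8
```

The two cfDNA features separate the planted groups perfectly (AUC 1.0,
n = 6 non-responders vs 8 responders): the generator plants a T2
concentration spike fold of 3.0 vs 1.2 and |log2FC| = 0.1 end-motif shifts,
both well above the calling gates at this sequencing depth. The clinical
classifier and its component variables hover far lower — their AUCs here are
in-sample and only weakly informative by construction, mirroring the
clinical reality that baseline covariates predict response poorly. This run
also called 10 increased / 13 decreased motifs (of 11/12 planted) and 8 of
the 8 planted promoter-depletion genes as significantly decreased TSS
scores in non-responders.

Lower-level entry points: `read_fragments()` / `filter_fragments()`
(retention rules: proper pairs, MAPQ ≥ 30, ≤ 5 mismatches, insert < 600 bp,
no duplicates/multimapped), `extract_end_motifs()`, `differential_motifs()`,
`motif_ratio()`, `tss_score_sample()`, `differential_tss()`,
`cfdna_ratio()`, `recist_classify()`, `ihc_score()`, `roc_auc()`. A CLI
wraps the main flows:

```sh
Rscript -e 'cfrag::cfrag_cli()' simulate --out cohort/ --seed 3
Rscript -e 'cfrag::cfrag_cli()' filter --in cohort/fragments/R01.tsv \
    --out filtered.tsv --stats stats.json
Rscript -e 'cfrag::cfrag_cli()' run --out results/ --seed 3
```

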