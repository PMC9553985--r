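# tcrscope

Antigen-specific T-cell repertoire analysis: calibrated CDR3β classifiers,
cohort biomarkers, clonal dynamics and single-cell phenotype links.

## The problem

Bulk TCRβ sequencing yields clonotype tables — CDR3β amino-acid sequence, V/J
gene, read count — but no information about what each clone recognises.
Experimental answers (pMHC multimer sorting) are low-throughput, so a central
move in tumour immunology is the *in-silico* multimer sort: train a
probabilistic classifier on epitope-sorted CDR3β sequences, calibrate its
decision threshold to a fixed false-positive rate, and sweep it across whole
repertoires to label, e.g., melanoma-antigen (MAA)-specific versus anti-viral
bystander clones. Downstream of the labels sit the questions clinicians care
about: does the aggregate frequency of predicted tumour-specific clones
separate patients from healthy donors, does a dominant (>1% of reads)
tumour-specific clone stratify survival, which clones expand or get replaced
across immune checkpoint therapy, and which single-cell phenotypes do the
predicted specificities occupy?

`tcrscope` implements that pipeline for R, for immunoinformaticians and
computational immunologists:

- **Repertoire I/O and QC** — ImmunoSEQ-style, AIRR-C and simple TSV dialects;
  non-functional clonotype removal; pooling, exact hypergeometric subsampling.
- **Diversity and sharing** — Shannon, Simpson, clonality
  `1 − H/ln(richness)`, public-clonotype overlap matrices.
- **Motif convergence** — CDR3-core k-mer enrichment against a reference
  (one-sided Fisher + BH), motif sharing and Spearman rank correlation.
- **Specificity models** — Gaussian-process CDR3 classifiers over spectral
  BLOSUM62 embeddings; LOO / 20-fold / leave-one-subject-out CV; ROC + AUROC
  and precision-recall + AP; FPR-5% threshold calibration; multi-epitope
  panels with a union rule and panel-level FPR estimation (≈ `1 − 0.95⁵` for
  five independent models).
- **Cohort analyses** — labelled-clone frequency biomarker with 10-fold CV
  logistic AUROC, greedy age matching, dominant-clone flag, Kaplan–Meier and
  log-rank (via the survival package).
- **Clonal dynamics** — per-clone two-sided Fisher expansion tests on raw read
  depths with BH (expanded ⇔ adjusted p < 0.05 and frequency up), and clonal
  replacement `1 − persisting frequency`.
- **Single-cell layer** — `ln(1 + 10⁴·x/total)` normalisation, specificity ×
  cluster enrichment, Welch-t differential expression with Bonferroni,
  paired exhaustion-fraction change, CellPhoneDB-style ligand–receptor
  permutation tests (≥ 50 cells, 1000 shuffles).
- **Synthetic data** — seeded generators for every input above, with planted
  motifs, expansions, cohort shifts and single-cell effects plus truth tables,
  so the whole pipeline is testable without restricted patient data.

## Worked example

```r
library(tcrscope)

# 1. simulate an epitope-specific training set and train a calibrated model
cfg <- syntheticConfig(seed = 42, cdr3_length_range = c(10, 18))
ts <- generateEpitopeRepertoire(cfg, motif = list(kmer = "WGQG", prob = 0.9,
                                                  position = "center"),
                                nPositives = 120, subjects = 6,
                                epitope = "MART1_AAGIGILTV")
pool <- generateCdr3s(syntheticConfig(seed = 99, cdr3_length_range = c(10, 18)), 3000)
cv <- crossValidate(ts, scheme = "auto", seed = 1, backgroundPool = pool)
cat(sprintf("CV (%s): AUROC %.3f, AP %.3f\n", cv$scheme, cv$auroc, cv$average_precision))
#> CV (kfold20): AUROC 0.890, AP 0.914

model <- trainEpitopeModel(ts, seed = 1, backgroundPool = pool)
calib <- generateCdr3s(syntheticConfig(seed = 7, cdr3_length_range = c(10, 18)), 1000)
model <- calibrateThreshold(model, predictScores(model, calib))
model
#> EpitopeModel 'MART1_AAGIGILTV' (gp_laplace): 240 training points, lengthscale 10.3, threshold 0.5568

# 2. label a repertoire and read off the biomarker
panel <- ModelPanel(list(model), groups = list(MAA = "MART1_AAGIGILTV"))
rep <- generateBackgroundRepertoire(syntheticConfig(seed = 5,
                                                    cdr3_length_range = c(10, 18),
                                                    motif = list(kmer = "WGQG", prob = 0.02,
                                                                 position = "center")),
                                    sampleId = "patient01")
labelled <- classifyRepertoire(panel, rep)
tf <- targetFrequency(labelled, "MAA")
cat(sprintf("anti-MAA frequency %.4f across %d clonotypes; dominant clone: %s\n",
            tf$frequency, tf$n_clones, dominantCloneFlag(labelled, "MAA")))
#> anti-MAA frequency 0.0640 across 32 clonotypes; dominant clone: TRUE

# 3. longitudinal expansion and replacement
lp <- generateLongitudinalPair(syntheticConfig(seed = 11), nExpanded = 20, fold = 10)
er <- expansionTest(lp$pre, lp$post)
rm <- replacementMetrics(lp$pre, lp$post)
cat(sprintf("expanded clones: %d (of %d tested); replacing frequency: %.3f\n",
            sum(er$expanded), sum(!is.na(er$p_value)), rm$replacing_frequency))
#> expanded clones: 20 (of 331 tested); replacing frequency: 0.003
```

Reading the output: 120 synthetic positives carrying a planted motif train a
20-fold cross-validated model at AUROC 0.89; the calibrated threshold 0.557
corresponds to a 5% false-positive rate on background CDR3s. Applied to a
10,000-read repertoire in which ~2% of clones carry the motif, the panel
labels 32 clonotypes totalling 6.4% of reads, including a dominant (>1%)
clone. In the longitudinal pair, all 20 planted 10× expansions are recovered
with no false calls, and replacement is near zero because no novel clones were
injected.

The methods vignette (`vignettes/tcrscope-methods.Rmd`) documents the models,
parameter defaults, generator assumptions and their limitations.

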