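# backsplicer

Predicting whether a paired splice-acceptor / splice-donor sequence
context supports circRNA back-splicing, and reading the learned
convolutional filters back out as RNA motifs.

## What it does

Back-splicing — the non-canonical junction of a downstream splice donor
(SD) to an upstream splice acceptor (SA) — produces circular RNAs, and
part of its regulation is encoded in the sequence flanking the two
sites.  `backsplicer` frames the problem as binary classification over a
pair of 100-nt windows (50 nt intron + 50 nt exon around each site,
one-hot encoded over A/C/G/U) with a dual-branch 1-D convolutional
network: per branch conv(256×12, valid) → dropout → conv(128×30, same,
stride 2) → dropout → max-pool(5,5) → dropout → flatten(1152); the two
branches (unshared weights) are concatenated (2304), batch-normalized
and fed to a sigmoid unit.  Training is RMSProp on binary cross-entropy,
batch 1024, ≤ 100 epochs with early stopping (patience 20, best-weights
restore).

Around the classifier the package provides, as tidyverse-style functions
over tibbles:

* **Dataset construction** — window assembly with the 50-nt flank
  filter, deduplication, canonical-splice negative sampling over 2–3
  exons of a transcript, stratified k-fold splitting, TSV / paired-FASTA
  / xlsx-sheet I/O.
* **Evaluation** — ACC, AUC (midrank ties), MCC, sensitivity,
  specificity; stratified 7-fold cross-validation; a batch-normalization
  ablation harness (`default`, `no_bn`, `bn_to_dropout`) on shared
  folds.
* **Motif interpretation** — first-layer activation scores per
  (sequence, filter, position); argmax subsequence selection; position
  probability matrices (per-position counts / support); MEME minimal
  format export (TOMTOM-ready) and parsing; positional occurrence
  densities around the splice site for positives vs negatives;
  intron/exon enrichment; cross-set PPM alignment by mean per-column
  Pearson correlation.
* **A planted-motif simulator** — seeded generator with side-specific
  PWM plants and a ground-truth log, so every stage above is testable
  without downloading a genome.

The network itself (forward, backprop, RMSProp, batch norm, early
stopping) is implemented in vectorized R over BLAS matrix products and
verified by finite-difference gradient checks and a shape oracle.

## A worked example

The shipped benchmark: 2000 positives carrying two planted 10-nt motifs
(SA-intron side and SD-exon side, probability 0.9 each) vs 2000
background negatives, cross-validated with a reduced network:

```r
library(backsplicer)

sim <- simulate_dataset(default_sim_config(seed = 7))
cfg <- model_config(conv1_kernels = 16, conv2_kernels = 16, conv2_size = 20,
                    dropout1 = 0.2, dropout2 = 0.2, batch_size = 256,
                    max_epochs = 15, early_stopping_patience = 15,
                    learning_rate = 2e-3, seed = 7)
cv <- cross_validate(sim$pairs, cfg, k = 7, seed = 7, keep_best_model = TRUE)
round(cv$mean, 4)
#>      acc    auc    mcc sensitivity specificity
#> 1 0.9385 0.9882 0.8797      0.9745      0.9025
```

Mean 7-fold test AUC 0.988: the planted signal is found (the ceiling of
~0.995 comes from plant probability 0.9).  Extract what the best fold's
filters learned:

```r
pos <- dplyr::filter(sim$pairs, label == 1)
cmem <- first_layer_activations(cv$best_model, pos, "SA")
ppms <- ppms_from_selection(select_subsequences(cmem))
ppm_best_alignment(ppms$filter14, default_sim_config()$plants[[1]]$pwm)
#> $score   0.997  — column correlation with the planted PWM
#> $offset  0
#> $overlap 10

occ <- scan_occurrences(cv$best_model, sim$pairs, "SA", filter = 14)
intron_exon_ratio(occ)
#>   fraction_intron fraction_exon     n
#> 1           0.857         0.143  1954
autoplot(occurrence_density(occ, smooth = TRUE))  # positive-class peak
                                                  # abutting the boundary
write_meme(ppms, "sa_motifs.meme",
           background = empirical_composition(sim$pairs))
```

The SA plant was recovered almost exactly (column correlation 0.997 at
offset 0), and 86% of its positive-sample occurrences fall on the
intron side, as planted; the density profile peaks at window start 40 —
the modal planted offset — in positives and stays flat in negatives.
Exact numbers for your machine are printed by the code; these are from
the shipped benchmark configuration under seed 7.

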