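# gliosemi

Semi-supervised prediction of IDH1 mutation status from multi-sequence
brain MRI, for imaging researchers who have many scanned glioma patients
but genotype labels for only a subset. The package implements the full
adaptive pipeline end to end and ships a synthetic phantom-cohort
generator, so every stage runs offline without clinical data.

## The method

Given labeled patients (IDH1 mutant / wild type) and unlabeled patients,
each with co-registered T1C / T2 / FLAIR / DWI volumes:

1. **Radiomics.** Gray-level co-occurrence (GLCM) and run-length (GLRLM)
   texture matrices are computed per slice with GrayLimits = [0, 2100],
   NumLevels = 100, GLCM directions {0°, 45°, 90°, 135°} × offsets
   {1, 4, 7}, GLRLM directions {0°, 90°}. With the 22 Haralick-style GLCM
   features and 11 Galloway run-length features, enumerating
   per-(direction, offset) values plus direction averages yields
   22·(4·3+3) + 11·(2+1) = 330 + 33 = **363 features per sequence**
   (1452 over four sequences).
2. **Screening.** Each feature is tested with an independent two-sample
   *t*-test; features with p < 0.05 survive.
3. **Rough-set reduction.** Features are quantile-discretized into a
   decision table. The *positive region* POS(B) is the union of
   indiscernibility classes (identical attribute tuples) that are pure in
   the decision. Attributes are deleted one by one whenever removal leaves
   POS unchanged, until no deletion is possible — the surviving subset (a
   *reduct*) preserves classification ability and is 1-minimal.
4. **Pseudo-labeling.** For every reduct feature, the cutoff maximizing
   Youden's J = sensitivity + specificity − 1 is found by exhaustive scan
   over observed values and both orientations. The per-feature threshold
   rules vote on each unlabeled patient (majority; ties → wild type).
5. **Weighted semi-supervised loss.** The classifier minimizes
   `L = Σ_labeled ℓ(f(x), y) + α · Σ_pseudo ℓ(f(x), y)` with labeled
   weight fixed at 1 and pseudo-label weight α ∈ [0, 1].
6. **SCSO.** α is tuned by Sand Cat Swarm Optimization, a population
   metaheuristic whose agents attack (|R| ≤ 1) or search for prey, with
   sensitivity rG decaying linearly from 2 to 0 over the iterations.
7. **UCNet.** A U-Net-style autoencoder (dense-block encoder,
   residual-block decoder, skip connections, trained on mean-squared
   reconstruction error) extracts one feature vector per slice from its
   globally average-pooled bottleneck; a CRNN (1-D convolution → LSTM →
   dropout → softmax) classifies the ordered slice-feature sequence with
   the weighted loss. Convolutions are compiled (RcppArmadillo); all
   gradients are exact and verified against finite differences.

## Worked example

```r
library(gliosemi)
cfg    <- demo_pipeline_config(seed = 1)  # 32x32x4 phantoms, T2+FLAIR
report <- run_pipeline(cfg)
```

The run log prints each stage; with seed 1 the demo cohort (10 labeled
patients per class + 8 unlabeled) gives:

```
t-test retained 296 / 726 features (P < 0.05)
reduct: 1 attributes, |POS| = 20
pseudo-labeled 8 patients (6 mutant / 2 wild)
SCSO tuned pseudo-label weight alpha = 0.565
pipeline complete
```

```r
report$rules[[1]]
#> <threshold_rule> FLAIR|GLCM|Correlation|avg|1 ≤0.7476  J=1.000 AUC=0.000
str(report$metrics[c("alpha", "val_accuracy", "rule_holdout_accuracy")])
#> $ alpha        : num 0.565
#> $ val_accuracy : num 1
#> $ rule_holdout_accuracy: num 1
```

Reading: the t-test kept 296 of the 726 two-sequence radiomics features;
the rough-set reduction found that a single attribute (the
direction-averaged GLCM Correlation of FLAIR at offset 1) already
preserves the positive region; its Youden rule separates the labeled
classes perfectly (J = 1; the rank AUC of 0 means mutant values lie
entirely *below* the cutoff, matching the "≤" orientation); 8 unlabeled
patients were pseudo-labeled by the rule vote; SCSO chose α = 0.565 as
the pseudo-label weight minimizing validation loss; and the final CRNN
classified the held-out labeled patients perfectly at this easy phantom
separation. All artifacts (feature CSVs, t-test statistics, reduct JSON,
rules CSV, pseudo-labels CSV, SCSO trace, training histories, metrics
JSON, model) are written to `cfg$out_dir`.

A command-line wrapper with the same stages lives at `inst/cli/gliosemi`
(`simulate`, `extract-features`, `select`, `pseudo-label`, `tune-weight`,
`train`, `predict`, `run-all`).

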