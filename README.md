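# prohl

Sequence-based classification of bacterial proteins as **short-lived**
(half-life < 1 hour) or **long-lived**, for metabolic engineers hunting
turnover-limited bottleneck enzymes and for anyone building protein
stability classifiers on small, imbalanced bacterial datasets.

Intracellular enzyme levels depend on protein turnover as much as on
expression: a pathway enzyme with a half-life under an hour can
rate-limit an entire synthetic pathway. `prohl` predicts that stability
class from sequence alone by fusing three views of a protein:

1. **Residue-level embeddings** — a `d × L` matrix per sequence, projected
   to a fixed-length vector by two Conv2D → average-pooling → dropout
   blocks whose parameters are trained jointly with the classifier;
2. **Sequence-level embeddings** — reduced by PCA to the components
   explaining 95% of variance;
3. **Physicochemical descriptors** — four families with ablation-group
   tags: gapped k-mer pair composition (CKSAAP), dipeptide deviation from
   expected mean (DDE), composition/transition/distribution (CTD), and
   sequence-order descriptors (Moran autocorrelation + sequence-order
   coupling numbers), z-scored and filtered by a per-feature two-class
   ANOVA (keep *p* ≤ 0.01).

The concatenated representation feeds a fully connected sigmoid
classifier trained with Adam, early stopping (patience 5, best weights
restored), and model selection by **grid search over 1,296 hyperparameter
configurations** under stratified k-fold cross-validation, maximising the
mean Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

with long-lived as the positive class. The package also provides
CD-HIT-style greedy redundancy reduction at 0.5 identity, a
leave-one-group-out descriptor ablation harness, a synthetic
labelled-proteome generator with plantable degron motifs (default: the
ssrA tag `AANDENYALAA`), and a deterministic synthetic embedder so the
entire pipeline runs and is testable offline. See
`vignettes/prohl-methods.Rmd` for the full model description.

## Worked example

```r
library(prohl)

# simulate a labelled proteome with a planted degron signal
spec <- synthetic_spec(n_long = 120, n_short = 40, length_range = c(50, 120),
                       p_motif = 0.9, effect_size = 2, seed = 42)
train_ds <- generate_synthetic(spec)
test_ds  <- generate_synthetic(synthetic_spec(n_long = 30, n_short = 10,
                                              length_range = c(50, 120),
                                              p_motif = 0.9, effect_size = 2,
                                              seed = 43))
emb <- synthetic_embedder(seed = 7, d_local = 22, d_global = 16,
                          L_padded = 130,
                          signal_map = signal_map_from_spec(spec))

# train with the published default configuration (kernel 7x7, 8 filters,
# 2 layers, units = input dim, dropout 0.2, lr 1e-3, batch 32)
cls <- prohl_train(train_ds$sequences, train_ds$labels$label, emb,
                   config = model_config(seed = 3), seed = 1)

pred <- prohl_predict(cls, test_ds$sequences)
head(pred, 5)
#>          id probability_long_lived predicted_class note
#> 1 synth0001               4.07e-05     short_lived <NA>
#> 2 synth0002               1.00e+00      long_lived <NA>
#> 3 synth0003               9.99e-01      long_lived <NA>
#> 4 synth0004               9.89e-01      long_lived <NA>
#> 5 synth0005               1.00e+00      long_lived <NA>

round(compute_metrics(confusion_counts(test_ds$labels$label,
                                       pred$predicted_class)), 3)
#>   ACC   SEN   SPE   PPV   NPV   MCC
#> 0.975 1.000 0.900 0.968 1.000 0.933
```

`probability_long_lived` is the sigmoid output for the positive
(long-lived) class; records failing validation (length outside 50–1655 or
non-standard residues) get a `note` instead of a prediction and the batch
continues. On this held-out set the classifier recovers the planted
signal almost perfectly (MCC 0.933); the specificity of 0.900 means 9 of
the 10 short-lived proteins were caught.

A command-line interface wraps the same functions:

```sh
exec/prohl simulate --out sim --seed 1 --n-long 120 --n-short 40
exec/prohl train --fasta sim/sequences.fasta --labels sim/labels.tsv \
    --out model --folds 3 --grid reduced
exec/prohl predict --model model --fasta sim/sequences.fasta --out pred.tsv
exec/prohl eval --truth truth.tsv --pred pred.tsv --out metrics.json
```

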