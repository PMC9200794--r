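# seqboost

Binary classification of DNA sequences — e.g. disease-associated genes
versus background genes exported as FASTA — and probability ranking of
unlabeled candidates, built from four pieces:

1. **Composition / gapped k-mer features**: a fixed 14,891-dimensional
   space (at K = 3, n = 5) of terminal Z-curve coordinates, GC content,
   AT/GC ratio, GC/AT skews, word counts of length 1–3, and eight gapped
   k-mer families counting patterns `left-word · g wildcards · right-word`
   for g = 1..5 (names like `diDiKGap_g3_AC_GT`).
2. **Spectral descriptors**: five numerical encodings of a sequence
   (binary indicators, integer, real, cumulative Z-curve, EIIP), the DFT
   power spectrum of each, and 18 summary statistics per spectrum (PAPR,
   period-3 SNR, quantiles, moments) — 90 features.
3. **SAMME.R feature selection**: real-valued AdaBoost over depth-limited
   trees; per-feature scores are averaged Gini impurity decreases, the
   default rule keeps features with nonzero importance.
4. **A gradient-boosted decision tree** with logistic loss: init
   h₀ = ½·log(Σy/Σ(1−y)), pseudo-residuals r = ỹ/(1+e^{ỹh}) with
   ỹ = 2y−1, least-squares trees, Newton leaf values, shrinkage lr, and
   probabilities p = 1/(1+e^{−2H}).

Evaluation uses seven metrics (ACC, AUC, AUPR, F1, MCC, SEN, SPC) under
stratified 4- or 10-fold cross-validation, with feature selection refit
inside each training fold (fitting it once before CV leaks labels and
inflates null AUC to ~0.9), and results averaged over negative batches. A
synthetic-data module generates batch-structured two-class FASTA with
planted gapped patterns so the whole pipeline is testable offline.

## Worked example

The 11-base sequence `TGACCGAGAGA` is used as a running example throughout
the tests:

```r
library(seqboost)
zcurve_terminal("TGACCGAGAGA")
#>  x  y  z
#>  5  1 -1

v <- pyfeat_vector("TGACCGAGAGA")   # length 14,891
round(v[c("gc_content", "atgc_ratio", "gc_skew",
          "pseudo_GA", "monoMonoKGap_g1_G_G")], 4)
#>          gc_content          atgc_ratio             gc_skew
#>             54.5455              0.8333              0.3333
#>           pseudo_GA monoMonoKGap_g1_G_G
#>              4.0000              2.0000
```

x(L) = 5 because the sequence has 4 A + 4 G purines against 2 C + 1 T
pyrimidines; `pseudo_GA` counts the four overlapping GA words;
`monoMonoKGap_g1_G_G` counts G·x·G patterns.

End to end on a small synthetic world (40 positives, 2 negative batches of
40, two planted gapped patterns enriched in positives):

```r
cfg  <- synth_config(n_pos = 40, n_neg_batches = 2, batch_size = 40,
                     length_range = c(150L, 250L), seed = 11)
gd   <- generate_dataset(cfg)
pcfg <- pipeline_config(select = list(rounds = 25),
                        gbdt = list(rounds = 50), cv = list(k = 5),
                        seed = 11)
res  <- run_pipeline(gd$positives, gd$negatives, pcfg,
                     out_dir = "seqboost_run")
res$metrics
#> <metrics_report> ACC=0.788 AUC=0.883 AUPR=0.892 F1=0.773 MCC=0.584
#>                  SEN=0.750 SPC=0.825
head(res$ranking$feature_names[res$ranking$ranking], 4)
#> [1] "triMonoKGap_g1_GGA_T" "diDiKGap_g1_GA_TC"
#> [3] "diDiKGap_g1_CG_GA"    "diDiKGap_g5_GG_CC"
```

The metrics are 5-fold cross-validated and averaged over the two negative
batches; the top-ranked features are gapped k-mers overlapping the planted
`GGA·g·TC` pattern. At the full default scale (182 positives, 4 batches of
185, 10-fold CV) the batch-averaged AUC on planted-signal data exceeds
0.90 and permuted labels score ~0.5 — see
`tests/testthat/test-acceptance.R`.

`run_pipeline()` writes `features.tsv`, `importance.tsv`, `mask.json`,
`model.json`, `metrics.json` and (for queries) `ranked.tsv` under
`out_dir`, each stamped with the config hash.

## Command line

Every stage is also a subcommand reading/writing plain files:

```sh
inst/exec/seqboost simulate   --preset protein --out data/ --seed 3
inst/exec/seqboost preprocess --in raw.fa --out clean.fa --dedup id
inst/exec/seqboost featurize  --in clean.fa --out features.tsv --family pyfeat
inst/exec/seqboost evaluate   --pos pos.fa --neg n1.fa,n2.fa --cv 10 \
                              --out metrics.json
inst/exec/seqboost rank       --model model.json --in candidates.fa \
                              --out ranked.tsv
```

## Documentation

`vignettes/seqboost-methods.Rmd` describes the feature definitions and
their pinned conventions, the boosting equations and their numerical
safeguards, the fold-internal selection protocol and why it matters, what
the synthetic generator does and does not emulate, and known limitations.
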