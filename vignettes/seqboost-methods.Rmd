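---
title: "seqboost: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqboost: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqboost)
```

## The problem

seqboost classifies DNA sequences into two classes — typically
disease-associated genes versus background genes exported as FASTA from a
genome browser — and ranks unlabeled candidates by predicted probability.
The study design it targets is a single positive set evaluated against
several same-sized batches of negatives, with all performance numbers
averaged over batches. Everything needed to exercise the pipeline without
external downloads is generated by the synthetic module.

## Feature families

### Composition and gapped k-mer features (14,891 dimensions)

`pyfeat_features()` builds a fixed-schema vector of 13 blocks:

| block | size | content |
|---|---|---|
| zcurve | 3 | terminal Z-curve coordinates x(L), y(L), z(L) |
| gccontent | 1 | 100·(G+C)/L |
| atgc_ratio | 1 | (A+T)/(G+C) |
| cumulative_skew | 2 | (G−C)/(G+C), (A−T)/(A+T) |
| pseudo_composition | 84 | overlapping counts of all words of length 1..K (K = 3) |
| eight k-gap families | 80–5120 each | counts of left-word, g wildcards, right-word, g = 1..n (n = 5) |

With K = 3 and n = 5 the total is 14,891. Features are raw overlapping
occurrence counts; an optional `normalize` flag divides each count by its
number of possible placements. Tree ensembles are invariant to per-feature
monotone scaling, so the choice does not affect downstream results, and raw
counts make small worked examples exact.

Canonical ordering is fixed for serialization: within each k-gap family the
gap ascends in the outer loop, then left and right words lexicographically
with A\<C\<G\<T; names read like `diDiKGap_g3_AC_GT`.

Two degenerate-input conventions: the AT/GC ratio of a G+C-free sequence is
reported as `NA` and flagged (then mean-imputed before model fitting), and
skews with a zero denominator are 0. This keeps feature matrices finite
without discarding pathological records silently.

The Z-curve block uses the terminal coordinates. The three cumulative
channels track purine/pyrimidine (x), amino/keto (y) and weak/strong
hydrogen-bond (z) excesses; their values at position L are the only
three-number summary consistent with the cumulative definition.

### Spectral descriptors (90 dimensions)

`rff_features()` encodes a sequence five ways — 4-channel binary
indicators; integer (T=0, C=1, A=2, G=3); real (A=−1.5, G=−0.5, C=0.5,
T=1.5); cumulative Z-curve; EIIP pseudopotentials (G=0.0806, A=0.1260,
T=0.1335, C=0.1340) — takes the DFT power spectrum of each (squared
magnitudes, summed over channels for binary and Z-curve, no zero-padding,
DC bin included), and summarizes each spectrum with 18 statistics:
PAPR, SNR, min, max, median, population/sample SD, percentiles 15/25/50/75,
variance, coefficient of variation, amplitude, semi-IQR, IQR, skewness and
kurtosis.

Several of these statistics have no universal definition, so the package
pins conventions and the tests pin them too:

* **PAPR** = max(P)/mean(P).
* **SNR** = P\[round(L/3)\]/mean(P) — the period-3 bin, the conventional
  signal bin in genomic signal processing (coding regions show 3-base
  periodicity).
* **CV** = population SD / mean; **variance** is the sample variance.
* **skewness/kurtosis** are the standardized 3rd/4th central moments,
  kurtosis non-excess (normal → 3).
* **percentiles** use linear interpolation (R's default type 7).
* Descriptors use all bins including DC; `drop_dc = TRUE` excludes it.
* Length-1 sequences are rejected (sample SD undefined).

## Feature selection: SAMME.R importance

`fit_importance()` boosts depth-limited classification trees (default:
stumps, 50 rounds) with the real-valued AdaBoost update: per round, leaf
class-probability estimates p (clipped away from 0/1) reweight each sample
by exp(−0.5·ỹ·(log p − log(1−p))), and every split credits its weighted
Gini impurity decrease to its feature. Scores are averaged over rounds and
normalized to sum to one; ranking ties break by ascending feature index, so
the whole procedure is deterministic. The default selection rule keeps all
features with nonzero importance — with 50 stump rounds this bounds the
selected set at 50 features, which is in the spirit of the original
system's "a couple hundred from 14,891" reduction; the observed 213-feature
average there is an empirical outcome on its data, not a target.

**Where selection runs matters.** Fitting the selector on a full dataset
and then cross-validating on the selected columns leaks held-out labels
through the feature choice: on label-permuted synthetic data that protocol
yields a 10-fold AUC near 0.89 despite there being no signal. seqboost
therefore refits selection inside each training fold of
`cross_validate()`; with that protocol the permuted-label AUC is ~0.5, as a
null should be. `run_pipeline()` additionally fits one full-data ranking,
used only for the exported importance table and candidate-ranking model,
never for the reported cross-validated metrics.

## The GBDT classifier

Labels y ∈ {0,1} are boosted as ỹ = 2y−1. The model keeps a score H(x)
equal to half the log-odds:

* init: h₀ = 0.5·log(Σy / Σ(1−y));
* per round: pseudo-residuals rᵢ = ỹᵢ/(1+exp(ỹᵢ·h(xᵢ))) (the negative
  gradient of log(1+exp(−ỹh))); a least-squares regression tree partitions
  the residuals (greedy variance-reduction splits at midpoints of sorted
  unique values, stopping at `max_depth`, `min_leaf` or zero gain); each
  leaf value solves argmin_v Σ log(1+exp(−ỹ(h+v))) by safeguarded
  Newton–Raphson from 0 (first step Σr/Σ|r|(1−|r|), tolerance 1e−8, 25
  iterations, clamped to ±4 — a saturated leaf's true minimizer is
  infinite);
* update: h ← h + lr·(leaf value); probabilities p = 1/(1+exp(−2H)),
  classification at p ≥ 0.5.

Defaults are M = 100 rounds, lr = 0.1, depth 3, min_leaf 5 — unstated in
the source system, chosen as standard boosted-tree practice and exposed in
the config. Scores are clipped at ±50 before exponentials.

One internal tension in this formulation is worth recording: the loss
log(1+exp(−ỹh)) is minimized at the *full* log-odds, while h₀ and the
sigmoid(2H) link treat H as *half* the log-odds. Consequently an M = 0
model predicts exactly the class prevalence, but unregularized boosting
pushes single-leaf predictions to p²/(p²+(1−p)²) — sharper than the
prevalence. This does not affect ranking (AUC/AUPR) or the 0.5 threshold
(h = 0 either way), only probability calibration at the extremes; the
tests assert the actual closed forms.

## Evaluation

Seven metrics: ACC, AUC, AUPR, F1 = TP/(TP+0.5(FN+FP)), MCC, SEN, SPC
(plus precision and FPR = 1−SPC). AUC is the trapezoidal area over the
tie-grouped ROC (equal to the Mann–Whitney statistic); AUPR is the
recall-step-weighted precision sum (step interpolation, no trapezoid).
Zero-denominator metrics are reported as 0 with a flag rather than NaN so
batch averages stay defined. Folds are stratified with a fixed seed —
without stratification per-fold MCC/AUC can be undefined — and per-fold
metrics are arithmetically averaged (a pooled-prediction variant is behind
a flag). `batch_evaluate()` pairs the positive set with each negative batch
and averages the per-batch reports.

## The synthetic world

`synth_config()` defaults state the world the tests run in:

* shapes mirror the target study design: `preset = "protein"` gives 182
  positives and 4 negative batches of 185; `"lncrna"` gives 137 and 8×141;
* sequence lengths uniform in 200–400 bases — desk-scale stand-ins for
  gene-length sequences, long enough for stable spectra and k-gap counts;
* background composition uniform (0.25 each) in both classes, so
  composition is not a confounder unless configured;
* two planted gapped patterns, `AC---GT` at Poisson rates 3.0 (positives)
  vs 0.2 (negatives) and `GGA-TC` at 2.5 vs 0.3 — strong, known-truth
  signal for exactly two named k-gap features; insertions overwrite
  background at uniform positions, so length is class-independent;
* an optional period-3 G bias per class (default off) feeds the spectral
  family's SNR bin when exercised.

What a green end-to-end test establishes: the pipeline recovers planted
gapped-pattern signal (batch-averaged 10-fold AUC ≥ 0.90), ranks the
planted features at the top of the importance list, and reports null-level
AUC on permuted labels. What it does not establish: performance on real
genomes — real genes have non-uniform composition, repeats, exon
structure, and far longer sequences, none of which the generator emulates,
and the original system's headline numbers depend on its external data.

## Numerical and degenerate-input choices

* FASTA parsing/writing is delegated to Biostrings (60-column wrap);
  record ids are the first whitespace-delimited header token; dedup keeps
  the first record per id (default) or per exact sequence.
* Ambiguity codes (N, R, Y, …) are stripped by default: every downstream
  formula is defined over {A,C,G,T} only. A record left empty is an error.
* The cumulative skews use (G−C)/(G+C) and (A−T)/(A+T); the source's
  printed denominators reduce every input to −1 and are treated as a sign
  typo.
* Split ties break toward the lowest feature index and lowest threshold;
  all fits are deterministic given their inputs, and seeds only control
  fold assignment and data generation (kept below 2³¹).
* Parseval (time-domain energy = mean spectral power) is enforced at 1e−9
  relative tolerance against a direct O(L²) DFT oracle in the tests.

## Known limitations

Binary classification only; no reverse-complement-aware counting; no
protein alphabets; no confidence intervals on metrics; probability
calibration inherits the half/full log-odds tension described above; the
SAMME.R selector with depth-1 stumps can select at most `rounds` features.
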