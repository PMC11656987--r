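---
title: "Detecting and explaining LTR retrotransposon sequences with ltrlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and explaining LTR retrotransposon sequences with ltrlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrlearn)
```

## The problem

Long terminal repeats (LTRs) flank both ends of LTR retrotransposons and act
as the element's promoter and terminator. They are short (roughly 100–4000
bp), highly variable in length and composition, and organised rather than
conserved: canonical TG..CA terminal nucleotides, a core promoter with a
TATA box (consensus TATAWA) upstream of the transcription start site, and a
collection of transcription-factor binding sites (TFBS) in the U3 region.
Alignment-based comparison works poorly on such sequences, which makes them
a natural target for sequence-level machine learning — provided the models
can also be *explained*, so that a good classifier becomes a source of
biological insight rather than a black box.

`ltrlearn` implements that workflow end to end: curated positive/negative
set construction, three featurization tracks, two trainable model families,
statistical model comparison, and an explainability layer that maps model
behaviour back onto sequence positions and motifs. A synthetic data
generator with a planted-signal truth table makes every step testable
offline.

## Data model

Sequences travel as tibbles (one row per record: `id`, `sequence`,
`species`, `is_ltr`, `superfamily`, `family`), motifs as `ltr_pwm` objects
(4 × width matrices over A/C/G/T, counts or probabilities). Three
classification tasks are supported throughout: LTR detection (binary),
superfamily classification (Ty1/Copia vs Ty3/Gypsy, binary), and family
classification (15-way softmax by default; the family list is a
configuration default, not a claim).

All coordinates are 0-based and half-open. Sequences are handled in their
element orientation; reverse-complement scanning is available behind a flag
but off by default, because LTRs are orientation-defined.

## Negative-set construction

A useful LTR-negative set must be harder than uniform random DNA, otherwise
the models learn base composition instead of sequence organisation. Three
classes are composed (`compose_negative_set()`), by default in equal
thirds:

* **genomic-like** windows sampled from supplied contigs, avoiding excluded
  (annotated-LTR) intervals;
* **uniform-random** sequences;
* **Markov resamples**: the positives are clustered at 70% identity, an
  order-2 Markov chain is trained per cluster
  (`P(b|c) = (count(cb) + q)/(count(c·) + 4q)`, pseudocount `q = 0.5` so
  small clusters never produce dead ends), and sequences are generated from
  those chains. These match the positives' local 3-mer composition while
  destroying their spatial organisation — the most informative negative
  class.

Generated lengths follow the empirical length distribution of the source
cluster, preserving the length structure the models see. A solo-LTR screen
(`solo_ltr_screen()`, local alignment at the conventional 80% identity /
80% coverage thresholds) removes negatives that are actually orphaned LTRs.

## Featurization tracks

* **TFBS counts** (`scan_pwm_counts()`): each motif's log-odds window is
  slid along the forward strand; a position counts as an occurrence when its
  score reaches `min + rel_threshold · (max − min)` of the motif's
  attainable score range (default `rel_threshold = 0.8`, uniform background,
  pseudocount 0.8 — standard JASPAR-scanning practice; the threshold rule is
  fully specified so any implementation agrees). Counts are re-weighted by
  smoothed TF-IDF (`idf(t) = ln((1+N)/(1+df(t))) + 1`, L2-normalised rows)
  to de-emphasise unspecific, ubiquitous binding sites.
* **One-hot encoding** (`one_hot_encode()`): N bases are removed, sequences
  are truncated to their 5'-most `L_max` bases (default 4000) or padded at
  the 3' end; padded positions are masked out of every model pass.
* **k-mer tokenization** (`kmer_tokenize()`): overlapping stride-1 k-mers
  (k ∈ {4, 5, 6}) for embedding-based models, plus the classical pooled
  k-mer Jaccard comparison (`jaccard_kmer()`, default k = 6).

## Model tracks

**Gradient-boosted trees** (`train_gbdt()`, xgboost backend) consume the
TF-IDF features; `grid_search_cv()` performs the stratified 5-fold grid
search used for model selection. Training is single-threaded and seeded, so
results are reproducible bit for bit.

**CNN-LSTM** (`build_cnn_lstm()` + `train_sequence_model()`): a 1-D
convolution over the one-hot input, ReLU, max pooling, a masked LSTM over
the pooled feature sequence, and a task head (sigmoid or 15-way weighted
softmax). Defaults: 64 filters of width 12 (spanning typical plant TFBS
widths so filter-to-motif mapping stays meaningful), pool 4, 64 LSTM units.
The forward/backward passes are hand-derived C++ (RcppArmadillo); their
correctness is guarded by finite-difference gradient checks in the test
suite. Training follows the regime of the sequence classifiers: Adam,
at most 15 epochs, batches of 64, early stopping with 3-epoch patience on
the validation loss, best-epoch weights restored. Family-task losses are
weighted by inverse class frequency (`class_weights()`, `w_c = N/(K n_c)`),
the standard reading of proportional class weighting under imbalance.

Two recurrent-layer choices deserve comment, because the defaults differ
from the most literal topology reading:

* **Bidirectional recurrence (default).** With a forward-only LSTM read out
  at its last state, the 3' end of the sequence sits next to the readout
  while 5' features must survive hundreds of pooled steps. In practice the
  gradient — and therefore both the model's use of, and any attribution
  over, the 5' half — decays by many orders of magnitude, and the network
  collapses onto 3'-end shortcuts. Running the LSTM in both directions and
  concatenating the final states removes the asymmetry; `bidirectional =
  FALSE` restores the single forward pass.
* **Remember-biased forget gates** (initial bias 3): the same
  vanishing-path argument, applied within each direction.

**Windowed-embedding pooling** (`window_pool_embeddings()`): any
fixed-dimension embedder — the contract a transformer encoder satisfies —
is slid along the sequence in 510-base windows with stride 170 (one third of
the window), with a final window anchored at the sequence end; the window
embeddings are average-pooled into one vector. A small convolutional head
(`build_pooled_head()`: 32 filters of size 3, global max pooling, dense 32,
task output) is trained on the pooled vectors. The default embedder is a
deterministic k-mer-hash projector (`kmer_hash_embedder()`), which makes the
pooling path fully testable offline; any pre-trained DNA encoder satisfying
the contract can be plugged in instead.

## Evaluation and model comparison

`compute_metrics()` reports precision/recall/F1 with binary, support-
weighted, or macro averaging (the family task defaults to support-weighted;
macro is available). `stratified_kfold()` keeps per-fold class proportions
within one item. Two comparison tests mirror the study design:

* `wilcoxon_signed_rank()` — two-sided; zero differences dropped, average
  ranks on ties; for n ≤ 25 the p-value comes from the *exact* tie-aware
  null distribution of the signed-rank sum (dynamic programming over doubled
  ranks), above that from the tie-corrected normal approximation. The
  two-sided choice is deliberate where the study direction is unstated.
* `friedman_nemenyi()` — the Friedman chi-square on within-row ranks,
  followed (only when Friedman rejects at α = 0.05, the conventional gate)
  by Nemenyi pairwise p-values from the studentized-range distribution of
  mean-rank differences.

## Explainability layer

* `tree_shap()` — exact TreeSHAP attributions for the boosted ensemble in
  margin space; additivity is exact and the test suite checks equality with
  brute-force coalition Shapley values on small ensembles.
* `model_agnostic_shap()` — permutation-sampling Shapley estimates for any
  predictor, averaging each permutation over a background sample.
* `expected_gradients()` — integrated gradients from the all-zero
  (absent-base) baseline in logit space for the CNN-LSTM; additivity holds
  up to quadrature error, relative to the zero input of the same length.
* `perturbation_importance()` — each named feature column is replaced by
  uniform draws on `[0, max(F_i)]` over 5 random iterations (the default)
  and the mean F1 drop reported.
* Positional aggregation: `positional_track_onehot()` (per-position sum of
  squared channel attributions) and `positional_track_kmer()` (mean over
  all tokens covering a position). k-mer-level aggregation
  (`aggregate_kmer_importance()`) takes the *mean* attribution per distinct
  k-mer — a sum would confound frequency with effect — and min-max scales
  the positive and negative groups separately to [0, 1] and [−1, 0].
* Anchoring: `find_tata()` scores the degenerate TATAWA pattern PWM-style
  inside the central 20–80% of the sequence (an offline stand-in for an
  external promoter predictor; anchor files override it), the TSS defaults
  to TATA + 30 bp (canonical spacing), and `center_tracks()` windows tracks
  to anchor ± flank and takes per-column medians, without smoothing (a
  smoothing flag exists but defaults off, since the source analysis does
  not state any).
* `assemble_consensus()` chains overlapping important k-mers (exact-match
  overlap of at least k − 2 positions at the best relative offset) and
  stacks same-offset variants into bracket classes, e.g.
  `c("TATAAA", "TATATA")` → `TATA[AT]A`.
* CNN filters: `extract_filters()` pulls the first-layer filters;
  `normalize_filter()` applies `exp(λ·S/max(S))` with λ = 3 and the global
  matrix maximum (per-column maxima optional), then column-normalises for
  PWM export; `write_meme()` emits MEME minimal format and `match_motifs()`
  is the internal matcher (best mean per-column Pearson correlation over
  offsets and both orientations, overlap ≥ 5). It reports raw correlation
  scores, not E-values — E-value calibration belongs to external motif
  suites.

## Edge tetramer analysis

`edge_tetramers()` tallies exact (first 4, last 4) base pairs;
`assign_canonical()` corrects 1-base annotation shifts (candidates: identity,
`T`-prepended 5' shift, `A`-appended 3' shift, or both; the winner maximises
canonical TG/CA presence then edge complementarity, identity wins ties; no
2-bp shifts); `summarize_edges()` aggregates the top-5 pairs per canonical
pair with integer-rounded percentages over the summarized counts (the top-5
scope matches how such tables are printed). `complementarity()` counts
positions at which the 3' tetramer equals the reverse complement of the 5'
tetramer.

## The synthetic generator

`generate_dataset(synthetic_spec())` emulates the study conditions at desk
scale: positives of 300–3000 bp carrying superfamily-specific terminal
tetramers (Copia TGTT..AACA, Gypsy TGAT..ATCA), a TATAWA box at 45% of the
length (LTR promoters carry a centrally positioned TATA box), and per-family
planted PWM motif instances (15 families, 3 motifs each from disjoint
consensus pools, 2 instances per motif, width 12, consensus probability
0.95); negatives follow the negative-set recipes, with the Markov class
trained on the positives grouped by family. Every planted coordinate is
recorded in a truth table, and regeneration under the same seed is
byte-identical.

Width 12 and consensus 0.95 were chosen so that the default scanner
(`rel_threshold = 0.8`) recovers ≥ 95% of planted instances while keeping
its false-positive rate low enough that feature tables measure signal, not
noise. `difficulty_sweep()` interpolates planted-instance fidelity toward
background along a square-root profile of the strength parameter — a linear
PWM interpolation collapses the midpoint to near-background fidelity for a
range-threshold scanner, leaving nothing between "chance" and "easy" —
while the motif dictionary itself stays at full information (the dictionary
is the analysis input; the sweep degrades the data, not the analyst's
knowledge).

What the generator does *not* emulate: nested insertions, target-site
duplications, solo-LTR genesis, intra-family sequence divergence structure,
or genome-scale composition heterogeneity. Tests passing on this generator
demonstrate that the pipeline recovers planted structure of the stated
kinds; they do not certify performance on real annotations.

## Desk-scale problem sizes and observed behaviour

The package's acceptance tests exercise the pipeline on a fixed-seed
dataset of 2000 positives + 2000 negatives, split 70/10/20 and stratified.
The TFBS track uses the 45 generator motifs (150 boosting rounds, depth 3);
the CNN-LSTM runs with 32 filters × width 12, pool 20, 32 LSTM units,
L_max = 3000 (lossless for these lengths) and learning rate 1e-2 — sizes
chosen as sensible desk-scale settings of parameters the interface leaves
configurable. Both tracks reach held-out F1 ≥ 0.9 under these conditions,
and mean F1 over three generator seeds is non-decreasing across the
(0, 0.5, 1) difficulty sweep.

On attribution tracks from the trained CNN-LSTM, the start- and
end-anchored median profiles rise orders of magnitude above the
far-from-signal background and the TATA-anchored profile peaks within a few
bases of the predicted box. One caveat is worth stating plainly: the TATA
peak's *amplitude* is modest (~1.3–2× background) because, with family
motifs and edge tetramers available, the classifier does not need the TATA
box; fixtures engineered to force TATA reliance (conjunction class rules)
are not reliably learned by this architecture at a few thousand training
sequences. The TATA signal here is therefore assessed by localisation, not
amplitude.

## Known limitations

* The greedy identity clustering computes exact global alignments behind a
  shared-k-mer screen; it matches CD-HIT's greedy semantics at desk scale
  but is not engineered for hundreds of thousands of sequences.
* The internal TATA heuristic is a stand-in for a real promoter predictor;
  anchor files from external tools take precedence when supplied.
* The embedding track ships with the k-mer-hash projector only; transformer
  embedders must be supplied by the user through the embedder contract.
* Family-task experiments at desk scale use few sequences per family;
  the family head is exercised for correctness (shapes, losses, weighting),
  not benchmarked for accuracy.
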