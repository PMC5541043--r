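---
title: "Comparing hierarchical music segmentations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing hierarchical music segmentations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierseg)
```

## The problem

Listeners perceive musical structure at several time scales at once: a rock
song divides into verses and choruses, each of which divides into phrases.
Annotation corpora therefore store *hierarchical* segmentations — an ordered
sequence of flat labeled partitions of the timeline, coarse to fine. Two
annotators of the same recording frequently disagree, and the disagreement
can be *superficial* (they carved the same analysis at different depths, or
used different label names) or *fundamental* (they heard different
structures). Flat agreement metrics compare one level against one level and
cannot tell these apart. This package scores whole hierarchies against each
other, and provides the surrounding apparatus: flat baselines, an acoustic
correlation pipeline, corpus-scale evaluation tools, and synthetic
generators that make everything testable without corpus downloads.

## The hierarchical agreement model

A flat segmentation of a track of duration $D$ is a map $S:[T]\to Y$ from
sampled time frames to labels. A hierarchy $H=(S_0,S_1,\dots,S_m)$ stacks
$m$ stored levels; the implicit level $S_0$ assigns a single label to the
whole track and is never stored. For frames $u,v$ the **meet**

$$M(u,v\mid H)=\max\{k: S_k(u)=S_k(v)\}$$

is the deepest level at which the two frames share a label (0 when only the
implicit level matches). The meet induces a partial order on pairs of
frames: deeper meets mean "more similar under this analysis". The levels are
*not* assumed nested; the maximum ranges over all stored levels
independently, so a finer level may reunite frames the coarser level
separates.

Two hierarchies are compared through ordered triples of pairwise-distinct
frames. The comparison set

$$A(H)=\{(t,u,v): M(t,u\mid H) > M(t,v\mid H)\}$$

collects every ranking judgment the annotation makes: "$u$ is more similar
to $t$ than $v$ is". Ties contribute nothing. Then

$$\text{L-precision} = \frac{|A(H^R)\cap A(H^E)|}{|A(H^E)|},\qquad
  \text{L-recall} = \frac{|A(H^R)\cap A(H^E)|}{|A(H^R)|},$$

and the **L-measure** is their harmonic mean. Because only the *order* of
meet values matters, the scores are invariant to bijective relabeling within
any level, to duplicating a level, and in general to any strictly monotone
transformation of one hierarchy's meet values — exactly the superficial
disagreements the flat metrics confound. These invariances are enforced as
property tests over seeded random hierarchies.

Both flat baselines operate on a single level pair: frame-pairwise
precision/recall over the sets of identically-labeled frame pairs, and the
normalized conditional entropy (NCE) over/under-segmentation scores from the
joint frame-label distribution. All three families return a
precision-like score, a recall-like score and their harmonic mean, with the
0/0 convention that an empty denominator yields 0 (with a warning) — so a
degenerate single-label annotation scores 0 even against itself, which is a
deliberate choice: such an annotation expresses no ranking judgments to
agree with. For NCE, a singleton label set makes the corresponding
normalized entropy 0 and the score 1: a one-label estimate cannot be
over-segmented. The NCE scores are invariant to the logarithm base since the
numerator and the $\log|Y|$ normalizer scale together.

### Counting triples without cubic work

$|A(H)|$ naively costs $O(T^3)$; at the conventional 10 Hz sampling a
five-minute track has $T=3000$ and $2.7\times10^{10}$ triples. For each
anchor frame $t$ the package instead forms the joint histogram of the pair
of meet-value rows $(M^R[t,\cdot], M^E[t,\cdot])$ and counts concordant
value pairs from shifted cumulative sums, giving
$O(T(T + d_R d_E))$ overall for depths $d_R,d_E$. The equivalence with
brute-force enumeration is checked exhaustively on hundreds of random grids
with $T\le 40$ in the test suite. Counts are accumulated in doubles because
they overflow 32-bit integers near $T=3000$.

### Frame sampling conventions

Segments are half-open $[\text{start}, \text{end})$: a boundary instant
belongs to the segment on its right. A hierarchy of duration $D$ sampled at
rate $r$ produces $\lceil Dr\rceil$ frames at times $i/r$. The structural
metrics default to 10 Hz; the acoustic pipeline uses 4 Hz (matrices at the
native ~43 Hz frame rate would be prohibitively large). Scores depend
mildly on the rate; all reported values fix the defaults. When two
annotations of one recording disagree about the duration, both are
truncated to the shorter span (with a warning beyond a 1 s tolerance, and a
hard error when the ratio exceeds 2): truncation never fabricates
agreement, whereas padding with invented labels would. Input files with
boundary jitter up to 0.01 s between consecutive segments are repaired by
snapping to the midpoint; anything larger is treated as a corrupt file, not
guessed at.

## The acoustic correlation pipeline

When two annotations disagree fundamentally, one explanation is that the
annotators attended to different acoustic attributes. The pipeline reduces
each annotation to a 4-vector of correlations with feature self-similarity:

1. **Features** from 22,050 Hz mono audio, hop 512 (~43 Hz): tempo
   (384-lag Hann-windowed autocorrelation of the onset strength envelope,
   columns peak-normalized), rhythm (scale-transform magnitude of the tempo
   columns, 33 bins), chroma (12 pitch classes from a 36-bin-per-octave
   log-frequency filterbank over C1–C8, frames peak-normalized), and MFCC
   (first 20 coefficients). All are linearly interpolated to 4 Hz; chroma
   and MFCC are time-delay embedded with their two previous frames (36 and
   60 rows) to stabilize local similarity.
2. **Self-similarity**: $G[u,v]=\exp(-\lVert X[u]-X[v]\rVert^2/\sigma)$ with
   $\sigma$ the mean over frames of the median squared distance to all
   frames (self included, as the estimator is written). This bandwidth makes
   $G$ invariant to global feature rescaling.
3. **Correlation**: meet matrix and each $G$ are centered and scaled to unit
   Frobenius norm (an idempotent operation, applied exactly once per
   matrix); the Frobenius inner products give the z-vector
   $z(M)\in[-1,1]^4$ over (tempo, rhythm, chroma, MFCC).
4. **Distance**: $\delta = (z^R-z^E)^\top W^{-1}(z^R-z^E)$ with
   $W_{ij}=\langle \hat G_i,\hat G_j\rangle$. The whitening discounts
   directions in which features are mutually correlated (tempo and rhythm
   especially). When $W$ is near-singular (reciprocal condition number
   below $10^{-8}$ — e.g. duplicated features) the Moore–Penrose
   pseudo-inverse is substituted, with a message.

$\delta$ is symmetric, zero for identical annotations, and depends on the
annotations only through their meet matrices.

### Numerical choices in the feature extractors

Choices the construction leaves open were fixed once, for determinism and
testability:

* Onset strength is the band-average of the half-wave-rectified first
  difference of the log-power 128-band mel spectrogram (the standard
  spectral-flux construction); log-power floors at $10^{-10}$ (−100 dB) so
  silence stays finite, and digital silence propagates to all-zero tempo
  columns with no normalization applied.
* The autocorrelation windows are zero-padded at the signal edges, computed
  by FFT with padding to at least twice the window to avoid circular
  wrap-around, and clamped at 0 (the exact autocorrelation of a
  non-negative envelope is non-negative; FFT round-off can produce
  $-10^{-17}$).
* The scale (Mellin) transform resamples each 384-lag column on a geometric
  grid of 512 points from the minimum lag $t_0=0.5$ frames, multiplies by
  the measure factor $\sqrt{\text{lag}}$ ($e^{u/2}$ in log-lag $u$ — the
  term that makes the transform magnitude invariant to lag-axis scaling,
  i.e. to tempo), takes the DFT, and keeps the $\lfloor 64/2\rfloor+1=33$
  non-negative scale bins. The scale meaning of bin $k$ depends only on the
  total log-lag range, not on the grid density, so the grid size controls
  aliasing error only; 512 points keeps the worst-case grid spacing near
  the maximum lag at a few frames. The package's own oracle for this design
  is behavioral: click tracks at 100 and 150 BPM must be more similar to
  each other in rhythm space than either is to noise.
* Chroma aggregates STFT bin energies (4096-point transform) onto the
  log-frequency axis by nearest-bin assignment, 3 bins per semitone over
  C1–C8, then sums within pitch classes. This is a filterbank
  approximation rather than a true constant-Q transform; its contract here
  is pitch-class correctness (a 440 Hz tone must land on A), not bin-exact
  equality with any particular CQT implementation.

Because no audio-file reader is part of the package, the extractors take
numeric waveform vectors; tests synthesize clicks, sines, DC and noise
directly.

## Corpus-scale evaluation

`corpus_scores()` walks every unordered annotator pair of every track (all
10 pairs of a 5-annotator track) and emits a long tibble of all metric
families — the L triple, the per-level pairwise and NCE triples, and the
across-level max/min of pairwise F. It is order-independent in the manifest
and skips unreadable annotations with a warning rather than aborting a
corpus run. `quadrant_analysis()` splits a paired score scatter along the
per-axis medians; points exactly on a median line go to the lower half, and
fractions are reported both unconditionally and conditioned on an x-half,
matching statements of the form "of the pairs below the median flat score,
this share also falls below the median L-measure". `ks_statistic()` is the
two-sample Kolmogorov–Smirnov statistic (via `stats::ks.test`; an ECDF
enumeration serves as the cross-check in the tests), used to compare an
algorithm's score distribution against the inter-annotator distribution —
distributions are pooled per annotation pair, not averaged per track first.
`bootstrap_ci()` is the seeded percentile bootstrap.

## What the synthetic generators emulate — and what they do not

`random_hierarchy()` draws per-level boundaries from a Poisson process
(defaults: 180 s tracks, depth 2, 4 boundaries/minute/level, 5 labels per
level — typical of popular-music corpus annotations) with labels uniform
and adjacent repeats allowed. Nested generation (deeper levels keep all
parent boundaries) is the default because real coarse/fine annotations are
approximately nested; a non-nested mode exercises the max-over-levels meet
semantics. Boundaries closer than 50 ms to a neighbor are dropped so every
draw passes validation. `perturb_hierarchy()` applies one of five targeted
edits (label permutation, level duplication, fresh-label refinement,
boundary jitter, label-reassignment noise), each probing a specific metric
invariance. `planted_features()` maps each deepest-level label to a random
Gaussian prototype column plus noise, so feature self-similarity exhibits
exactly the block structure that structured audio produces, at the same
output dimensions as the real extractors after preparation.

The δ-vs-L experiment in the acceptance suite generates 50 tracks in which
annotator 1 tracks the planted (feature-correlated) structure closely
(0.5 s jitter, 5% relabel noise) while annotator 2 diverges by a per-track
severity (relabel fraction uniform on $[0, 0.7]$). This asymmetry
operationalizes the mechanism under study — disagreement driven by
attention to different cues — and yields a strong negative rank correlation
between δ and L. An earlier symmetric design (both annotators perturbed
equally) was discarded: at high severity both z-vectors collapse toward
zero *together*, so their difference, and hence δ, stops growing and the
relationship washes out.

These generators emulate the geometry of real annotations, not their
content: there is no genre structure, no annotator-specific style, no
harmonic or metrical coherence in the planted features, and label
vocabularies are uniform. Passing tests therefore demonstrate the metrics'
mathematical behavior and the pipeline's correctness, not that real
annotator disagreement has any particular distribution.

## Problem sizes and defaults used by the test and acceptance suites

Oracle equivalence runs 200 random grid pairs at $T\le40$, depth $\le4$;
the invariance suite runs 100 seeded cases per property on 15 s hierarchies
at 10 Hz; the δ–L simulation uses 50 tracks of 60 s at 4 Hz (10 Hz for L),
with a 2000-permutation sign test; bootstrap coverage uses 1000 replicates
of $n=100$ normal samples with 500 resamples each. The per-replicate sample
size $n=100$ was chosen because the percentile bootstrap's finite-sample
undercoverage at small $n$ is a property of the estimator, not of the
implementation under test.

## Known limitations

* Like all label-agreement metrics in this family, the L-scores cannot
  distinguish adjacent repetitions (`a a`) from one long segment (`A`), and
  variant markers (`A'`) are simply distinct labels — so repetition and
  variation cues are invisible. Hierarchies with very low label diversity
  legitimately receive near-zero scores against any annotation, including
  near-copies of themselves.
* Scores are computed on a sampled frame grid, so they inherit a mild
  dependence on the frame rate and on boundary placement within a frame.
* The chroma front end is a filterbank approximation of a constant-Q
  analysis, and several spectral-flux details are fixed by convention;
  z-vectors and δ values can shift at the second decimal under equally
  defensible alternative choices.
* δ explains disagreement only through the four implemented descriptors;
  annotations keyed to cues outside them (lyrics, instrumentation changes
  invisible to MFCCs) will look "uncorrelated" acoustically.
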