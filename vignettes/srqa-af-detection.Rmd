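---
title: "Symbolic recurrence analysis of RR intervals for AF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic recurrence analysis of RR intervals for AF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srqafib)
```

## The problem and the model

Atrial fibrillation (AF) disorganizes the timing of ventricular beats:
RR intervals that are smooth and quasi-periodic in sinus rhythm become
irregular and close to random. `srqafib` detects this change in short,
fixed-size windows of beats using *ordinal* information only — the
relative ordering of consecutive intervals — which makes the method
insensitive to the absolute scale of the signal, to monotone distortions
and to many non-stationarities, and leaves almost nothing to preprocess.

### Symbolization

For an embedding dimension $m$, each $m$-history
$\bar{x}_t = (x_t, \dots, x_{t+m-1})$ of a window of $T$ intervals is
assigned the unique permutation $\pi = (i_1, \dots, i_m)$ of
$\{0, \dots, m-1\}$ with
$x_{t+i_1} \le x_{t+i_2} \le \dots \le x_{t+i_m}$, ties resolved by
ascending offset. The tie rule is implemented as a stable sort of
(value, offset) pairs, so it is exact, not an epsilon convention; a
fully tied history maps to the identity pattern. The window becomes a
sequence of $n = T - m + 1$ symbols from the $m!$ element symmetric
group, indexed lexicographically — for $m = 3$:
$(0,1,2) = 0, (0,2,1) = 1, (1,0,2) = 2, (1,2,0) = 3, (2,0,1) = 4,
(2,1,0) = 5$.

For symbol frequencies to be statistically distinguishable, each of the
$m!$ patterns should be expected at least 5 times under independence,
i.e. $5\,m! \le w$. `max_embedding_dimension()` applies this rule; a
30-beat window admits at most $m = 3$, which is the default everywhere.
Larger $m$ is available but `build_dataset()` refuses an inadmissible
pair unless explicitly overridden.

### Symbolic recurrence and its quantification

Histories $t$ and $s$ are *symbolic recurrent* when they carry the same
symbol. The package stores the $n \times n$ matrix of shared symbols
(`recurrence_matrix()`), from which:

* $SRR = n^{-2}\sum_{t,s} SR_{ts}$ and $SRR(\pi)$, with
  $SRR = \sum_\pi SRR(\pi)$ exactly. The main diagonal is part of the
  printed sums, so $SRR \ge 1/n$; it is excluded only from
  diagonal-line counting, where it would contribute a trivial line.
* Diagonal lines (length $\ge 2$, both triangles, symbols may vary
  along a run) mark repeated symbol sequences; determinism is the
  fraction of recurrence mass on them,
  $D = \sum_d d\,n(d) / (n^2 SRR)$.
* Vertical lines in $SR(\delta)$ mark persistence of one pattern. For
  $m = 3$ only the monotone patterns $(0,1,2)$ and $(2,1,0)$ can occur
  twice in a row, so vertical measures are computed for those two:
  the trapping time $\bar{v}$ (mean vertical length), the fraction of
  the symbol's recurrence mass on vertical lines, and the entropy of
  the vertical length distribution. Each non-empty column of
  $SR(\delta)$ shows the same runs — the runs of $\delta$ in the symbol
  sequence — so the implementation counts those runs once and
  multiplies by the number of $\delta$-columns; the test suite checks
  this against a cell-by-cell matrix scan.
* Shannon entropies of the line-length distributions are in nats.
  The base is a free choice here — any base rescales a covariate by a
  constant, which the logistic coefficients absorb.

Degenerate structures never produce missing values: an empty line
distribution has mass 0, trapping time 0 and entropy 0 by convention,
so every window yields a complete covariate row.

One covariate has no printed closed form in the source material: the
"vertical line rate" of a symbol. The package defines it as
$\sum_v v\,n(v) / (n^2 SRR(\delta))$ — the laminarity-style mirror of
the determinism formula, i.e. the fraction of the symbol's recurrence
mass lying on vertical lines — and documents it as a convention.

### Windowing, features and the classifier

Records are cut into consecutive, non-overlapping windows of exactly
$w$ beats (trailing remainder dropped; no sliding in this version). A
window is AF when *strictly more than half* of its beats are annotated
AF; rhythms other than AF (sinus, flutter, junctional) all count as
non-AF, and windows spanning rhythm transitions are kept and labelled
by the same beat-count rule. Each window contributes 18 covariates: the
six $SRR(\pi)$, $D$, $ent(d)$, the two vertical-mass fractions, two
vertical entropies and two trapping times, and four RR statistics —
mean, median, the coefficient of variation $CV = s/\bar{RR}$ (sample
standard deviation, $n-1$ denominator; the usual estimator, chosen
because the source formula names only "standard deviation") and
$VMe = \sum_i |RR_i - Me(RR)| \,/\, \sum_i RR_i$ (even-length median =
mean of the central pair).

The classifier is plain maximum-likelihood logistic regression — no
regularization, since Wald p-values are part of the output — fitted by
IRLS with tolerance $10^{-8}$ and at most 100 iterations
(`stats::glm`). Zero-variance covariates are dropped with a warning;
(quasi-)separated data are flagged, the last-iterate coefficients kept,
and the model marked non-converged because the Wald inference is then
unreliable (predictions remain usable, which is all cross-validation
needs). The decision threshold sweeps the fixed grid
$\tau \in \{0, 0.001, \dots, 1\}$ with the strict rule "AF when
$p > \tau$", and minimizes the squared distance
$FPR_\tau^2 + (1 - Se_\tau)^2$ to the ideal corner; ties take the
smallest $\tau$, for determinism. Evaluation reports the confusion
counts, $Se$, $Sp = 1 - FPR$ and $ACC$.

Cross-validation is stratified by label (default $K = 10$), keeping
class balance in every fold; fold assignment is seeded and reproducible.
Per fold, the threshold is selected on the *training* folds' ROC —
selecting on the held-out fold would leak information into the reported
scores, so test-fold selection was rejected even though it can make
per-fold thresholds differ from a single full-data threshold. Grouped
assignment of whole records to folds is available (`by_record = TRUE`)
for when per-patient independence matters; it is not the default
because stratification is what keeps small folds balanced. Quartiles
(P25/median/P75) use linear interpolation between order statistics
(`quantile(type = 7)`).

## The synthetic generator

`gen_ns_record()` draws
$RR_t = 800 + 40 \sin(2\pi t / 4) + \varepsilon_t$,
$\varepsilon_t \sim N(0, 10^2)$ (ms): a 75 bpm rhythm with a 4-beat,
40 ms modulation coarsely mimicking respiratory sinus arrhythmia — the
period is deliberately short so that non-monotone ordinal patterns
occur and all six $SRR(\pi)$ covariates carry signal — plus small
beat-to-beat noise. `gen_af_record()` draws i.i.d. uniform intervals on
400–1100 ms, the simplest surrogate of the "random sequence of beat
intervals" character of AF; its symbol distribution is exchangeable,
hence uniform over the six patterns, which gives the test suite an
analytic target ($SRR \to 1/6$). An optional first-order correlation
(up to 0.3) is available through a Gaussian copula that preserves the
uniform marginal. `gen_mixed_record()` concatenates labelled segments
to emulate paroxysmal AF and exercise the majority-labelling rule
across transitions. All generators take explicit seeds, use R's default
Mersenne-Twister stream, and restore the caller's RNG state.

These surrogates reproduce the *statistical contrast* the method relies
on — ordinal regularity vs. ordinal randomness, low vs. high dispersion
— but not real electrophysiology: no ectopic beats, no annotation
noise, no gradual rate drift, no flutter-like intermediate regimes, and
a between-class separation far larger than between real NS and AF
windows. Consequently the synthetic study is a correctness check of the
pipeline (its cross-validated accuracy should be near-perfect, and is),
not an estimate of clinical performance; real-data performance must
come from the external PhysioNet validation path
(`scripts/afdb_validation.R`), which is optional and needs a manual
download.

## Problem sizes and reproducibility

The packaged synthetic study uses 400 windows per class per window size
$w \in \{30, 60, 120, 200\}$ with stratified 10-fold cross-validation —
large enough that fold medians are stable to well under a percentage
point, small enough to run in about a minute. Property-style tests run
the line-structure oracle on 1000 random symbol sequences ($n \le 12$),
recover known logistic coefficients at $n = 5000$, and check the Wald
type-I error over 200 null replicates. All stochastic tests fix their
seeds.

## Known limitations

* Ordinal features discard amplitude information by design; rhythms
  that disturb amplitude but not ordering are invisible to the SRQA
  block (the RR dispersion covariates partially compensate).
* Lag-1, univariate embedding only; no delay embedding or multivariate
  symbolization.
* No ectopic-beat filtering: annotation quality is taken as given.
* Decisions are per window; no per-patient aggregation or smoothing of
  consecutive window decisions.
* With 18 correlated covariates and well-separated classes, separation
  is common on small training sets; coefficients are then not
  interpretable even though classification remains accurate.
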