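---
title: "Segment-wise detrended-fluctuation artifact reduction for capacitive ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise detrended-fluctuation artifact reduction for capacitive ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecgclean)
```

## The problem

Capacitive (non-contact) ECG couples the cardiac potential through clothing
into electrodes in a seat or bed.  The useful signal is small — R peaks of a
few tenths of a volt up to a couple of volts after amplification — and any
body movement changes the electrode capacitance, producing two artifact
families:

* **coarse artifacts**: bursts of several volts lasting a fraction of a
  second to seconds, dwarfing the ECG;
* **slow-changing artifacts**: disturbances of amplitude *comparable* to
  the ECG whose power lies mostly below 15 Hz.  Because the ECG's own
  spectrum occupies the same band, no linear filter separates them, and
  because their amplitude matches the ECG, no amplitude threshold does
  either.

The approach implemented here classifies fixed-length *segments* by how far
the signal's cumulative-sum profile deviates from a local straight line,
and eliminates (excludes, never interpolates) the segments identified as
artifacts.

## The statistic

For samples $x_k$, $k = 1,\dots,N$, the profile is
$Y(i) = \sum_{k \le i} (x_k - \langle x \rangle)$.  The profile is cut into
non-overlapping segments of $SL$ samples; each segment gets a least-squares
line subtracted, and is summarized by the root mean square of the
residuals, $F_D(j)$.  Intuition:

* within a coarse burst the profile jumps by the (large) local signal area,
  so $F_D$ is far above the record's typical value;
* where the raw signal is nearly constant on the segment scale (a
  slow-changing artifact much slower than $SL$), the profile is nearly
  linear and $F_D$ falls toward zero;
* ordinary ECG sits in between: each beat contributes a bump of profile
  area on the order of amplitude × QRS width × sampling rate.

The printed form of the fluctuation could be read as a mean of squares, but
the slow-artifact threshold below is derived as $\sqrt{0.01} = 0.1$, which
forces the RMS reading; we therefore default to RMS
(`form = "rms"`) and keep the mean-of-squares variant available
(`form = "mean_square"`) for sensitivity analyses.

Segment grids are *forward* (trailing remainder dropped) for long records.
For records under 10,000 samples the segmentation is repeated from the end
of the series (*bidirectional*), doubling the number of segments that feed
the threshold statistics; when $SL$ divides $N$ the two passes coincide and
the duplicates are deliberately retained (unbiased double-weighting rather
than an ad hoc dedup).  Elimination decisions are always made on the
forward grid, which tiles the record; end-aligned segments only contribute
to the $F_D$ statistics.  Samples after the last full segment are never
classified and are carried into the cleaned output unchanged.

## Presence criterion and thresholds

Reduction of coarse artifacts is gated on a presence criterion,
$(\max x - \min x)/2 - \sqrt{M} > 1$ with $M = \langle x^2 \rangle$ (all in
volts): sparse large spikes inflate the half-range while leaving the RMS
almost untouched, whereas dense symmetric swings raise both terms and
cancel.  The constant 1 is dimensional (1 V); a record in other units must
be converted first (`load_record(scale = ...)`).

The thresholds are derived from the record's own statistics:

$$TH1 = \Big(\big(\tfrac{\max x - \min x}{2}\big)^2 - M\Big)\, C\,
  \mathrm{median}(F_D) + \frac{SD(F_D) + SD(x)}{SD(F_D)\,SD(x)}\,C_1,
  \qquad TH2 = TH1/2, \qquad TH3 = 0.1 .$$

* $C$ (default 0.25, units $1/\mathrm{V}^2$) scales the data-driven part;
  its useful range is 0.15–0.35 and the package default is the midpoint.
  Raising $C$ raises $TH1$ and therefore never eliminates more coarse
  segments (when the squared-half-range term is positive, which holds for
  any record with coarse bursts).
* $C_1$ = 1 V is dimensional; doubling it shifts $TH1$ by exactly
  $(SD(F_D)+SD(x))/(SD(F_D)\,SD(x))$.
* $TH3$ is analytic, not data-driven: a segment deviating from its linear
  trend by at most 0.1 at every sample has RMS fluctuation at most 0.1
  regardless of $SL$ (`fluctuation_value(rep(0.1, SL)) == 0.1`).  It is
  exported as `TH3_SLOW`.
* The median and the unbiased ($n-1$) standard deviation are computed over
  *all* grid segments, artifact segments included — robustly for the
  median, deliberately for $SD(F_D)$, whose inflation by bursts shrinks
  the second term.

The elimination rules, applied to the forward segments:

1. if coarse artifacts are present, `F_D > TH1` ⇒ eliminate (*coarse*);
2. each immediate neighbour of a coarse segment is eliminated (*adjacent*,
   single hop) when the adjacency rule fires — see below;
3. independently, when $\mathrm{mean}(F_D) - SD(F_D) > TH3$, still-kept
   segments with $F_D \le TH3$ are eliminated (*slow*).  The guard protects
   low-amplitude records, where the legitimate ECG fluctuation is itself
   small, from wholesale elimination.

Ties always keep the segment (strict inequalities throughout); the
`F_D \le TH3` comparison is inclusive, which differs from a strict reading
only on a measure-zero boundary.

### The adjacency rule

The method's source material states the spill-over check two inequivalent
ways: prose compares the *neighbour's own* $F_D$ with $TH2$, while the
elimination pseudocode compares the *difference* between the coarse
segment's $F_D$ and its neighbour's with $TH2$.  These disagree in
practice.  A burst rarely ends on a segment boundary; the segment grazed by
the last few samples of a burst has modest $F_D$, so the own-value rule
almost never fires — it cannot, by construction, catch a low-fluctuation
sliver.  The difference rule fires for essentially every quiet neighbour of
a strong coarse segment (if $F_D(j) > TH1 = 2\,TH2$ and the neighbour is
quiet, the difference exceeds $TH2$), which matches the stated purpose of
the check — catching artifacts "partially spilling over" — and is
consistent with a method that eliminates roughly one neighbouring segment
per burst side.  We therefore default to the pseudocode's difference rule
(`adjacency = "difference"`) and keep the prose variant
(`adjacency = "own"`) as an option; both are exercised by the test suite
against an independent transcription.

### Degenerate inputs

A record with zero sample variance (or a single-valued fluctuation profile)
has undefined thresholds.  `compute_thresholds()` signals a dedicated
condition class; `reduce_artifacts()` converts it into an all-kept result
flagged `degenerate = TRUE` with a warning, so pipelines keep running.

## Online operation

`reduce_online()` buffers the first 50 s (configurable), computes thresholds
exactly as in batch — decisions inside the window equal the batch decisions
on that window by construction — and then, per arriving full segment:
updates the running signal mean (which re-anchors the whole profile),
appends the segment's $F_D$ to the ever-growing collection, recomputes all
thresholds and the presence criterion over everything seen, and classifies
the new segment.  A segment already emitted can be retroactively re-marked
*adjacent* when its successor turns out to be coarse.  Old fluctuation
values are never discarded: the update cadence is once per segment, and the
cost per segment is one pass over the data seen so far (quadratic overall,
but a 300 s record at 400 Hz still takes about a second).

## Binarized entropy

The binarized entropies operate on the differential bit code
$c_i = \mathbb{1}[x_{i+1} - x_i > 0]$ (ties encode 0; length $N-1$ — the
natural bound for a difference code).  Windows of $m$ bits at delay $\tau$
are read as integers, counted into a $2^m$-bin histogram, and word-to-word
similarity is resolved through the $2^m \times 2^m$ Hamming-distance matrix
with an integer tolerance $r$ — so the whole computation is
$O(N + 4^m)$ rather than the naive $O(N^2)$.  A non-integer $r$ is floored
with a warning (Hamming distances are integers).  Empty histogram bins
contribute nothing to the log-average ($0 \cdot \ln(\cdot) := 0$), and the
window counts use the code length $N' = N - 1$ in every denominator.

`bin_ap_en()` returns $\hat\Phi^m - \hat\Phi^{m+1}$ (natural logs), both
orders at the same $(r, \tau)$ on the same code.  `bin_samp_en()` excludes
self-similarity — each window's own occurrence is removed from the
numerator *and* denominator of its neighbour proportion — and reports
$-10 \log_{10}(\hat\Phi^{m+1}/\hat\Phi^m)$, a decibel-style ratio; base 10
is chosen precisely because of the $-10\log(\cdot)$ form.  The ratio is
undefined when $\hat\Phi^m = 0$ (e.g. any constant series, or $r \ge m$,
where every word pair is within tolerance) or non-positive; those cases
return `NaN` with a warning rather than an error, so feature pipelines see
a flagged missing value.  Both estimators are invariant to adding constants
or positively rescaling the signal — the property that lets them run on
artifact-laden records directly.

## The synthetic generator

`generate_cecg()` emulates the statistical structure of bed/car cECG
recordings, not their physiology:

* **ECG**: a fixed P-QRS-T template (five Gaussian bumps) placed at
  jittered RR intervals (70 bpm, 5% relative jitter by default), scaled so
  the R peak is `ecg_amp` (default 0.5 V), plus white measurement noise
  (SD 0.02 V).  No arrhythmias, no respiration coupling, no morphology
  variability.
* **Slow-changing artifacts** *replace* the ECG (they model intervals where
  an expert can find no R peaks): Gaussian noise spectrally confined to
  0.5–15 Hz by FFT masking, rescaled so its RMS matches the clean record's
  RMS times `slow_amp_ratio` (default 1 — "comparable amplitude").
  Defaults: 6 intervals of 3–8 s per 300 s record, an invented but
  plausible rate for posture-drift episodes.
* **Coarse artifacts** *superimpose*.  The default shape, `spike_train`,
  is a 0.7–2.5 Hz electrode-displacement swing carrying a ~20/s train of
  sharp biphasic spikes, rescaled to a peak amplitude drawn from 2–8 V;
  durations 0.2–2 s; 10 bursts per record.  The sub-3 Hz swing reflects
  the time scale of a body movement and is what carries the burst's
  profile area; isolated millisecond needles, by contrast, have nearly
  zero signal area and would be invisible to any integral-based statistic
  — they are not how movement artifacts present.  `step` (baseline jump)
  and `clip` (rail saturation) shapes are available for stress tests; note
  that the interior of a long clean step is *locally linear in the
  profile* and is a designed blind spot of the fluctuation statistic.
* **Ground truth**: R-peak indices and a typed partition of the record
  into `useful` / `coarse` / `slow` intervals.  R peaks inside artifact
  intervals are removed from the truth — matching the expert convention
  that a segment is useful only where R peaks can be read.
* **Bed protocol** (`protocol = "bed"`): short (5 s) movements at a 60 s
  cadence over the first half of the record, and a 120 s rest / 60 s
  movement / 120 s rest pattern in the second half.  The full pattern
  needs 360 s; shorter durations are refused.

Artifact intervals are placed uniformly at random without overlap
(rejection sampling; an infeasible artifact load is refused up front using
expected total durations).  All randomness flows through the single config
seed, and equal seeds give bit-identical records.

What passing tests on this generator do **not** show: performance on real
capacitive recordings, whose artifacts have richer morphology (drift,
saturation recovery, clothing-dependent coupling), whose ECG morphology
varies beat to beat, and whose expert annotations embody judgment the
R-peak-presence rule only approximates.

## Evaluation conventions

A segment's true label is *useful* iff it contains at least one
ground-truth R peak; interval labels serve as a cross-check only.  In the
confusion counts, *kept∧useful* = TP, *kept∧useless* = FP,
*eliminated∧useless* = TN, *eliminated∧useful* = FN; metrics with zero
denominators are reported as `NaN`, never silently as 0.  SNR is
$10\log_{10}(P_s/P_n)$ over useful vs everything-else samples.  pNN50 uses
the standard successive-difference definition (|ΔRR| > 50 ms); a looser
reading sometimes seen in applied work (RR > 50 ms) is reported alongside
as `pnn50_loose`.  RR intervals spanning an elimination gap are excluded
via the cleaned-to-original index map.  All sample indices in annotations,
masks and index maps are 0-based with half-open intervals, matching the
on-disk JSON/CSV formats; add 1 when indexing R vectors.

## Numerical choices and test scales

* Detrending fits positions $1..SL$ in closed form (simple OLS); residuals
  are invariant to affine reindexing, and orthogonality to the trend is
  verified to $10^{-9}$ in tests.
* Fluctuation equivalence against a brute-force transcription (explicit
  `lm()` fits) is asserted to $10^{-9}$ relative; binarized-entropy
  equivalence against a naive $O(N^2)$ pairwise oracle to $10^{-12}$, for
  all $m \le 4$, $\tau \le 3$, $r \le m$, $N \le 500$.
* The reduction pipeline is checked decision-for-decision against an
  independent step-by-step transcription on seeded synthetic records.
* The headline percentages (burst-segment elimination, useful-segment
  preservation) are pooled over 20 records of 300 s at 400 Hz — about two
  minutes of total synthetic signal per record at 600 segments each, a
  size chosen so the whole suite runs in well under a minute while keeping
  per-record segment counts in the hundreds.
* Record round-trips through the CSV/JSON formats are bit-exact (17
  significant digits on write).

## Known limitations

* Slow-changing artifacts at amplitudes truly comparable to the ECG have
  fluctuation values inside the ECG's own range; the $TH3$ rule only
  removes segments whose profile is almost exactly linear, so such
  intervals largely survive reduction.  This is a property of the method,
  visible in the worked example's specificity, and is the reason the
  approach is complemented by artifact-tolerant features (binarized
  entropy).
* A constant-offset (step) artifact is invisible between its edges, by
  construction of the statistic.
* Threshold quality degrades when bursts dominate the record so thoroughly
  that `median(F_D)` itself is an artifact statistic.
* The online mode is quadratic in record length (full profile refresh per
  segment); acceptable for minutes-long buffers, not for unbounded streams.
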