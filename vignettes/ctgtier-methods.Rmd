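---
title: "Methods: rule-based FHR classification and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based FHR classification and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgtier)
```

## The problem

During labor, cardiotocography (CTG) records the fetal heart rate (FHR)
together with uterine contractions. Clinicians read the tracing in terms of
four features — baseline rate, baseline variability, accelerations and
decelerations — and summarise each stretch of tracing with a rule-table
classification: the 3-tier NICHD scheme (Category I normal, II
indeterminate, III abnormal) or the Japanese/Parer 5-tier scheme (Level 1
normal through Level 5 most severe). The question such classifications are
meant to answer is whether the fetus is sliding toward hypoxia and
acidosis, which at delivery is measured directly in umbilical artery blood
as pH and base excess (BE).

`ctgtier` implements this whole chain as a reproducible pipeline: it
extracts the features from raw paired FHR/UC series, classifies each
10-minute segment of the last hour before delivery under both schemes, and
relates the per-segment classifications of a cohort to pH/BE at delivery
with nonparametric tests. Because real intrapartum cohorts are rarely
shareable, the package also contains a first-class synthetic cohort
generator, so every stage — including the signal-level feature extraction —
is exercised end to end by tests.

One deliberate deviation from clinical practice is baked in: published
cohort analyses of this kind rest on *visual* classification by an expert.
Here a deterministic feature extractor replaces the human. The rule tables
themselves are unchanged; everything upstream of them (artifact rejection,
baseline estimation, episode detection) follows standard guideline
definitions with every threshold exposed in `feature_config()`.

## Feature extraction

**Cleaning** (`clean_fhr()`). Samples outside 30–240 bpm are rejected, as
is the later sample of any >25 bpm sample-to-sample jump; missing runs
shorter than 15 s are bridged linearly, longer gaps stay missing. The
operation is idempotent. These are conventional CTG artifact rules; the
values are configurable because no single published standard fixes them.

**Baseline** (`estimate_baseline()`). An iterative trimmed mean: start at
the window median (the lower in-sample median, so a bimodal window starts
on an actual plateau), repeatedly average the samples within ±15 bpm of
the current estimate until it moves by <0.5 bpm, then round to the nearest
5 bpm as baselines are read clinically. The ±15 bpm trim excludes
acceleration/deceleration excursions without needing them segmented first;
a window with equal time on two plateaus converges to one plateau (the one
containing the lower median), never to their average. Windows with less
than 120 s of usable signal are indeterminate, propagate as missing
classifications, and drop out of frequency denominators.

Baseline classes are `<80`, `80–110`, `110–160`, `>160` bpm. The printed
ranges overlap at their joints; we resolve each shared boundary toward the
less alarming class (110 and 160 are normal, 80 belongs to 80–110).

**Variability** (`variability_amplitude()`). After excluding
acceleration/deceleration spans (padded by 10 s so the shallow episode
tails below the detection threshold do not masquerade as oscillation), the
window is cut into 60 s bins; each bin with ≥30 s of usable signal
contributes its peak-to-peak range, and the window amplitude is the median
bin range. Classes use the printed bins — undetectable ≤2, minimal 3–5,
moderate 6–25, marked ≥26 bpm — with real-valued amplitudes between
printed edges assigned to the neighbouring class they exceed ((2, 5]
minimal, (5, 26) moderate).

**Episodes** (`detect_accelerations()`, `detect_decelerations()`). An
episode is an excursion of ≥15 bpm from baseline sustained for ≥15 s (the
core), extended outward to its baseline-return points (|deviation| < 2
bpm); overlapping extensions merge, so spans are disjoint. Requiring the
*core* — not merely the excursion — to last 15 s keeps marked variability
(±17 bpm swings) from generating phantom decelerations. Typing follows
standard definitions: duration ≥120 s (and <600 s) is prolonged; else an
onset-to-nadir under 30 s is abrupt, hence variable; gradual decelerations
are early when the nadir is within ±18 s of the nearest contraction peak
and late when it lags the peak by more than 18 s. A gradual deceleration
with no contraction within 120 s of its nadir falls back to variable; a
nadir *leading* the peak by more than 18 s (an odd configuration the
timing rules do not cover) counts as early. Severity defaults — variable
severe iff nadir <70 bpm and duration ≥60 s; late severe iff depth ≥45
bpm; prolonged severe iff nadir <80 bpm; early always mild — are labelled
assumptions: published tables grade mild/severe without printing uniform
cut-offs, and the 45 bpm late-depth cut keeps a 30 bpm late dip mild, the
behaviour the grading convention implies.

**Contractions** (`find_contractions()`). The UC channel is smoothed with
a 30 s moving average; peaks are local maxima at least 15 units above the
resting tone (10th percentile), at least 120 s apart, higher peaks winning
ties. Decelerations of one kind are *recurrent* when they accompany at
least half of the contractions in the segment (minimum two contractions) —
the standard ≥50% definition applied at the 10-minute scale.

**Sinusoidal pattern** (`detect_sinusoidal()`). In 60 s windows stepped by
30 s (windows overlapping a detected deceleration are excluded), the
dominant spectral component within 0.02–0.2 Hz must lie in the sinusoidal
band 0.05–0.083 Hz (3–5 cycles/min), that band must hold ≥60% of the
reference-band power, and the oscillation amplitude (half peak-to-peak)
must be 5–15 bpm. The segment is sinusoidal when ≥80% of eligible windows
pass and no acceleration was detected. The short window is a deliberate
choice: with recurrent decelerations every ~3 minutes, longer windows are
almost never deceleration-free and the pattern would be undetectable in
exactly the tracings where it matters.

## The rule tables

`classify_3tier()` is a direct transcription of the NICHD table: Category
I requires a 110–160 bpm baseline, moderate variability, no late, variable
*or prolonged* decelerations and no sinusoidal pattern (early
decelerations and accelerations are irrelevant); Category III is a
sinusoidal pattern, or undetectable variability with recurrent late or
variable decelerations or bradycardia (<80 bpm); Category II is everything
else. Treating a prolonged deceleration as compatible with Category I
would contradict the 5-tier grid (where a severe prolonged deceleration on
an otherwise normal tracing scores Level 4), so prolonged blocks Category
I; this extension of the printed rule is deliberate and tested.

`classify_5tier()` looks the feature tuple up in a grid: rows are
variability classes (moderate and minimal sub-indexed by baseline class;
undetectable, marked and sinusoidal rows ignore the baseline), columns are
the eight deceleration columns (none, early, variable/late/prolonged ×
mild/severe). The printed grid leaves some cells blank. Blanks resolve by
copying the nearest printed cell to the left in the same row, else the
nearest to the right — a local rule that preserves the row's printed
monotone structure. Both the printed and the resolved grid ship as CSV
resources (`inst/extdata/five_tier_grid*.csv`) so the rule table is
auditable as data; a test re-derives the resolved grid from the printed
one. When several decelerations are present the *worst* is the one whose
cell value in the active row is highest, ties broken toward the rightmost
column — cell value, not column position, because rows are not monotone
left-to-right (in the >160 bpm row a severe late deceleration outranks a
mild prolonged one).

Two consequences of the tables are asserted by exhaustive enumeration:
any Category I segment maps to Level ≤2, any Category III segment to
Level ≥4; and for a fixed baseline class and deceleration column, minimal
variability never classifies below moderate.

## Segmentation and cohort analysis

The last hour before delivery splits into six windows `(d − 600k, d −
600(k−1)]` seconds, labelled 60 … 10 (minutes before delivery); a window
is analysed when the trace covers ≥80% of its samples. Outcomes are
grouped exactly as the clinical convention prints them: six lower-closed
pH bins (<7.0, [7.0,7.1), …, ≥7.4) and two BE bins split at −12 mmol/L
(−12 itself in the upper bin).

The test battery (`run_tests()`) mirrors the canonical analysis set: a
Friedman test of classification values across the six repeated segments;
Kruskal–Wallis across pH bins within each segment with Tukey HSD pairwise
contrasts after it; a Wilcoxon comparison of the two BE groups within each
segment; and Wilcoxon signed-rank tests of paired adjacent-segment
contrasts. Two statistical choices deserve flagging. First, the two BE
groups are independent samples, so a signed-rank test is not well defined
there; the package defaults to the rank-sum (Mann–Whitney) test and
offers `stats_config(be_test = "signed_rank")` only for same-size groups.
Second, Tukey HSD assumes interval-scaled responses and is applied here to
ordinal classification values because that is the analysis convention
being reproduced; treat its p-values accordingly.

All statistics are tie-corrected. For total sample sizes ≤8 the p-values
are exact permutation enumerations (group reassignments for
Kruskal–Wallis and rank-sum, sign flips for signed-rank, within-row
orderings for Friedman); larger samples use the chi-square/normal
approximations, which at those sizes are standard. The exact paths are
validated against independent brute-force enumerators in the test suite
(agreement within 0.005, usually exact).

## The synthetic cohort generator

The generator (`synth_config()`, `simulate_cohort()`) emulates a cohort
of 1,909 low-risk vaginal deliveries — the reference cohort size — with
three linked components.

**Level trajectories.** Per-segment 5-tier marginals default to the
reference cohort's printed frequency table (zero cells get mass 5e-4 so
the support stays complete). Subjects are coupled across segments by a
Gaussian copula with latent-severity correlation ρ = 0.6: segment scores
√ρ·z + √(1−ρ)·e_t are pushed through each segment's marginal cut-points,
so marginals are preserved exactly in expectation while ρ controls how
consistently a subject stays "bad". ρ = 0.6 was chosen once as a
realistic degree of within-subject persistence; it is not fitted.

**Grid-cell choice and trace rendering.** A target level is realised by
drawing one of its grid cells and synthesising 10 minutes of signal
embodying that cell: a baseline plateau inside the cell's baseline class,
band-spread multi-sine oscillation scaled to the variability class's
target peak-to-peak amplitude (1/4/15/34 bpm; a pure 4 cycles/min
sinusoid of 8 bpm amplitude for sinusoidal cells), deceleration episodes
of the cell's column placed on the rendered contractions (a single
mid-segment episode for prolonged columns), and Gaussian contraction
bumps every 150–210 s on the UC channel. Oscillation components sit
outside the 3–5 cycles/min band and fade inside deceleration episodes so
episode geometry stays crisp. Cell choice is uniform within a level with
one exception: the probability of the (moderate, 110–160, early) cell —
the only Level-2 cell that is still 3-tier Category I — is calibrated per
segment so the generator's implied 3-tier marginals
(`derive_3tier_marginals()`) match the reference Category frequencies.
Four grid cells cannot be embodied exactly: at bradycardic baselines
(65–70 bpm) the late-severe depth (≥45 bpm) and prolonged-mild nadir
(≥80 bpm) requirements collide with the 30 bpm artifact floor; their
rendered traces extract as the neighbouring severity column, whose grid
level is identical, so level-recovery is unaffected.

**Outcomes.** pH and BE follow a linear-additive model in (level − 1)
with segment weights growing toward delivery (pH: intercept 7.38, weights
0.004…0.012, σ = 0.055; BE: intercept −3 mmol/L, weights 0.2…0.6, σ =
2.6), clipped to physiological bounds. This is the smallest model that
reproduces the two directional findings the pipeline must detect — worse
classes ⇒ lower pH/BE, association strengthening toward delivery — and
whose pooled mixture lands on the reported headline bin frequencies
(≈1% of subjects below −12 mmol/L BE, ≈57% in the [7.3, 7.4) pH bin). It
is a directional stand-in, not an estimate of any real cohort: no
regression of outcomes on classifications has been published to fit
against.

**What passing tests do and do not show.** Rendered traces are clean by
construction: stationary plateaus, stereotyped episode shapes, no
maternal-heart-rate contamination, no signal loss beyond what tests
inject. Round-trip recovery (≥95% of segments re-classified to their
target level; in practice >99.9%) therefore validates the internal
consistency of rendering, extraction and rule tables — it says nothing
about accuracy on real, messy tracings, where baseline drift and signal
loss dominate the error budget. Similarly, the generator gives sinusoidal
cells the same within-level weight as any other cell, so its implied
3-tier Category III frequency near delivery (≈2%) is higher than a real
low-risk cohort's (≈0.1%); recovery experiments compare against the
generator's own derived marginals, so this is a realism limitation, not
an inconsistency.

## Numerical choices and problem sizes

Rendering and analysis default to 4 Hz, the usual CTG monitor output
rate; any uniform rate ≥1 Hz is accepted and 1 Hz is a useful smoke
variant (the packaged test suite runs its full-cohort recovery experiment
at 1 Hz, n = 1909; `scripts/acceptance.R` runs the 4 Hz default, which
completes in a few minutes on one core). The baseline iteration converges
in well under 50 iterations on any window the trim rule does not empty;
an emptied trim set (possible only on pathological bimodal windows)
terminates the iteration at the current estimate. Exact permutation
enumeration is capped at total n = 8 (and (k!)^n ≤ 5·10^5 for Friedman);
beyond that the tie-corrected asymptotics take over. All randomness flows
from one seed set at the cohort level, so generation, rendering and
outcomes are reproducible byte-for-byte.

## Known limitations

- Automated extraction replaces expert visual reading; agreement with a
  human reader on real tracings is out of scope and unmeasured here.
- No maternal-heart-rate contamination detection, no adaptive filtering,
  no STV/LTV or computerized (Dawes–Redman-style) indices.
- The outcome model is synthetic and linear; it encodes directions and
  headline bin frequencies, not clinical effect sizes.
- Tukey HSD on ordinal values and the BE-group test naming follow the
  reproduced analysis convention rather than first-principles statistics;
  both are flagged where they occur.
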