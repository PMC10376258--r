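---
title: "Empirical feature selection for paretic-EMG gesture decoding: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical feature selection for paretic-EMG gesture decoding: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snailfs)
```

## The problem

Myoelectric pattern recognition for stroke rehabilitation must decode
movement intent from the paretic arm with a handful of surface electrodes.
Post-stroke EMG is heterogeneous — spasticity, muscle weakness, crosstalk
and subject-specific signal distortions — so feature sets tuned on healthy
or amputee data transfer poorly, and the choice of features dominates
classifier performance. `snailfs` takes the empirical route: score *every*
small feature combination by cross-validated classification accuracy, then
grow larger sets from the empirically superior ones instead of trusting
domain priors.

The pipeline is: synthesize (or read) multi-channel recordings, filter and
normalize, cut peak-locked gesture windows, extract a 127-feature
multi-domain bank, brute-force all 1–4-feature combinations under a
subject-wise SVM protocol, and amalgamate winners into 5–20-feature sets
with the SNAiL spiral search. A statistical harness compares selected sets
against eight canonical baselines.

## Synthetic cohort: what it emulates and what it does not

Clinical stroke EMG is not redistributable, so the generator supplies a
statistical stand-in shaped like the target recordings: 19 subjects,
5 bipolar channels (two forearm-flexor, two extensor, one thenar) at
1000 Hz with a 16-bit-scale dynamic range, six hand gestures (fist, pinch,
wrist flexion, wrist extension, palm open, thumb) repeated 10 times each,
plus rest — seven classes in all.

The signal model is the standard surface-EMG surrogate: zero-mean Gaussian
noise band-limited to 20–300 Hz (matching the analysis band), amplitude
modulated by a smooth Hann envelope per burst. Class identity lives in a
per-channel activation profile: each gesture activates a distinct on/off
pattern across channels (a 3-bit pattern cycled over the montage with a
small deterministic taper, so any montage of three or more channels keeps
all six gestures and rest geometrically distinct). Rest is a low-amplitude
baseline (`rest_amp`, default 0.08 relative units) running through the
whole recording; rest-class windows are sampled from inter-burst spans.

Tunable knobs, with defaults chosen once as a realistic mid-impairment
cohort:

* `severity` (default 0.8, per subject in [0, 1]) linearly attenuates each
  gesture profile toward the rest profile by `1 - severity`. Severity 0
  makes all seven classes statistically identical (a built-in chance-level
  control); severity 1 with no crosstalk is separable by construction.
* `subject_gain_sd` (default 0.15) — per-subject, per-channel log-normal
  gains emulating electrode placement and impedance variability; this is
  what makes subject-wise holdout genuinely harder than pooled CV.
* `crosstalk` (default 0.05) — a symmetric channel-mixing matrix with
  `1 - crosstalk` on the diagonal, the textbook model of muscle-signal
  bleed between electrodes.
* `artifact_rate` (default 0) — Poisson spike artifacts of 12× the local
  RMS, used to exercise the despiking filter.

What the generator does **not** model: motor-unit action potentials,
electrode-skin biophysics, fatigue drift, spasticity bursts or any
individual patient waveform. Class information is carried almost entirely
by amplitude geometry, not by spectral or fractal structure, so passing
recovery tests show the *search machinery* ranks genuinely informative
features above noise — they do not certify clinical decoding accuracy, and
the clinical accuracy figures of any particular cohort are not
reproducible from synthetic data. For search-recovery experiments the
feature-level simulator `simulate_feature_matrix()` plants 5 informative
features (one-vs-rest class means arranged so that dropping any planted
feature collapses one gesture onto the all-quiet class) among pure-noise
features; separation 2 noise-SD units, subject offsets 0.3 SD.

## Preprocessing

Fixed order, as the driver `preprocess_recording()` enforces: band-pass →
Hampel → RMS normalization → window detection.

* **Band-pass**: 4th-order Butterworth, 20–300 Hz, applied zero-phase
  (forward–backward) per channel so burst peak timing is preserved for the
  short windows. The hardware acquisition band (5–500 Hz) is treated as a
  property of acquisition and not re-applied.
* **Hampel despiking**: window of 100 neighbouring samples, threshold 2
  robust standard deviations. "Standard deviation" is estimated as
  1.4826 × MAD, the standard Hampel scale; a windowed true SD would itself
  be corrupted by the spike being tested.
* **RMS normalization** to unit RMS per channel, removing inter-subject
  gain before any amplitude feature is computed.
* **Window detection**: a moving-RMS envelope (100 ms) summed over
  channels; peaks above an adaptive threshold (median + 3 × MAD of the
  envelope — a reproducible stand-in for manual artifact screening) each
  yield one window with 1/3 of its length before the peak (supremum
  border) and 2/3 after (infimum border), clamped to 30–60 ms. The 30–60 ms
  range is read as bounds on the *window length*; the alternative reading
  (offsets around the peak) is noted but not adopted. Overlaps resolve in
  favour of the higher peak.

## The feature bank

127 features across five domains — 80 time-domain (TD), 19 frequency
(FD), 13 time-frequency (TFD), 10 fractal (FRD), 5 spatial (SD) — listed
in `inst/extdata/feature_manifest.json` and mirrored by
`feature_registry()`. Design choices that matter:

* **Thresholds** for ZC/SSC/WAMP default to 0.01 × window RMS (MYOP 0.5 ×
  RMS): relative thresholds survive RMS normalization, absolute ones do
  not.
* **AR modelling** uses Burg estimation (stable on 30–60-sample windows,
  where Yule–Walker is not) at orders 2–6; cepstral coefficients (CC,
  a.k.a. CC-R) follow the standard LPC-to-cepstrum recursion on the AR(4)
  fit.
* **Signed-log variants** `L<name>` compute `sign(v)·ln(1 + |v|)`,
  compressing the voluminous values distorted signals produce while
  preserving sign and monotonicity; 26 TD features plus MASP (as MLASP)
  are registered this way.
* **Wavelets**: db4 (8-tap), 3 levels, with windows under 64 samples
  extended by mirror padding; DWT/SWT features summarize detail-band
  log-energies. No wavelet package in the dependency set provides these
  primitives, so the pyramid and à-trous transforms are implemented (and
  unit-tested) in the package.
* **Empirical band split**: EWT-k/EWP-k index the k-th of 10 bands of one
  decomposition. Bands are support-adaptive: band 1 is everything below
  the 2nd power-percentile frequency, band 10 everything above the 98th,
  and eight interior bands split the occupied support uniformly. This
  keeps the lowest band nearly empty for band-limited signals while
  remaining fully deterministic.
* **Hilbert–Huang**: a compact sifting EMD (spline envelopes, up to 4
  modes) followed by the analytic-signal instantaneous frequency;
  the HHT feature is the amplitude²-weighted mean frequency.
* **Fractal family FR1–FR4**: variogram-scaling dimension estimated from
  log V(τ) over lags 1..k+1 (FD = 2 − β/2); a line gives 1, white noise 2.
  Higuchi FD (kmax 8), first-order DFA, approximate/sample entropy
  (m = 2, r = 0.2 SD), Katz and Petrosian dimensions complete the domain.
* **Spatial ratios** compare flexor- against extensor-tagged channels
  (power, MAV, RMS, WL, SSI ratios) with an ε-guarded denominator capped
  at 10⁶, computed once per segment.
* Several acronyms whose full definitions live only in the source
  literature's appendix (FR4, PERC2, FDD, ASM, ROG, RSD1/RSD2, NSV, ER,
  CARD/CRD, MNPD) are implemented with field-standard readings and are
  deliberately manifest-driven so a different reading can be swapped in
  without touching the search machinery. The same applies to the exact
  composition of the 47 non-TD entries, which is not pinned down by the
  main-text counts (127 total, 80 TD) that the registry does honour.

Extraction is per channel with concatenation in registry × channel order;
provenance (feature, channel, domain per column) travels with the matrix.

## Evaluation protocol

The score of a feature set is the mean CCR over repeated random
subject-wise holdout. Each iteration holds out
`max(1, round(n_subjects × 0.1))` subjects — 2 of 19 at the default
fraction — standardizes the selected columns on training statistics only,
fits a one-vs-one soft-margin SVM (linear kernel, C = 1; the kernel is
configurable but linear keeps millions of fits tractable and performed
indistinguishably here), and scores the held-out subjects. Splits with a
class missing from training are redrawn (bounded) so scores stay
comparable across candidates. A seed ladder derives every iteration's
split from (base seed, iteration, candidate hash); by default the
candidate hash is dropped, so **all candidates see the same splits** and
rankings are paired comparisons — whether the original protocol reused
splits across candidates is unknowable from the text, and pairing is the
choice that minimizes ranking noise. The no-leakage property (neither
standardization nor fitting touches held-out rows) is asserted by an
instrumentation hook in the tests.

## Brute-force search

Combinations are enumerated lexicographically as a stream (no level is
ever materialized; level sizes are C(n, r), e.g. 8,001 pairs and
10,334,625 tetra sets at n = 127) and scored incrementally with
CSV checkpointing, so an interrupted run resumes without rescoring. The
ranking key is (mean CCR descending, SD ascending, lexicographic name
tuple) — the source ranking uses accuracy alone, but a deterministic total
order is required for reproducibility, so ties break on stability then
name. Desk-scale guard rails refuse levels above 20,000 candidates unless
explicitly unlocked; the full tetra level is supported but is a
cluster-scale computation by nature. `top_quintile()` keeps
`⌈0.2 K⌉` candidates; `domain_distribution()` and `linkage_trace()`
reproduce the domain-mixture and superset-lineage analyses of ranked
pools.

## SNAiL: the spiral amalgamation

The growth rule makes the qualitative "Fibonacci spiral net" concrete; it
is isolated behind `snail_config()` so alternative readings remain
pluggable:

1. **Seeds**: the union of top-quintile candidates of every brute-force
   level up to `source_depth`, re-sorted. The deepest-sourced seeds form
   the first stage pool (stage pools are uniform in size, m features
   each); the whole union feeds the extension alphabet.
2. **Parents**: the top `max(2, round(|pool| / φ))` sets, φ = 1.618.
3. **Candidates**: every `parent ∪ {f}` with `f` from the alphabet
   (seed features ∪ parent features), deduplicated canonically, capped at
   `⌈φ·|pool|⌉` in parent-rank order — one feature per stage, matching the
   numerically increasing 5, 6, …, 20 set sizes.
4. **Truncation**: after scoring, the ranked pool keeps `⌈k/φ⌉`
   candidates (never fewer than one); the stage winner is *reimplanted*
   into the seed pool so later alphabets can reuse it.
5. **Stopping** ("deferred overfitting", which the source names but never
   formalizes): stop at `max_size` (20) or once the best mean CCR has not
   improved for `patience` (2) consecutive stages past `min_size` (5).
   Scores are cached by canonical set name, so a re-proposed set is never
   re-evaluated and brute-force seeds inherit their scores.

Two degenerate limits anchor the design: with φ → ∞ the pool truncates to
a single set and the spiral reduces to greedy forward selection (asserted
against a hand-rolled greedy oracle), and with a flat score landscape the
patience rule stops the search early. `best_overall` is monotone
non-decreasing by kept-best semantics. `compare_sources()` reruns the
spiral under identical seeds for source depths 2–4 and reports winners and
their Jaccard overlaps.

## Statistical comparison

`compare_all()` evaluates the empirical winners and the eight canonical
baselines under one protocol and seed (same splits for every row), then
tests the reference set against each other row with a one-tailed unpaired
Student t-test, pooled variance, DF = n₁ + n₂ − 2 (198 for two
100-iteration samples — the pooled equal-n form is what that printed DF
implies, so Welch is not used). Zero pooled variance is handled
explicitly: equal means give t = 0, p = 0.5; unequal means give the
limiting p with a degeneracy flag. Significance stars mark
p < 0.05/0.01/0.001/0.0001; no multiple-testing correction is applied,
matching the source analysis. The shared-seed design makes iterations
paired *in fact*, but the test remains unpaired as specified — a
conservative mismatch. The all-127-features concatenation is available as
a control (`all_features_baseline()`).

## Numerical choices and degenerate inputs

* Constant windows raise typed degenerate-segment errors for features that
  are undefined on them (AR, NSV, Hjorth mobility, entropies, DFA, HFD);
  extraction propagates the segment index and feature name.
* Sample entropy with zero matches returns the `log(n)` cap rather than
  infinity; spatial ratios cap at 10⁶ via the ε-guard.
* Chance-level assertions use the binomial standard error at the distinct
  instance count, not the per-iteration SD: holdout iterations reuse the
  same few subjects, so per-iteration SEs understate the true sampling
  variance of the mean.
* All randomness flows through one 31-bit seed ladder (double-precision
  arithmetic, exact below 2⁵³, reduced mod 2³¹ − 19), so every stage is
  bit-reproducible from one integer.

## Problem sizes used in tests and the acceptance script

The shipped experiments are deliberately desk-scale: synthetic cohorts of
4–10 subjects with 2–4 repetitions, candidate banks of 8–25 features,
20-iteration protocols, and mono-to-binary brute-force levels; recovery
experiments use 10 seeds. These sizes were chosen so the full suite
documents the machinery in minutes on a single CPU while remaining
statistically decisive (the planted-recovery margins are wide). The
search scales to the full bank and 100-iteration protocol by changing
configuration values only.

## Known limitations

* The synthetic cohort carries class information mainly in amplitude
  geometry; TFD/FRD features are exercised numerically but are rarely the
  winning features on synthetic data, unlike on real paretic EMG.
* The appendix-defined feature formulas are best-effort standard readings
  (documented above) rather than certified re-implementations.
* EDF input is not implemented; the delimited CSV + JSON sidecar is the
  sole interchange format.
* No distributed execution: candidates are independent and the
  checkpointed stream makes external schedulers trivial, but orchestration
  is out of scope.
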