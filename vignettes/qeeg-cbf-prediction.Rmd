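---
title: "Predicting CBF recovery during CPR from pause EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CBF recovery during CPR from pause EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegcpr)
```

## The model

`qeegcpr` asks a binary question at every defibrillation attempt in a
ventricular-fibrillation (VF) resuscitation: *has carotid blood flow
(CBF) recovered to at least 30 % of its pre-arrest baseline?*  The
answer is predicted from the only artifact-free EEG available during
CPR — the roughly 3-second compression-free pause before each shock.
Mechanical compressions contaminate the EEG with a periodic artifact far
above physiological amplitudes, so no attempt is made to analyze EEG
during compressions; the pipeline's scope is pause EEG only.

The predictive claim rests on a physiological chain: restored cerebral
perfusion re-activates cortical neurons, which shifts the pause EEG from
a suppressed, low-amplitude, delta-dominated state toward higher
amplitudes, a larger share of fast (8–47 Hz) power, a higher spectral
edge, and higher signal complexity.  The twenty quantitative-EEG
parameters computed per sub-epoch (see `qeegFeatureNames()`) quantify
exactly these axes: amplitude (Magnitude, Ratio05, burst suppression
ratio), spectral balance (band-power ratios and fractions, BcSEF), and
complexity (entropies, bispectral SynchFastSlow).

The full procedure is: simulate or load sessions; band-pass 0.5–47 Hz;
cut each pause into three 2-s sub-epochs with 1.5-s overlap; extract 20
features per sub-epoch; label each pause by its measured CBF recovery
rate at the 30 % criterion; rank features by neighborhood component
analysis (NCA) and hard-filter by Student's t-test at p < 0.05, keeping
the top 10; then evaluate five fixed-hyperparameter classifiers by
leave-one-animal-out (LOAO) cross-validation with SMOTE applied inside
each training fold, pooling all held-out predictions into one confusion
matrix and ROC per model.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| EEG sampling rate | 250 | Hz | acquisition rate of the modeled recordings |
| analysis band | 0.5–47 | Hz | acquisition band-pass; keeps mains out |
| sub-epoch length / overlap | 2 / 1.5 | s | three windows fit a 3-s pause |
| group criterion | 30 | % of baseline CBF | perfusion level associated with recovery of brain function |
| CBF averaging window | 10 | s before pause | "flow during the CPR period"; the period itself is not sharply defined, so the window is a configuration parameter |
| suppression threshold / run | 5 µV, ≥ 0.5 s | — | isoelectric amplitude limit plus the standard burst-suppression run criterion |
| selection size K | 10 | features | the modeled analysis keeps ten parameters |
| SMOTE neighbors | 5 | — | standard choice; must stay below the minority count |
| SVM | poly-3, cost 1 | — | pinned hyperparameters; kernel scale `sqrt(d)` after z-scoring |
| KNN | k = 9, squared-inverse weights | — | pinned |
| RF | 30 trees, subspace `ceiling(sqrt(d))` | — | "random subspace" read as per-tree feature subsets of the conventional size |
| MLP | 10 hidden units | — | "10 hidden layers" read as one hidden layer of ten units, the convention of the era's tooling |

## What the synthetic generator emulates — and what it does not

The generator (`generatorConfig()`, `simulateCohort()`) reproduces the
protocol state machine (baseline, 1 min untreated VF, four 2-min BLS
cycles ending in the first defibrillation attempt, then up to ten 2-min
ACLS cycles each ending in an attempt; non-ROSC after the tenth failed
attempt) and the four qualitative EEG regimes: baseline activity above
±20 µV, isoelectric VF below ±5 µV, periodic compression artifact above
±50 µV at the compression fundamental (default 102 min⁻¹, a mechanical-
device convention, not a protocol constant), and recovered
mixed-frequency activity.

EEG is synthesized as band-limited colored noise: a `1/f` slow component
on 0.5–8 Hz plus an exponentially decaying fast component on 8–47 Hz.
Two logistic ramps in the recovery rate *r* drive the regime: peak
amplitude `1.5 + 21·plogis((r−30)/10)` µV and fast-power share
`0.33 + 0.30·plogis((r−30)/15)`.  Below roughly 35 % recovery the signal
is additionally multiplied by a burst–suppression envelope (suppressed
segments scaled to 0.18 of burst gain), which concentrates signal energy
into bursts.  These constants were chosen once so that the two groups'
feature medians reproduce the expected orderings — higher Magnitude,
DeltaR, BcSEF, BG_Alpha+, spectral/Rényi/log-energy entropy and lower
DAR, DTABR, DeltaPR in the recovered group — and are stored in the
configuration rather than hard-coded.

Recovery rates are drawn per animal: a fixed share of animals
(default 3 of 8) are non-responders whose rates stay in a low Gamma(2, 6)
regime (median ≈ 10 %), while responders draw rates above
`32 + Gamma(2, 12)` with high probability and achieve ROSC with
probability 0.25 per eligible attempt.  This mirrors a cohort in which
most animals contribute predominantly one class and the pooled class
split is roughly 53 : 47.  The CBF trace is piecewise-constant per stage
with additive Gaussian noise (σ = 8 mL/min on a 300 mL/min baseline),
and labels are recomputed from the trace, so borderline pauses can
legitimately flip groups — label noise the real measurement would also
have.

What the generator deliberately does **not** model: arterial pressure or
end-tidal CO₂, defibrillator electronics, ventilation, inter-electrode
artifacts, or any physiologically realistic EEG microstructure (spindles,
reactivity, nonstationary spectra within a regime).  Consequently,
passing tests show the *pipeline* is correct and that the *qualitative*
group separation is recovered; they say nothing about classifier
performance on real recordings, which depends on biological variability
the simulation does not contain.  The synthetic cohort is intentionally
easier than real data (pooled LOAO AUC ≈ 0.99 versus ≈ 0.91–0.93
reported on animals).

## Numerical choices

* **Filter** — 4th-order Butterworth band-pass applied forward–backward
  (`signal::filtfilt`), i.e. zero-phase; only the band is prescribed by
  the acquisition hardware, the realization is ours.
* **Spectral estimator** — unwindowed periodogram of the demeaned 2-s
  sub-epoch (0.5 Hz bins), Parseval-scaled so total power equals mean
  squared amplitude.  Band powers use half-open `[a, b)` edges so that
  the five canonical bands partition 1–47 Hz without double counting;
  overlapping definitions (e.g. 8–20 vs 8–13 Hz) are computed
  independently.  Whether the original analysis windowed or averaged
  sub-spectra is unknown; the estimator is therefore a swappable
  configuration point.
* **Log conventions** — band ratios and SynchFastSlow use log10 (the
  BIS-family convention, consistent with ratio magnitudes around ±0.7);
  entropies use natural log.
* **Amplitude probability distribution** — `p_i = x_i² / Σ x_j²` over
  the 500 epoch samples, with a 1e-12 floor inside every log.  The
  underlying definition gives no estimator, so this energy-normalized
  choice is ours.
* **Log-energy entropy** — two conventions are implemented
  (`entropy_convention`): `probability` (`Σ log p_i²`) and `raw_energy`
  (`Σ log x_i²` over raw µV samples, the wavelet-toolbox convention).
  The default is `raw_energy` because only its scale (hundreds to
  thousands, crossing zero between groups) matches the magnitudes this
  parameter takes on real recordings; the probability variant is kept
  for completeness.  Neither is asserted against reported numeric values
  — the estimator there is genuinely underdetermined (reported Rényi
  medians even exceed the uniform bound `ln 500` for 500 samples).
* **DeltaPR** — implemented as the plain fraction `P_1–4 / P_1–47`; the
  reported group medians (≈ 0.28) are only consistent with the plain
  fraction, not a log-wrapped variant.
* **BG_Alpha+** is reported on the 0–100 scale, all other fractions on
  0–1, matching the scales on which these parameters are conventionally
  quoted.
* **Ratio05** uses a strict inequality at 5 µV: a sample exactly at the
  limit is not "under ±5 µV".
* **NCA** — diagonal (per-feature weight) NCA with the weighted
  Manhattan metric, z-scored inputs, weights initialized at 1, λ
  defaulting to 1/n, adaptive-step gradient ascent; deterministic.  The
  original implementation and regularization are unstated, so exact rank
  order on synthetic data is not asserted — only the selection *logic*
  (significance as a hard filter, rank order among survivors, top 10)
  is pinned, via the bundled reference ranking table.
* **SMOTE placement** — inside each training fold only.  The reported
  fold class counts (117 majority vs 71 minority with one animal held
  out) identify a *training* fold, and in-fold application is also the
  only leakage-free choice.  The equalize-to-majority target (71 + 46
  synthetic) is the algorithmic definition; a reported post-balancing
  count that disagrees with this arithmetic was treated as a typo.
* **Evaluation pooling** — per-fold test sets are nearly single-class,
  so per-fold sensitivity/specificity are undefined; predictions are
  pooled across folds before computing the confusion matrix and ROC.
  "Averaged over animals" cannot be computed as stated for single-class
  test animals; pooling is the only well-defined reading.  A stated
  5-fold inner CV coexists contradictorily with the LOAO description;
  the outer LOAO loop is authoritative here, and in-fold selection is
  available behind `selectionInFold` (default off, matching the modeled
  analysis's single whole-cohort selection).
* **MLP training** — one hidden layer of 10 units via `nnet` (BFGS);
  the original used scaled conjugate gradients, a backend detail that
  does not change the architecture.
* **Degenerate inputs** — zero-power spectra yield 0 fractions with a
  warning; zero signals yield 0 entropies; metrics with empty
  denominators are `NA` with a warning, never silently 0; zero KNN
  distances are floored at 1e-12.

## Problem sizes used by the test suite

Monte-Carlo checks use sizes chosen to make the checked property stable:
the 20-seed median for end-to-end AUC (cohorts of 8 animals, ~50–65
pauses each run), 520 pauses (≥ 200 per group) for the median-ordering
calibration, 50 seeded draws for regime monotonicity, 25 seeded cohorts
(n = 200, 6 features) for the NCA ranking property, 100 seeds for the
Parseval identity, and 1000 instances for the AUC/Mann–Whitney
equivalence.  The monitoring stage defaults to 120 s (the protocol
monitors 20 min to confirm sustained ROSC); monitoring EEG is never
analyzed, so this only bounds artifact size.

## Known limitations

* Synthetic-only validation: no deposited recordings exist for the
  modeled experiment, so reported animal-level classifier performance is
  not a reproduction target.
* The feature set on synthetic data is more mutually redundant than on
  real EEG (all regime axes are driven by one latent recovery rate), so
  the NCA ranking among correlated features is less stable than the
  selection logic itself.
* Single-channel frontal EEG only; no artifact handling during
  compressions by design.
* Binary classification only; recovery-rate regression is out of scope.
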