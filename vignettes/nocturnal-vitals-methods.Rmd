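---
title: "Methods: nocturnal vital-sign monitoring analysis for COPD screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nocturnal vital-sign monitoring analysis for COPD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightsigns)
```

## The problem

Chronic obstructive pulmonary disease (COPD) is formally diagnosed by
spirometry (post-bronchodilator FEV1/FVC below 70%), but spirometry requires
a clinic visit and patient effort. People with COPD carry physiological
signatures that unobtrusive bed sensors can record every night at home:
autonomic dysfunction visible in heart-rate variability (HRV), a faster
resting heart rate, a higher nocturnal respiratory rate, and episodes of
tachypnea. A single night is noisy — sleep quality, mood and transient
illness all move these features — so the analytic idea this package
implements is to *average multi-night features over windows of t days*
(after trimming each window's extremes) and ask how classification
performance changes as the monitoring window grows from one night to a
month.

`nightsigns` provides the full desk workflow: a synthetic cohort generator,
nightly feature extraction, night-level quality control (QC), trimmed
multi-day aggregation, logistic-regression classification with ROC
evaluation, and diagnostic-accuracy sample-size arithmetic. Because real
nocturnal cohorts of this kind are hospital-held and not shared, the
generator is a first-class, tested component: it is what makes every
downstream stage verifiable.

## Nightly features

Ten features summarize one night (Table). Spectral powers are absolute
(ms²) over the conventional HRV bands; modal values are integers.

| feature | definition | units |
|---|---|---|
| `sdnn` | sample SD (n−1) of heartbeat intervals | ms |
| `tp` | spectral power over (0, 0.40] Hz | ms² |
| `ulf` | band power below 0.0033 Hz | ms² |
| `vlf` | band power 0.0033–0.04 Hz | ms² |
| `lf` | band power 0.04–0.15 Hz | ms² |
| `hf` | band power 0.15–0.40 Hz | ms² |
| `lf_hf` | LF/HF ratio | — |
| `hr_mode` | modal per-minute heart rate | beats/min |
| `rr_mode` | modal per-minute respiratory rate | breaths/min |
| `rrf` | minutes with RR strictly above 21 | min |

Band powers are always reported in absolute ms²; normalized-unit variants
(bounded at 100 by construction) are deliberately not computed, so any
cutoff derived here is in ms².

### Spectral estimation

Beat intervals are an *irregularly sampled* series (one value per beat, at
the beat's time). Resampling onto a uniform grid and applying an FFT
biases band powers through interpolation; we instead use the Lomb–Scargle
periodogram of the interval-versus-beat-time tachogram, which is the
least-squares sinusoid fit at each frequency and needs no resampling.
Numerical choices, fixed once:

* frequency grid: oversampling factor 5 (spacing `1/(5·span)`) up to
  0.5 Hz;
* band edges closed on the left, open on the right; ULF is open at 0; the
  total power integral is over (0, 0.40];
* the periodogram is rescaled so that its integral over the full grid
  equals the interval variance (a Parseval contract), making band powers
  directly interpretable as ms² of interval variance;
* evaluation uses cyclic Lagrange extirpolation onto a power-of-two grid
  plus one FFT (the Press–Rybicki scheme, spreading order 4), with the
  direct per-frequency sums retained as a `method = "direct"` reference;
  the two agree to about 1e-4 relative on band integrals;
* records shorter than 30 minutes are refused; ULF and VLF are reported
  `NA` below 5 hours because slower-than-0.04 Hz rhythms are not
  meaningfully resolved on part-night records;
* a constant interval series returns all-zero powers, and `lf_hf` is `NA`
  (undefined, not infinite) when HF is exactly zero;
* modal HR/RR round per-minute values to integers first and break modal
  ties towards the smaller value; `rrf` counts strictly-above-21 minutes,
  so a minute at exactly 21 breaths/min does not count.

## The synthetic cohort generator

`generate_cohort()` draws participants (group, age, sex, BMI category,
acute-exacerbation windows for cases), a per-participant monitoring
schedule, and per-night physiology. Its defaults *are* the study
conditions the package's qualitative checks run under: 50 cases + 50
controls, 60 scheduled nights each, compliance 0.73 (each scheduled night
recorded independently with that probability — the denominator of
compliance is scheduled nights, exposed as a parameter rather than
asserted), and QC-violation injection rates of 2%/3%/2%/2%/1% for
motion / short sleep / long sleep / data loss / zeroed vitals, plus 0.15
exacerbation episodes per case per 30 nights with 3–10-day durations
(no duration distribution is established for such episodes; this range is
a package choice).

The group phenotypes encode, in the package's own defaults, the contrast
structure typical of nocturnal COPD monitoring: cases have all band powers
raised (HF 2000 vs 800 ms², total ~7850 vs ~3900 ms²) *at the same LF/HF
ratio of 1.5*, a slightly faster heart rate (875 vs 920 ms mean interval),
a higher respiratory rate (17.5 vs 15 breaths/min) and far more tachypnea
(median 3 vs 0.05 minutes per night). The intended discriminability
ordering — respiration strongest, HRV intermediate, heart rate weak,
LF/HF null — was calibrated once against the magnitudes such cohorts
report (e.g. an HF cutoff between the two group levels, an RR cutoff near
16 breaths/min, near-zero control tachypnea) and is not revisited.

Variability has three layers, all chosen to keep features positive and to
give the trimmed mean something real to suppress:

* *between persons*: one shared lognormal amplitude multiplier on band
  powers (σ = 0.45 log units) times one extra multiplier per band pair
  (ULF,VLF) / (LF,HF) (σ = 0.35); additive shifts on mean beat interval
  (SD 60 ms) and respiratory rate (SD 1.2); a wide lognormal multiplier
  (σ = 1.5) on the tachypnea rate;
* *between nights*: independent lognormal multipliers per band (σ = 0.5),
  additive shifts on interval (SD 25 ms) and rate (SD 0.8);
* *within nights*: the signal itself (band-limited modulation, AR(1)
  minute-to-minute respiration noise, Poisson tachypnea minutes).

Two design points deserve emphasis. First, the person-level component is
essential: with night-level noise only, pooled person-time classification
would become perfect as the window grows, which is not how saturating
multi-night performance behaves. Second, the *pairing* of the person-level
band multipliers is deliberate: it makes the LF/HF ratio person-invariant
(so a group-matched LF/HF stays statistically null) while still preventing
any band ratio from being a deterministic group fingerprint that a
classifier could exploit noise-free. The case VLF/ULF target ratio equals
the control one for the same reason.

QC-violating nights are injected by overriding *metadata* independently of
the signal (motion count 600–900, sleep below 5 h or above 9 h, 60–240
minutes of loss); a zeroed-vital night zeroes the modal HR or RR (in
signal mode, the respiration channel). This lets tests target each rule in
isolation.

### Two signal levels

`level = "features"` draws the ten nightly features directly from the
latent per-night physiology (total power as the band sum with a 0.8%
lognormal estimator jitter — measured total power is never the exact band
sum — and SDNN as its square root). `level = "signal"` synthesizes the
actual per-night series from the same latents: band-limited random-phase
Fourier synthesis on a 0.125 s grid (every line in a band carries equal
amplitude so the lines sum exactly to the band target), integrated into
beat times so that `diff(beat_times)` *is* the interval series; and
per-minute respiration whose baseline is capped at 21 breaths/min so that
tachypnea minutes come only from injected episodes (making the expected
RRF equal the configured rate). Feature-level cohorts cost milliseconds
per night and power the cohort-scale analyses; signal-level cohorts cost
a few hundred ms per night and power the estimator-recovery tests, where
LF and HF band powers are recovered within a few percent (median) on 8 h
records. A nonzero band must contain at least 3 synthesis grid lines, so
ULF requires records longer than ~15 minutes.

What the generator does *not* emulate: raw sensor waveforms, ectopic
beats and arrhythmia, sleep staging, apnea, circadian drift within the
night, seasonal trends, or feature distributions conditional on age, sex
and BMI (demographics are drawn but do not feed the vital-sign model, so
covariate adjustment is available but idle on synthetic data). Passing
tests therefore show the *pipeline's* correctness and the direction of its
statistical behaviour, not clinical performance on real signals.

## Quality control

A night is excluded iff any of: artifact motions ≥ 600 (inclusive), sleep
< 5 h or > 9 h (exactly 5 or 9 kept), data loss ≥ 60 min (inclusive),
modal HR or RR equal to 0, or the night date falling in `[start − 7 days,
end]` of an exacerbation window (calendar-date arithmetic; "during" is
read as up to the window's last day). Participant-level eligibility is a
roster-construction concern, not a night filter. Decisions are per-night
and order-free.

## Aggregation

The `t`-day statistic is the window sum minus its maximum and minimum,
divided by `t − 2` — removing exactly one occurrence of each extreme.
For `t = 1` the nightly value is the sample (the formula is undefined
there); `t = 2` is refused. Windows are the *most recent t kept nights*,
rolled anchor-by-anchor with calendar gaps allowed: at realistic
compliance, strictly consecutive calendar windows would leave almost no
30-night samples, and rolling windows are the only reading consistent
with person-time counts that shrink only moderately as `t` grows. This
is a documented package choice; a calendar-aligned variant is out of
scope. Per participant, sample counts are non-increasing in `t` by
construction.

## Classification and evaluation

The unit of analysis is the pooled person-time sample. This mirrors the
design such studies report, and its limitation should be understood:
samples from one participant are correlated (the more so because rolling
windows overlap), so pooled p-values are anti-conservative and apparent
performance is optimistic. Concretely, the feature screen (two-sided
Mann–Whitney at α = 0.05, no multiplicity correction) is well calibrated
on nightly (`t = 1`) samples, where a group-matched feature such as LF/HF
is retained only at the nominal 5% rate, but over long overlapping
windows even a matched feature can reach nominal significance; the
package therefore treats the nightly screen as the canonical one in its
own acceptance checks. Train/evaluate is on the same samples (apparent
performance), as is conventional for this design; a cross-validation
variant is a natural extension and deliberately not default.

The Mann–Whitney z uses the tie-corrected variance and a half-unit
continuity correction (keeping the normal p within 0.02 of the exact
permutation p down to groups of six). The chi-square is plain Pearson.
Logistic regression is the unregularized IRLS fit (`stats::glm`,
binomial; deviance tolerance 1e-8, 100 iterations); perfect
single-feature separation makes the likelihood maximumless and is refused
with an error naming the feature, or degraded to a flagged non-converged
fit inside the batch pipeline.

ROC curves are built over all distinct score values with the rule "score
≥ threshold ⇒ case". AUC is the trapezoid integral, identical to the
tie-corrected Mann–Whitney `U/(n₁n₂)`. Confidence intervals and paired
AUC comparisons use the DeLong nonparametric variance (via pROC); the
p-value reported with each AUC is the DeLong test against 0.5. The Youden
cutoff maximizes sensitivity + specificity − 1, ties resolved towards the
lower threshold, and at that cutoff the reported Youden index equals
sensitivity + specificity − 1 exactly. Model-probability evaluations
dichotomize at 0.5; single raw features are evaluated at their Youden
cutoff, so cutoffs are in feature units (minutes for `rrf`, breaths/min
for `rr_mode`, ms² for band powers). Between-timescale comparisons are
computed on the anchors for which all windows exist, so the DeLong
comparison is validly paired.

## Sample-size arithmetic

For a target sensitivity/specificity `p` estimated with relative
tolerance `f` at two-sided level α, the precision formula is
`n = ceil(z²_{1−α/2} · p(1−p) / (f·p)²)`, evaluated separately for
sensitivity (cases) and specificity (controls). The group with the larger
demand is sized by its formula and the other follows the design ratio;
when the demands tie, the specificity/controls side anchors — with
Se = Sp = 0.90, α = 0.01, f = 0.10 and a 1:2 ratio this yields 74
controls and 37 cases, 111 in total. Dropout inflation (`n/(1−dropout)`,
rounded up) is reported separately and *not* folded into the designed
total, matching the convention of quoting the analytic minimum.

## Problem sizes and determinism

All randomness flows from the integer seed in `sim_config()`; a fixed
seed makes cohorts byte-identical and `run_study()` reports reproducible.
The package's own checks run at sizes chosen to exercise the statistics
without waste: qualitative cohort properties on 50 seeds of the default
50+50 × 60-night configuration; estimator recovery on 100 synthetic 8-h
nights; QC fidelity on 1,000 metadata-randomized nights; exact
permutation comparisons at group sizes 6–8.

## Known limitations

* Pooled person-time inference ignores within-person correlation (see
  above); effect directions are trustworthy, absolute p-values are not.
* Apparent (resubstitution) performance only, by design.
* The generator's demographics do not modulate its physiology, so
  covariate adjustment cannot be meaningfully exercised on synthetic
  data.
* The fast periodogram is approximate at the 1e-4 relative level; use
  `method = "direct"` where exactness matters more than time.
* Signal-level synthesis makes clean beats only — no artifact model at
  the signal level (artifacts enter through QC metadata).
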