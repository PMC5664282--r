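---
title: "Validating a qualitative multiresidue screen for antimicrobials in eggs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a qualitative multiresidue screen for antimicrobials in eggs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggscreen)
```

## The problem

Laying hens treated with antimicrobials deposit drug residues into eggs,
both in the albumen (laid down over a few hours from freshly secreted plasma
protein) and in the yolk (which grows exponentially over roughly ten days
and therefore integrates exposure over that window).  Regulatory monitoring
needs a fast qualitative screen that, for dozens of analytes at once, calls
a sample *compliant*, *noncompliant*, or *not detected* relative to a
maximum residue limit (MRL) or, for banned substances, relative to a low
screening level — with a guaranteed bound on the false-negative rate.
Suspect samples then go to a separate quantitative confirmatory method;
the screen itself never quantifies.

`eggscreen` implements the statistical calculus used to validate such a
screen and the decision logic used to apply it, together with synthetic
generators for both kinds of input data, so that every stage of the
pipeline can be exercised and tested without instrument output.

## The validation calculus

Validation is performed per analyte and per MRM transition, in instrument
response units, at the analyte's *level of interest* \(C_{val}\):

* **T-value** — from the noise of \(n = 20\) blank egg samples of different
  origins: \(T = \bar{B} + 1.64\,\mathrm{SD}_B\).  This is the minimum
  response above which a signal is unlikely (about 5% under a normal noise
  model) to come from a blank.
* **Cut-off factor** — from samples spiked at \(C_{val}\), 20 replicates on
  each of three days pooled (\(n = 60\)):
  \(F_c = \bar{M}_{an} - 1.64\,\mathrm{SD}_{an}\).  A truly spiked sample
  falls below \(F_c\) with probability about 5%.
* **Detection capability (CCβ) verdict** — categorical: if \(F_c > T\), a
  positivity threshold exists (any value in \((T, F_c]\)) that
  simultaneously keeps the false-positive contribution of noise and the
  false-negative rate at the level of interest below ~5%, so CCβ lies
  *below* \(C_{val}\).  If \(F_c \le T\), it lies *above*.
* **Limit of detection** — \(LOD = 3\bar{B} \cdot C / \bar{M}_{an}\), the
  concentration whose expected response is three times the mean blank
  noise, under response linearity.
* **Sensitivity** — the percentage of 20 spiked samples with response at or
  above \(F_c\) ("positive agreement").
* **Selectivity** — blank records are scanned for co-eluting signals with
  S/N > 3 inside the retention-time window; such interferences are exactly
  the mechanism that can push \(T\) above \(F_c\) and invalidate a
  transition.

The level of interest is derived, not stored: the MRL where a
single-residue MRL exists; \(0.75 \times\) MRL where the residue definition
combines the parent with an epimer (tetracyclines), so that validation
covers the combined definition with margin; a per-family qualitative
default for banned or non-established analytes; and an explicit per-analyte
override where policy fixes a level directly (doxycycline, validated at the
tetracycline family level of 300 µg/kg despite having no MRL of its own).
The positive-control level is always \(0.75 \times C_{val}\).

```{r}
panel <- default_panel()
head(as.data.frame(panel)[, c("analyte", "family", "mrl",
                              "validation_level",
                              "positive_control_level")], 8)
```

## Decision logic for study samples

A sample is **identified** when both MRM transitions show S/N > 3, the
major transition elutes within the retention-time window (default ±2.5%),
and the minor/major response ratio matches the reference relative ion
intensity within a tiered relative tolerance (±20% above 50%, ±25% for
20–50%, ±30% for 10–20%, ±50% at or below 10%).  An identified sample is
**positive** when its major-transition response reaches the validated
\(F_c\), and **noncompliant** when that response also strictly exceeds the
mean response of the batch positive control.  The gating chain —
not identified ⇒ not positive ⇒ not noncompliant — is enforced
structurally and property-tested.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 1.64 | threshold multiplier in both \(T\) and \(F_c\); 1.64 exactly (the rounded one-sided 95% normal quantile), not 1.645 |
| `rt_tolerance` | 0.025 | relative retention-time window half-width |
| `n_blanks`, `n_spiked_fc`, `n_spiked_sens` | 20, 60, 20 | the validation design sizes |
| `lod_floor` | 1 µg/kg | reporting floor: smaller LODs print as "<1", full precision kept in the machine-readable export |
| `n_controls` | 2 | positive-control replicates averaged per batch |

Standard deviations use the \(n-1\) denominator throughout: the 20 and 60
samples are treated as samples from the blank and spiked populations.  The
60 spiked responses are pooled over days with no day-effect correction,
since the cut-off equation is defined on a single mean and SD.  Ties are
resolved conservatively for consumer protection: a response exactly at
\(F_c\) counts as detected, \(F_c = T\) yields an *above level* verdict,
and a sample exactly at the control mean stays compliant (the control sits
below the MRL).  A negative \(F_c\) (spread exceeding the mean) is returned
as-is with a `low_signal` flag rather than clamped, because clamping would
silently change sensitivity.

## What the synthetic generators emulate

**Validation simulator.** Blank noise and spiked responses are
zero-truncated normal draws under the 20-blank / 20 × 3-day design, with an
optional shared per-day offset and an optional co-eluting interferent that
adds a fixed mean response to the blanks of one transition (a quarter of it
contaminating the recorded noise).  With population parameters \((\mu,
\sigma)\) and the population cut-off \(\mu - 1.64\sigma\), the long-run
fraction of spiked draws below the cut-off is \(\Phi(-1.64) \approx
0.0505\) — the quantitative content of the "false-negative rate below 5%"
guarantee, which is approximate, not a strict bound.  By the same token, a
sensitivity of exactly 100% on 20 replicates is the *likely* outcome, not a
guaranteed one: about 5% of replicates fall below their own pooled cut-off.

**Depletion simulator.** A deliberately minimal linear two-compartment
deposition model: plasma follows first-order accumulation during dosing and
exponential washout, \(p(t) = p(t-1)e^{-k_e} + F \cdot \mathbb{1}[t \le
t_{dose}]\); albumen tracks the previous day's plasma; yolk integrates
plasma over its 10-day growth window with exponentially increasing
deposition weights \(w_j \propto e^{g j}\) toward lay; the pooled-egg
concentration mixes the compartments by a yolk mass fraction of 0.36
(approximately a hen egg).  Optional multiplicative lognormal noise is
mean-preserving; `noise_cv = 0` gives the mean curve.  The model is linear
in dose and in the partition coefficients, which the tests exploit.

The packaged per-drug defaults are **calibration fixtures**: the residue
study reports post-treatment noncompliance durations (enrofloxacin 9 days
above its 7.5 µg/kg control level, its metabolite ciprofloxacin 6,
doxycycline 4, lincomycin 1, oxytetracycline never above 225 µg/kg,
neomycin never detected because it is essentially unabsorbed from the gut)
but no numeric concentration series, so the partition scales were tuned
once so the noise-free mean curves cross their positive-control levels at
those day counts, with the crossing placed at the geometric midpoint
between the bounding days.  The qualitative shapes encode the stated
physiology — quinolones yolk-dominant (slow washout through the 10-day yolk
window), lincomycin albumen-dominant with high plasma protein affinity
(fast washout), doxycycline highly absorbed, oxytetracycline poorly
absorbed.  Tests built on these fixtures therefore guard the
simulator-plus-classifier contract, not an independent pharmacokinetic
prediction, and passing them says nothing about real depletion kinetics
beyond the day-count anchors.

Features of real data the generators do *not* emulate: heteroscedastic and
non-normal instrument noise, matrix suppression/enhancement varying between
egg batches, retention-time drift, carry-over, egg-to-egg follicle
hierarchy, and any response nonlinearity (one linear response factor per
drug suffices because the compliance decision only needs ordering relative
to the positive control).

```{r}
series <- simulate_depletion(depletion_defaults("enrofloxacin")$config)
round(series$concentration, 1)
```

## A complete run

```{r}
cfg <- validation_sim_defaults("lincomycin", panel, seed = 5)
val <- validate_panel(simulate_validation(cfg, panel, "lincomycin"), panel)
format_validation_report(val)

fx <- study_fixture("lincomycin")
scr <- run_screen(fx$records, fx$manifest, val, panel,
                  treatment_end_day = fx$treatment_end_day)
scr$timelines
```

The fixture's validation design keeps \(F_c\) comfortably below the
positive-control response (20% replicate CV plus an 8% day effect put the
cut-off near 65% of the spiked mean, against a control at 75%), so the
compliance boundary, not the positivity boundary, determines the reported
timelines — matching how the residue study reasoned about its day counts.

## Numerical and design notes

* The validation statistics are plain closed-form expressions; every one is
  cross-checked in the test suite against naive loop/closed-form
  re-implementations on random small inputs.
* The published LOD values for individual analytes depend on unpublished
  instrument responses and are deliberately not reproduced; the LOD code is
  covered by its algebraic identities (linearity in noise and
  concentration, inverse proportionality to response, `LOD = C` when the
  mean noise is a third of the response) instead.
* `validate_panel` validates the identification (major) and confirmation
  (minor1) transitions; a third stored transition is metadata only.
* The tiered ion-ratio tolerances are the conventional screening-criteria
  bands; the reference relative intensities in the packaged panel are
  stored values, never recomputed.  (The criteria citation in the source
  literature gives the decision number as 2002/675/EC; the screening
  criteria as described correspond to the better-known 2002/657/EC.)
* Simulation sizes in the tests are kept small (20/60-replicate designs,
  16-day series, one 10^5-draw Monte-Carlo check) because the statistics
  involved converge quickly; all suites run in seconds.
* The CLI (`inst/exec/eggscreen`) is a thin wrapper over `run_validate()`,
  `run_screen()` and `run_simulate()`; its exit status is nonzero when any
  transition fails validation, for pipeline gating.

## Limitations

The package consumes already-integrated responses and noise values; peak
picking, chromatogram integration and raw file parsing are out of scope, as
are extraction chemistry and instrument control (transition tables store
the tuned settings as metadata).  Whether "noise" is a height or an area is
deliberately left to the data producer — it is treated as an opaque
response-unit value.  There is no CCα, no precision/trueness/linearity
validation (the qualitative scheme replaces them by design), and no
confirmatory quantification.
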