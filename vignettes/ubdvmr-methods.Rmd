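---
title: "Scoring and simulating bladder-distension visceromotor responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulating bladder-distension visceromotor responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubdvmr)
```

## The measurement

Urinary bladder distension (UBD) is a standard preclinical assay of visceral
nociception: compressed air inflates the bladder of a lightly anesthetized
mouse to a set pressure (15–75 mmHg) for 20 s while electrodes in the
external oblique abdominal muscle record the reflexive electromyogram, the
visceromotor response (VMR). The VMR is quantified per distension as the
background-subtracted, rectified, integrated voltage over the 20 s stimulus
window; the same operator applied to the 20 s pre-distension window supplies
a baseline measure. All stimulus scores of a session are divided by the
*smallest* pre-distension value of that session, and the three replicates at
each pressure are averaged before statistics. Two experimental confounds
dominate the assay's reliability: how isoflurane anesthesia is stepped down
before testing (a short ~30 min induction versus a long ~90 min step-down),
and how tightly body temperature is held at 37.5 °C.

`ubdvmr` implements this scoring procedure, constructors for the standard
distension/anesthesia/temperature protocols, a synthetic EMG generator that
encodes the known confound phenomena, balanced fixed-effects ANOVA with
Bonferroni post-tests, and the pERK Western-blot densitometry pipeline. The
simulation studies in `vmr_power_study()` and `blot_power_study()` run the
*entire* pipeline — generator, scorer, statistics — on replicated cohorts.

## Scoring: definitions and numerical choices

For a uniformly sampled trace \(v(t)\) and an event with onset \(t_0\),

\[
\mathrm{AUC}_{\text{stim}} = \int_{t_0}^{t_0+20} |v(t) - b|\,dt, \qquad
\mathrm{AUC}_{\text{pre}} = \int_{t_0-20}^{t_0} |v(t) - b|\,dt,
\]

with the background \(b\) estimated, by default, as the mean of the event's
own pre-distension window (a DC-offset estimate; a whole-trace-mean option
exists). The normalized VMR is
\(\mathrm{AUC}_{\text{stim}} / \min_e \mathrm{AUC}_{\text{pre}}(e)\), the
minimum running over all non-sensitization events of the session.

Numerical choices:

* **Integration** is the trapezoidal rule at native sampling; no resampling
  or filtering. Integration windows are *closed* intervals \([a, b]\) at
  sample points, which makes the closed forms exact (a constant \(c\) over
  20 s gives exactly \(20c\)) and integration additive across a shared
  boundary sample. Adjacent stimulus/pre windows therefore share one
  boundary sample; at 1 kHz this contributes at most half a sample interval
  of overlap and is far below scoring noise. Event *ownership* of samples
  (for envelope construction in the simulator) is half-open
  \([t_0, t_0 + 20)\).
* **Background before rectification.** The original acquisition scripts are
  not public, so whether background was removed per event or per session is
  unknowable; per-event DC removal from the event's own pre-window is the
  standard EMG reading and is the default, with `background = "global"` as
  the alternative.
* **Sensitization distensions.** The three initial 60 mmHg distensions exist
  to overcome the assay's initial sensitization; they are scored but flagged,
  and excluded from both the normalizer minimum and all tables.
* **Normalizer scope** defaults to the whole session
  (`normalizer_scope = "experiment"`); a per-set variant exists but is off.
* A session whose smallest pre-distension AUC is 0 (a perfectly silent
  baseline, impossible with real or simulated noise) fails loudly, naming
  the offending event, rather than dividing by zero.
* Missing replicates average over what is present, with a warning.

Two invariances follow and are property-tested: adding any constant offset
to a trace leaves all scores unchanged (the background absorbs it), and
scaling a trace by \(k > 0\) cancels in the stimulus/normalizer ratio.

## The synthetic generator

The scored quantity depends on the signal only through its rectified
integral, whose expectation is set by the noise envelope; so evoked EMG is
modeled as amplitude-modulated zero-mean Gaussian noise, not motor-unit
spike trains. During a distension at pressure \(P\), time \(t\), current
temperature \(T\) and session temperature minimum \(T_{\min}\):

\[
\sigma(t) = \sigma_0 + g_a \, G \, d(P) \, A(t) \, H(T, T_{\min}),
\]

* \(\sigma_0\): resting noise scale (`baseline_sd`, 0.05 mV);
* \(d(P) = s\,\max(0, P - P_0)\): drive, linear above a threshold
  \(P_0 = 10\) mmHg with slope \(s = 1\). Any monotone form would do; linear
  is the minimal choice and both parameters are configurable;
* \(G\): gain (`response_gain`, 0.02 mV per drive unit);
* \(g_a\): per-animal lognormal gain, sdlog `animal_sd` = 0.2;
* \(A(t)\): anesthesia factor — 1 for the long induction;
  \(e^{-rt}\) with \(r\) = `anesthesia_drift_rate` = 0.7 h\(^{-1}\) for the
  short induction, encoding the progressive decline of responses when
  testing starts ~30 min after induction;
* \(H(T, T_{\min})\): temperature factor
  \(1 - k(37.5 - T)\) with \(k\) = `temp_sensitivity` = 0.12 °C\(^{-1}\),
  capped at `hysteresis_floor` = 0.55 for the rest of the session once
  \(T_{\min}\) has reached 33.5 °C — cooling to the bottom of the tested
  range suppresses responses *persistently*, with no within-session recovery
  on rewarming.

Factors are multiplicative and lie in \((0, 1]\); the hysteresis memory is a
pure function of the running minimum temperature, so re-running any prefix
of a schedule reproduces its factors exactly. Reproducibility follows a
single-master-seed contract: each animal's stream is derived by a fixed
integer mix of `(seed, animal index)`, and each study replicate derives its
cohort seed the same way, so any replicate can be regenerated in isolation.

Effect magnitudes are *operating points, not physiological estimates*: the
source experiments report p-values and figures, not effect sizes, so the
defaults were fixed once, at design time, such that the full pipeline
recovers each qualitative pattern with high probability at the published
cohort size (n = 6) — and loses it when the corresponding mechanism is
switched off. They are recorded in every simulation manifest.

What the generator does *not* emulate: non-Gaussian EMG burst structure,
movement and electrode artifacts, isoflurane pharmacokinetics,
thermoregulatory dynamics, bladder-wall mechanics, or any correlation
between an animal's gain and its drift/suppression. Passing pipeline tests
on this generator therefore validate the *scoring and statistics*, and the
internal consistency of the phenomenological model — not the biology of
real traces.

## Protocols

`build_protocol()` produces fully timed event tables. Every event is
20 s pre-interval + 20 s stimulus + 60 s ITI (100 s of event time); graded
sets ascend 15→75 mmHg with triplicates (1500 s per set, matching the
~30 min set duration); sets follow each other immediately (the gap is the
last event's ITI), except that a temperature change inserts a 300 s
stabilization gap. Scored designs begin with three flagged 60 mmHg
sensitization distensions. Time zero is the start of testing (end of
anesthesia stabilization); surgery is not modeled. The blot design
(`fig5_blot`) is five 75 mmHg distensions at 0.875% isoflurane with no
sensitization events, at 37.5 or 33.5 °C.

## Statistics

`one_way_anova()` / `two_way_anova()` are the classical fixed-effects
mean decompositions for *balanced complete* layouts, with F tested against
the error (or within) mean square; unbalanced input is rejected outright
rather than silently switching sums-of-squares conventions, because every
design here is balanced. Bonferroni post-tests compare the primary factor's
levels pairwise within each stratum of the second factor using the pooled
error term, \(t = |\bar y_1 - \bar y_2| / \sqrt{\mathrm{MS}_E \cdot 2/n}\),
with raw p multiplied by the whole family size (pairs × strata), the
behavior of the legacy commercial software used in this field. p-values
below 1e-15 are reported as "< 1e-15", never 0. The nine-set
temperature-ramp design is analyzed one-way with every set compared against
the first 37.5 °C set.

Animals cross sets in every VMR design, yet set/temperature are analyzed as
plain fixed effects with animals as replicates — deliberately matching the
field's printed analysis style rather than a repeated-measures or
mixed-model formulation. Every report carries a note to this effect. Two
consequences are worth stating plainly:

1. **Between-animal variability makes the crossed tests conservative**, not
   anticonservative: an animal's multiplicative gain cancels exactly in
   between-set contrasts (the same animals sit in every cell) but inflates
   the error mean square.
2. **The session-minimum normalizer has the same structure.** The minimum of
   45 noisy pre-distension AUCs is itself a noisy statistic — an extreme
   order statistic with standard deviation around half the per-window
   noise — and it is *shared by every score of that animal's session*.
   Under a pure-noise null this shared factor again cancels in set
   contrasts while inflating within-cell variance, so the set-effect test
   rejects *below* its nominal level: simulation at the study settings puts
   the empirical type-I rate of the triplicate-averaged pipeline near 1–2%
   rather than 5%. This is a property of the published normalization scheme
   itself, not of the generator; the acceptance suite measures it honestly,
   and power statements in this package are therefore if anything
   understatements.

## Simulation studies

Replicated studies run at 25 Hz sampling (the package's chosen study scale,
recorded per manifest; single-trace work defaults to 1 kHz). The
rectified-AUC coefficient of variation is \(\sqrt{(1 - 2/\pi)/(2/\pi)/N}\)
with \(N\) samples per window — already ≈3.4% at 25 Hz — and every
calibration/power quantity in the studies depends on sampling rate only
through this cv, so study conclusions are insensitive to the rate while a
2000-replicate calibration stays within minutes on one CPU. Study sizes:
2000 replicates for null calibration, 100 for each pattern-recovery rate,
cohorts of n = 6, blot groups of n = 9.

## Densitometry

Blot input is a lane-intensity table (band quantification from gel images
is out of scope). Per lane, pERK1 and pERK2 are divided by their own total
ERK1/ERK2; ratios are then divided by the *mean* ratio of the 37.5 °C
undistended control group — mean rather than median so that the reference
group's normalized mean is exactly 1, the convention in which such results
are plotted. When samples span several gels the control mean is pooled, not
per-blot (per-blot assignments are not recoverable from a pooled table).
The 2 × 2 analysis (distension × temperature) is the same balanced two-way
ANOVA with distended-vs-control post-tests within each temperature, run
separately for pERK2 and pERK1.

## Known limitations

* No repeated-measures or mixed modeling (by design; see above).
* The generator's effect sizes are conventions, so study rejection *rates*
  are statements about the pipeline at those operating points, not about
  animal data.
* Only Bonferroni adjustment is provided; no non-parametric alternatives.
* Native acquisition formats (Spike2 `.smr`, Igor `.pxp`) are not parsed;
  traces enter as CSV.
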