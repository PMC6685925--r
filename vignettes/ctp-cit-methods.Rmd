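---
title: "Methods: simulating and analyzing a CTP P300 concealed information test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a CTP P300 concealed information test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpcit)
```

## The paradigm and what the package models

A Concealed Information Test infers recognition of a critical detail (the
*probe*) from the fact that, for a knowledgeable examinee, the probe is a
rare, personally salient oddball among matched *irrelevant* items and
therefore evokes a larger parietal P300. The Complex Trial Protocol (CTP)
separates the recognition task from response demands: every primary item
receives the same keypress, and an interleaved secondary task (rare *targets*
among *nontargets*, 1:4) keeps attention engaged. Each trial is
secondary item → 1500–1700 ms → primary item → 1500–1700 ms, in three blocks
of 180 trials (one block per item category: forename, birthday date,
favorite animal; 1 probe + 5 irrelevants × 30 repetitions per block).

This package implements the full chain — stimulus construction, constrained
sequence randomization, synthetic EEG generation, preprocessing, peak-to-peak
P300 scoring, bootstrap classification, and group statistics — so the whole
analysis can be exercised and validated on simulated data with known ground
truth.

## Constrained sequence generation

The schedule must satisfy exact combinatorial constraints: trials come in
successive groups containing all six primary items in random order; the same
primary or secondary item never appears in consecutive trials; and every
primary item is preceded by each nontarget exactly `reps/5` times and by each
target exactly `reps/10` times (targets appear half as often as each
nontarget, preserving the 1:4 ratio). No constructive algorithm is implied by
those constraints, so `generate_block()` uses randomized assignment with
rejection: group permutations are re-drawn on boundary repeats, and secondary
items are assigned greedily against the exact per-primary-item quota
(weighted by remaining quota), with bounded restarts and a depth-first
backtracking fallback. `reps` must be divisible by 10 so the quotas are
integers; `validate_sequence()` re-checks every contract and is run over
seeded sweeps in the tests. Inter-stimulus intervals are uniform on
1500–1700 ms recorded at 1 ms resolution.

Foil construction mirrors the item-generation procedure: candidates are drawn
from a category pool preferring minimal character-length distance to the
probe, excluding items sharing the probe's initial letter (dates exempt,
since month names repeat), participants may flag up to two displayed
candidates as personally meaningful, and five task irrelevants are drawn from
the unflagged remainder.

## The synthetic EEG generator

`simulate_session()` generates epochs directly (the modeled analyses all
operate on epochs; a continuous-recording path exists for the
resampling/filtering stages). Channels: Pz, Cz, Fz, the mastoids TP9/TP10,
and four EOG channels. Per trial, Pz carries a raised-cosine P300-like
component (default peak 550 ms, width 400 ms — a modeling choice; the
analysis constrains only that the peak fall inside the 400–800 ms scoring
window), Cz and Fz attenuated copies, and the mastoids small (0.1) copies.

Amplitudes are specified **on the peak-to-peak P300 scale at the analysis
channel** (Pz re-referenced to linked mastoids): the kernel amplitude is the
target value divided by the scored P300pp of the unit kernel (≈0.95) and by
the effective re-reference gain (1 − 0.1 = 0.9). A noiseless subject
therefore scores exactly the specified values, which makes parameter-recovery
tests exact. Defaults follow the calibration of a typical guilty participant:
irrelevant base 4.84 µV; probe increments 9.16 (forename), 5.66 (date),
3.57 µV (animal); target 13.10, nontarget 6.44 µV. Innocent profiles force
all probe increments to zero — the modeled study design has no innocent group,
but simulated innocents are required to measure classifier specificity.
`generate_cohort()` adds between-subject variability (truncated normals with
SDs matching the calibration table) and returns profiles plus seeds; sessions
are materialized lazily and deterministically by `simulate_subject()`.

Noise is white (10 µV SD per scalp sample), an alpha-band sinusoid (2 µV,
10 Hz, random phase), a linear drift (2 µV), stereotyped blinks (100 µV on
the vertical EOG at 3/min, leaking into scalp channels with a fixed
topography), and occasional large artifacts (6% of epochs, 80–150 µV on a
monitored channel) so that amplitude rejection retains roughly 28 of 30
epochs per item cell, matching typical CTP recordings. Behavioral responses
use a shifted lognormal RT (shift 150 ms) with category-specific probe
slowing, role-specific error rates, and a 1% anticipatory-response rate.

What the generator does *not* emulate: realistic scalp topography or volume
conduction, non-stationary noise, eye movements beyond stereotyped blinks,
habituation across blocks, and recall-check responses. Passing
parameter-recovery tests therefore demonstrates the correctness of the
analysis chain under the stated statistical assumptions, not its performance
on real recordings.

## Preprocessing

The chain runs in a fixed order — resample (250 Hz), bandpass, epoch
(−100 to 1400 ms, half-open sample convention, 375 samples at 250 Hz, onset
at the t = 0 sample), baseline (−100 to 0 ms), EOG regression, ±75 µV
rejection at Pz/TP9/TP10, linked-mastoid re-reference of Pz — and records a
provenance list with every parameter. For simulated data the epoch-domain
subset (`preprocess_epochs()`) applies, since epochs are generated at the
target rate with band-limited components.

The bandpass is a Hamming-windowed sinc FIR with −6 dB points at 0.3 and
30 Hz, applied zero-phase. Transition bandwidths default to
`min(max(0.25·f, 2), f)` at the low edge (0.3 Hz — a wider transition would
misplace the −6 dB point of so low a cutoff) and 7.5 Hz at the high edge; the
narrower band sets the kernel length. Resampling is integer-factor
decimation behind a windowed-sinc anti-alias lowpass.

Ocular correction is stationary ordinary-least-squares regression on the EOG
channels over all epochs jointly — deterministic, testable, and adequate when
leakage topography is fixed, which is how the generator produces it. An
adaptive (recursive least squares) algorithm is out of scope; the provenance
output records the method. Zero-variance EOG channels are dropped; rejection
applies after correction, following the narrative order of the processing
chain.

## Peak-to-peak P300 scoring

On a condition-averaged waveform, `p300_pp()` finds the maximum-mean 100 ms
segment lying entirely within 400–800 ms, then the minimum-mean 100 ms
segment lying entirely between that segment's midpoint and 1400 ms; P300pp is
the difference of the two means. Numerical choices: the scan step is one
sample (the finest deterministic grid); window containment bounds whole
segments with inclusive boundaries (`bound = "start"` switches to bounding
segment starts); ties break to the earliest start; midpoints are floored to
the sample grid; a max segment abutting a window edge sets a flag (and
optionally warns), the automated analogue of visually verifying that the peak
falls inside the window. The implementation is checked for exact equality
against an exhaustive brute-force scan on 1000 random waveforms.

Only correct-response trials enter averages. `score_subject()` reports
per-condition amplitudes (probe, pooled irrelevant, target, nontarget) and
per-category probe−irrelevant differences.

**A bias the difference score must avoid.** The probe average is built from
~30 epochs, the pooled irrelevant average from ~150; a noisier average has a
systematically larger peak-to-peak value (its maximum segment captures more
upward noise and its minimum more downward noise). Measured on simulated
innocents, probe − pooled-irrelevant differences run +0.6 to +0.8 µV. The
default difference score therefore subtracts the *mean of the per-item
irrelevant P300pp values*: each item average carries the same trial count as
the probe average, so the noise inflation cancels in expectation (measured
innocent bias ≈ 0.1 µV). Both variants coincide exactly on noiseless data;
the pooled variant remains available (`diff_irrelevant = "pooled"`) and the
pooled amplitude rows are what condition-summary tables report.

## Bootstrap classification

`bootstrap_bad()` resamples epochs with replacement B = 1000 times, averages
and scores each draw, and reports the proportion of iterations with probe
P300pp above irrelevant P300pp; p̂ ≥ 0.9 yields a "knowledgeable" verdict.
B, the threshold, and the comparison mode (all-irrelevants pooled, or the
maximum over per-item irrelevant scores) follow the conventions of the P300
CIT literature and are all configurable — the study this pipeline models
reports its bootstrap only as the conventional diagnostic, so these defaults
are the package's central documented assumption.

The same noise-inflation issue applies with more force here, because the two
bootstrap averages are compared directly per iteration. Drawing each pool at
its original count makes the null comparison strongly anticonservative
(measured on simulated innocents: mean p̂ ≈ 0.87, false-positive rate at
0.9 ≈ 0.58). The default `draws = "variance_matched"` chooses draw counts so
both bootstrap averages have equal total variance around their true means
(`1/m + 1/n` equated across conditions; for 30 probe vs 150 irrelevant
epochs, 30 and 17 draws), which restores calibration (measured null mean
p̂ ≈ 0.5, false-positive rate ≈ 0). `"match_probe"` and `"original_counts"`
are available for comparison with historical implementations. Note that with
unequal pools no scheme makes the null *exactly* symmetric — exact
exchangeability holds only for equal pools, which is how the calibration
tests construct their null.

## Group statistics

`mixed_anova()` implements the split-plot decomposition (one within-subject
factor crossed with one between-subjects factor, balanced within, unequal
group sizes allowed) with sequential sums of squares per stratum, tested
against `aov()` as an independent oracle on balanced and unbalanced toy
designs. Greenhouse–Geisser ε comes from the pooled within-group covariance
of the repeated measurements (exactly 1 for two levels) and corrects both
degrees of freedom; partial η² is SS_effect / (SS_effect + SS_error).
Cohen's *d* for probe−irrelevant differences defaults to d_z
(mean/SD of within-subject differences), with d_av as an option; t tests use
pooled variance by default (matching classical two-group degrees of freedom),
Welch optionally. Significance uses uncorrected α = .05 throughout, matching
the modeled analysis; no multiplicity correction is exposed by default.

Power for the within–between interaction follows the repeated-measures
convention of common power software: λ = f²·N·m·ε/(1−ρ), df₁ = (g−1)(m−1)ε,
df₂ = (N−g)(m−1)ε, with ρ = 0.5 and ε = 1 defaults; at f = 0.25, α = .05,
N = 35 this gives 0.819. `power_mc_interaction()` cross-checks the formula by
simulating the 2 × 2 mixed design and counting rejections.

Exclusion screening (`apply_exclusions()`) encodes the documented failure
modes — probe accuracy below 0.75, secondary-task target accuracy below
0.60, more than 4 of 9 recall checks failed. The two accuracy cutoffs
generalize the two concrete reported cases (49% probe accuracy, 56% target
accuracy) and are configuration values, not reported constants.

## Problem sizes and determinism

Every stochastic function takes a seed and is reproducible; helpers derive
child seeds so nested draws never perturb an enclosing stream. The test
suite validates the sequence contracts over dozens of seeds, scoring against
brute force over a thousand waveforms, and the simulation studies at their
design scale: 200-subject guilty and innocent cohorts for parameter recovery
and classifier calibration (full three-block sessions, preprocessing and
scoring included), B = 250 bootstrap draws inside those sweeps, and 5000
Monte-Carlo replicates for the power cross-check. The `analysis/` drivers use
the study's group sizes (19 + 16).

## Known limitations

* The simulator's simplifications listed above; in particular, real
  irrelevant items differ from one another, while simulated irrelevants share
  one base amplitude per subject.
* The EOG correction is stationary; slowly drifting leakage would be only
  partially removed.
* `mixed_anova()` covers the one-within × one-between designs used here, not
  arbitrary factorial layouts.
* Bayes factors are not implemented.
* Resampling supports integer decimation factors only (sufficient for
  1000 → 250 Hz).
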