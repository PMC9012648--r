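---
title: "How the reference choice shapes the auditory brainstem response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the reference choice shapes the auditory brainstem response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrref)
```

## The problem

The auditory brainstem response (ABR) is a train of sub-microvolt scalp
potentials (waves I-V) in the first 10 ms after a click. Every EEG channel
is a potential *difference* against a reference, and because the ABR is so
small, the reference contaminates it badly: the amplitude a clinician reads
off a trace depends on whether the montage was re-referenced to the average
of all channels (AR), to the two mastoids (MM), or standardized to a point
at infinity (REST). `abrref` implements all three transforms together with
a physics-based synthetic acquisition, so that every claim about their
behaviour can be checked against a known ground truth.

## Forward model

Scalp potentials are computed for a three-shell concentric sphere (brain,
skull, scalp). For each harmonic degree $n$, matching the potential and the
radial current density at both interfaces, and imposing zero current
through the scalp, turns the infinite-medium dipole expansion into a
surface gain $S_n$; the potential of a dipole at fractional radius
$\beta$ seen by electrode $\hat e$ is

$$ V = \frac{1}{4\pi\sigma_1 R^2}\sum_{n\ge1} S_n\,\beta^{\,n-1}
   \big[\, n P_n(x)\,(\hat j\cdot\vec p) + P_n'(x)\,
   ((\hat e - x\hat j)\cdot\vec p) \,\big], \qquad x=\hat e\cdot\hat j, $$

with $\hat j$ the dipole's radial direction and $\vec p$ its moment. For
equal conductivities $S_n=(2n+1)/n$ and the series sums in closed form
(`homogeneousSpherePotential()`), which is the independent oracle used in
the tests.

Defaults: shell radii 0.87 / 0.92 / 1.0 of a 0.09 m scalp radius,
conductivities 1 / 0.0125 / 1 (skull 1/80 of brain and scalp), a 500-point
Fibonacci source layer at 0.86 of the brain radius, and series truncation
at $n=60$. Sixty terms were chosen because at the layer radius
($\beta \approx 0.75$) the neglected tail is below $10^{-6}$ of the field
norm, verified by the convergence test (60 vs 120 terms). The per-degree
5x5 boundary system is row/column-equilibrated before solving; without
that, powers $u^{\pm n}$ overwhelm double precision near $n \approx 100$.

## The three reference transforms

* **AR** subtracts the instantaneous mean of all channels (30 scalp + 2
  mastoids by default, matching a 32-channel cap).
* **MM** subtracts the mean of M1 and M2.
* **REST** builds $T = G\,G_{avg}^{+}$ from the source-layer lead field
  $G$ (its average-referenced version $G_{avg}$ is rank-deficient by one,
  so the pseudo-inverse is a truncated SVD with a relative cutoff of
  $10^{-6}\sigma_{max}$). Data are centred across channels before $T$ is
  applied, which makes the operator idempotent and invariant to whatever
  reference the data carried.

Because the cap samples only the upper head, the channel mean is not the
surface mean, and REST at 32 channels retains an irreducible common-offset
error (about 3-4% at Cz for the deep generator here). On quasi-uniform
whole-sphere sampling this offset vanishes with density (mean in-layer
reconstruction error 0.8% at 32 points, 0.03% at 128), which is the
benchmark the test suite uses to separate the transform's intrinsic
fidelity from cap-coverage bias; the coverage-dependence itself is tested
on the physical cap (32-channel error > 128-point error).

## The synthetic acquisition

`defaultAbrTemplate()` describes the click response as six
derivative-of-Gaussian (biphasic) components. Waves I/III/V sit at
1.60 / 3.65 / 5.60 ms (at 80 dB nHL, 25/s) -- the clinical interwave
spacings 2.05 and 1.95 ms -- with II and IV midway between their
neighbours at half amplitude. All brainstem waves share a 0.5 ms width
(2 sigma): with unequal widths the 1500 Hz low-pass displaces narrow and
wide peaks by different amounts, which would bias the interwave spacings
the study is built around; a common width makes the displacement cancel
in every latency difference. The middle-latency component (21.25 ms,
7.5 ms width, open 4-sigma support 10-40 ms, peak moment twice wave V's
for a ~1 uV vertex deflection) starts after the 0-10 ms ABR window, fits
inside the 40 ms inter-stimulus interval at 25/s, and overlaps later
epochs at 50-100/s. Its width is the slowest biphasic shape those
support constraints allow, which keeps its energy below the 100 Hz
analysis band: a sharper MLR would survive the band-pass and its trough
(arriving ~6 ms into the next epoch at 50/s) would cancel wave V at
moderate rates, contrary to the clinical picture in which wave V stays
scoreable across the rate series, most clearly for the mastoid and
infinity references. Even so, the superposed middle-latency activity at
100/s raises the averaged waveform's floor and with it the detectability
threshold, so the average reference -- whose amplitudes are smallest --
sits closest to losing wave V there, the published asymmetry.

Stimulus laws (documented constants, directions from the literature):
latencies +0.3 ms per 10 dB below 80; amplitudes halved per 20 dB below
80; wave V latency +0.2 ms per rate doubling relative to 25/s. The laws
are anchored at the 25/s, 75 dB condition the summary tables are quoted
at, so the interwave spacings there equal the template's construction
values exactly.

The ABR generator is a single equivalent dipole at (0, 0.02, 0.02) m
pointing superior; the MLR source is more superficial. This geometry gives
a vertex-positive, mastoid-negative topography, so Cz carries the largest
response, the mastoid mean is negative (MM *adds* amplitude at Cz), and
the all-channel mean is positive (AR subtracts amplitude): the amplitude
ordering MM > REST > AR follows from the physics, not from tuning. Wave V
peak moment is 20 nA.m, putting the clean Cz wave V just under 1 uV --
the top of the clinically reported ABR range, and large enough that the
explicit detectability criterion keeps wave I above threshold at 4000
averages.

Background noise is spatially correlated: 16 random in-layer dipoles with
$1/f^{1.7}$ spectra (flat below 0.1 Hz) projected through the same lead
field, scaled to 8 uV broadband RMS per channel, plus 1 uV white sensor
noise. The exponent is calibrated to the analysis band: it leaves about
0.5 uV RMS between 100 and 1500 Hz, so a 4000-epoch average has a ~8 nV
residual -- the regime in which real ABR recordings resolve a 0.02 uV
wave I. A flat 1/f spectrum across the full 10 kHz band would put 3.5 uV
into the analysis band and no realistic averaging count could recover
wave I. Single-epoch broadband SNR remains far below one, so averaging is
genuinely required.

Per-subject variability jitters component amplitudes by +/-15%, source
depth by +/-8% and orientation by up to 8 degrees; latencies are not
jittered, so the cross-subject truth of the interwave table is the
template itself. These jitter magnitudes are stand-ins, not fits to
reported between-subject SDs.

## Signal chain and numerical choices

The chain is the standard offline one: 3rd-order Butterworth 100-1500 Hz
band-pass applied forward-backward (zero phase, effective 6th-order
magnitude), 0-10 ms half-open epochs locked to each click (200 samples at
20 kHz, onset sample included), arithmetic averaging, re-referencing, and
peak scoring. Zero-phase filtering is deliberate: a causal clinical
filter delays peaks, and any inconsistency between methods would break
the latency-invariance comparison; the choice is documented because
absolute latencies from causal hardware will differ. No artifact
rejection is applied; all epochs are retained.

Because re-referencing is a purely spatial linear map, it commutes with
filtering and averaging; the orchestrator exploits this and applies the
reference transforms to the filtered epoch average rather than to the
160-second continuous record, after computing that average over a
+/-50 ms padded window so the acausal filter sees the data it needs. The
equivalence with the literal filter-then-re-reference-then-epoch order is
exact up to filter ring-down truncation (below $10^{-5}$ relative) and is
asserted in the tests.

Wave scoring makes the clinician's judgement explicit: within
rate/level-shifted search windows (I: 1.0-2.4, III: 3.0-4.4, V:
4.8-7.2 ms at 80 dB / 25/s), the largest positive local maximum is the
peak; its time is refined by three-point parabolic interpolation (at
20 kHz the 0.05 ms sample grid would otherwise dominate the latency
error); amplitude is peak minus the lowest point in the following 1.5 ms
(peak-to-trough, the dominant clinical convention and offset-invariant; a
baseline-to-peak switch is provided). A wave is declared absent when no
local maximum of the demeaned trace exceeds twice the RMS of its
8.5-10 ms tail. Flat traces yield `found = FALSE`, never a fabricated
peak, and interwave latencies involving an absent wave are `NA`.

## What the defaults reproduce

```{r, eval = FALSE}
cfg <- defaultRunConfig(seed = 20220408, nSubjects = 10,
                        conditions = data.frame(rate = 25, level = 75),
                        nStimuli = 4000, trials = 1)
ex <- runExperiment(cfg, outDir = "abr-report")
ex$summaries[["r25_l75"]]
```

On the default seeded session the pipeline recovers mean I-III and III-V
interwave latencies of 2.05 and 1.95 ms (within a sample) identically for
AR, REST and MM -- re-referencing never moves a peak -- while wave V
amplitudes order MM > REST > AR in every subject with an MM:AR ratio
above 2. Across the rate grid (10-100/s at 75 dB) and the level grid
(80-45 dB at 25/s), measured wave V latency increases monotonically with
rate and with attenuation, for every method. These are the quantities the
test suite asserts and `scripts/acceptance.R` recomputes; the vignette
states no number the code does not produce.

Default problem sizes (10 subjects x 4000 epochs x 32 channels at 20 kHz
for the summary tables; one subject at 1000 epochs per condition for the
rate/level series) were chosen as the smallest runs on which the
stochastic checks are stable.

## Limitations

* The head is a concentric sphere; real skulls are neither spherical nor
  homogeneous, so absolute microvolt values (and hence the exact
  amplitude ratios of the published tables) are outside what a synthetic
  study can certify -- only their ordering and the latency invariances
  travel.
* The generator is one equivalent dipole per response class; real ABR
  generators are distributed along the auditory pathway.
* Background noise is stationary; blinks, EMG bursts and electrode drift
  are not modelled, so the no-artifact-rejection choice is benign here in
  a way it may not be on real data.
* The EDF reader covers the common single-rate EDF/EDF+C layout used by
  the writer; exotic multi-rate files are out of scope.
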