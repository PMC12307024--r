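---
title: "Frequency-tagging EEG analysis with rifteeg: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagging EEG analysis with rifteeg: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rapid invisible frequency tagging (RIFT) modulates stimulus properties —
pixel luminance of a picture, amplitude of a spoken distractor — with
sinusoids above the perceptual flicker-fusion range (here 68 Hz visual and
54 Hz auditory). The brain's steady-state evoked potentials (SSEPs) then
carry narrowband power at exactly those frequencies, and the power indexes
attentional allocation to each tagged stimulus. When the two driven neural
responses interact *nonlinearly*, additional spectral components appear at
the intermodulation frequencies $f_2 \pm f_1$ (here $68-54 = 14$ Hz and
$68+54 = 122$ Hz); a multiplicative interaction is the minimal mechanism,
since

$$\sin(2\pi f_1 t)\,\sin(2\pi f_2 t)
  = \tfrac{1}{2}\cos\!\big(2\pi(f_2-f_1)t\big)
  - \tfrac{1}{2}\cos\!\big(2\pi(f_2+f_1)t\big).$$

`rifteeg` implements the full analysis chain for such an experiment on
*synthetic* data: a seeded generator of multi-channel EEG epochs, minimal
preprocessing, boxcar-tapered power spectra with a percentage-power-change
statistic, a two-tailed cluster-based permutation test over a scalp
adjacency graph, and the per-participant electrode-selection contrast at
the intermodulation frequency with its two validation procedures.

## The generative model

Each trial of `simulate_dataset()` is 1,000 ms of baseline followed by
1,000 ms of tagging, sampled at 1000 Hz, over a 31-channel 10–20 montage
(time 0 = tagging onset). The baseline contains only background activity;
the tagging window adds three phase-locked sources, each projected to the
scalp through a fixed topography $w \in [0,1]^{31}$ (maximum weight 1):

* auditory drive $w^{a}\, A\, \sin(2\pi f_1 t)$, broad topography;
* visual drive $w^{v}\, B\, \sin(2\pi f_2 t)$, occipital/central topography;
* interaction $w^{im}\, g_c\, \big(A \sin 2\pi f_1 t\big)\big(B \sin 2\pi
  f_2 t\big)$, left-frontal topography, with a condition-dependent gain
  $g_c$.

The interaction gain is the experimental effect: $g_{\mathrm{unrelated}}
\ge g_{\mathrm{related}} \ge 0$, i.e. the representations of picture and
distractor interact more strongly when they are unrelated. By the
product-to-sum identity each intermodulation component has amplitude
$g_c A B / 2$, hence bin power $(w^{im} g_c A B / 2)^2 / 4$ — the
closed-form oracle used in the tests.

Background activity is 1/f Gaussian noise plus a 10 Hz alpha oscillation
with a random phase per trial and a posterior topography. The noise is
synthesized in the frequency domain (white Gaussian traces filtered by the
amplitude profile $f^{-\chi/2}$, zero at DC, rescaled so the broadband
standard deviation equals `noise_sd`), which gives exactly the target
spectrum without filter transients. Per participant, the two source
amplitudes are jittered by independent log-normal factors
(`participant_jitter_sdlog`), so some simulated participants show weak
tagging peaks, as real cohorts do.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_participants` | 30 | cohort size of a typical RIFT EEG study |
| `n_trials_per_condition` | 55 | usual per-condition trial yield after artifact rejection |
| `f_audio`, `f_visual` | 54, 68 Hz | above the flicker-fusion range; difference lands on the 1 Hz grid at 14 Hz |
| `amp_audio`, `amp_visual` | 2 µV | SSEP amplitudes of a strong tag |
| `g_related`, `g_unrelated` | 0.25, 0.75 | set by an analytic power calculation (below) so the condition effect is clearly detectable at full scale and recoverable in reduced cohorts; calibration knobs, not effect-size estimates |
| `noise_sd` | 8 µV | broadband background EEG magnitude |
| `noise_exponent` | 1 | canonical 1/f slope of resting EEG |
| `alpha_amp` | 10 µV | prominent posterior alpha |
| `participant_jitter_sdlog` | 0.3 | between-participant SSEP variability; leaves a minority of participants without visible peaks |

The power calculation behind the gains: with a 1 s window, the 14 Hz noise
bin power is roughly $\sigma^2 (1/14) / \sum_{f=1}^{500} (1/f) \approx
0.66$ µV², and the per-participant percent-change noise standard deviation
is $\approx 141/\sqrt{n_{\mathrm{trials}}}$ percentage points per
condition. The default gains put the related/unrelated difference of
intermodulation bin power at $(0.75^2 - 0.25^2)(AB/2)^2/4 = 2$ µV², i.e. a
percent-change difference of roughly 75 points — a paired-t effect around
$t \approx 3$ in a 10-participant, 15-trial-per-condition run and far
larger at full scale.

### What the generator does *not* emulate

Trial-to-trial amplitude drift, non-stationary alpha, line noise,
eye/muscle artifacts, volume-conduction correlations between channels
(noise is independent per channel), latency jitter of the driven response,
and any semantic/behavioral structure. Passing tests therefore show that
the *analysis chain* is correct and calibrated under a model that satisfies
its assumptions — not that the pipeline is robust to every pathology of
real recordings.

## The analysis chain

**Spectra.** `windowed_power()` extracts the 1,000 ms window, applies a
single rectangular (boxcar) taper spanning the full window, and evaluates
the DFT on the requested grid (default 1–80 Hz, 1 Hz steps — the native
resolution of a 1 s window, so on-grid components do not leak). We read
"each frequency step modulated with a boxcar taper, then Fourier
transformed" as this single full-window rectangular taper, the only reading
on which 1 Hz steps are natural. Power convention: a unit-amplitude on-grid
sinusoid has bin power $1/4$ (one-sided, amplitude²/4, no doubling).
Single-trial power is averaged within condition — not the complex spectra —
so components with weak cross-trial phase coherence survive. The 122 Hz sum
component is reachable only via an explicit extended grid (`f_hi = 150`),
because the default grid ends at 80 Hz.

**Percent change.** `percent_change()` computes
$((P_{\mathrm{tag}} - P_{\mathrm{base}}) / P_{\mathrm{base}}) \times 100$
per participant, condition, channel and frequency. A zero baseline cell is
a hard error naming the offending cell rather than a silent `Inf`.

**Preprocessing.** `bandpass_notch()` is a zero-phase (forward–backward)
Butterworth cascade: order-2 high-pass at 0.1 Hz, order-6 low-pass at
100 Hz, order-2 band-stops of half-width 1.5 Hz at 50/100/150 Hz. The
orders and half-width were chosen so the 50 Hz line drops by more than
20 dB while the 54 Hz tag, only 4 Hz away, keeps >96% of its RMS.
Re-referencing subtracts the mean of the named reference channels;
interpolation replaces a bad channel by the *equal-weighted* mean of its
adjacency neighbors — the simplest auditable choice where only "a weighted
average of neighboring channels" is specified; spherical-spline weighting
is deliberately out of scope. The default pipeline leaves filtering off:
the generative model contains no line noise or drift, so the cascade would
only add edge effects; it is exercised by its own tests and available via
`preprocess$enabled`.

**Cluster permutation test.** `cluster_test()` computes per-electrode
paired t statistics, marks electrodes with two-tailed $p <$
`alpha_form` (default 0.05 on the $t_{n-1}$ reference — the conventional
cluster-forming threshold), and forms clusters as connected components of
same-sign significant electrodes in the montage adjacency graph; at least
two electrodes are required, and the cluster mass is the sum of member t
values. The null distribution flips each participant's condition labels
independently with probability ½ — the paired-exchangeability reading of
"randomly separated into two artificial groups" that a dependent-samples t
test requires — and records the maximum |mass| per permutation (0 if no
cluster forms). Both tails share this single max-|mass| null, and each
observed cluster gets $p = (1 + \#\{null \ge |mass|\})/(1 + n_{perm})$,
compared to `alpha` (not `alpha/2`); the +1 correction keeps p values valid
and strictly positive in finite samples. Whether the original analysis used
separate per-tail nulls at `alpha/2` cannot be determined from its
description; the convention here is stated, not attributed. An
`exhaustive = TRUE` mode enumerates all $2^n$ flips, making the p value an
exact enumeration probability — the tests verify this against a from-scratch
oracle. Degenerate electrodes (zero-variance differences) give $\pm\infty$
t with a warning and count as significant; all-zero differences give
$t = 0$.

**Electrode selection.** Per participant, the six electrodes (`k = 6`,
configurable) with the largest percent change at the target frequency —
*averaged over the two conditions*, so the selection favors neither — are
reduced to the largest connected component of the induced adjacency
subgraph (singletons are legal here, unlike permutation clusters). Ties in
the top-k ranking are broken by montage order; size ties between components
go to the component holding the largest percent-change value, then montage
order. The cluster-mean percent change per condition feeds a two-tailed
paired t test (related − unrelated) with signed Cohen's
$d = \bar d / s_d$. Two validations: the same procedure at 12/13/15/16 Hz
(a genuine intermodulation response peaks exactly at 14 Hz), and at
54/68 Hz (the selection should land on the configured auditory/visual
topographies).

**Pipeline and gating.** `run_pipeline()` runs simulate → (optional
preprocess) → spectra → tagging-vs-baseline cluster tests at 54/68/14 Hz
(conditions combined) → percent change → condition contrasts — but a
condition contrast is computed *only* when the corresponding
tagging-vs-baseline test is significant, and the 14 Hz selection contrast
is gated the same way. Reports are fully reproducible from config + seed
(permutation seeds are fixed offsets of the master seed), and `write_report()`
emits a deterministic JSON/TSV bundle with a manifest.

## Numerical choices

* DFT via an explicit complex-exponential matrix on the requested grid;
  identical convention for on- and off-grid frequencies.
* Noise synthesis packs two real traces per complex FFT column (the real
  and imaginary parts of a symmetric-filtered complex trace are independent
  filtered traces), for speed without changing the distribution.
* Connected components by a plain BFS on the adjacency matrix — it sits in
  the permutation hot loop; `igraph` serves as the independent oracle in
  the tests, never as the implementation.
* Permutation t statistics are vectorized over permutations using the
  sign-flip identity: flipping signs leaves $\sum d_i^2$ unchanged, so only
  the permuted means are recomputed.
* The epoch container is a single file with a JSON header line followed by
  little-endian float64 samples; round trips are bit-exact. Config files
  (YAML/JSON) serialize doubles at 17 significant digits so a written
  config regenerates a bit-identical dataset.

## Verification experiments and their sizes

The test suite includes four simulation experiments; sizes are the
package's chosen verification scale.

* **Type-I calibration** — 200 null datasets (equal gains, 10
  participants, 31 channels, 15 trials per condition; trial count is a free
  choice since calibration does not depend on it), 500 permutations each:
  the fraction of datasets with any significant 14 Hz condition cluster
  must lie in [0.02, 0.09], the 95% binomial band around the nominal 0.05.
* **Oracle equivalence** — exhaustive-enumeration p equals the from-scratch
  enumeration oracle (7 participants, 4 electrodes); cluster formation
  equals brute-force connected components over all 64 significance patterns
  of a 6-node graph.
* **Effect recovery** — 100 seeded runs at the default gains (10
  participants, 15 trials per condition): the 14 Hz selection contrast must
  be significant with related < unrelated in the majority, and over a fixed
  40-seed set the detection count must not decrease as $g_{\mathrm{unrelated}}$
  rises through 0.25, 0.50, 0.75.
* **Qualitative pattern** — one full-scale default run (seed fixed in
  advance): significant 54/68/14 Hz tagging-vs-baseline clusters with
  occipital electrodes in the 68 Hz cluster, no base-frequency condition
  clusters, a significant negative 14 Hz selection contrast, and a 12–16 Hz
  validation peak at exactly 14 Hz. The base-frequency condition contrasts
  are true nulls, so this run carries the usual α-level false-positive risk
  per contrast; the seed was not selected on the outcome.

## Known limitations

* Channel noise is spatially independent; real EEG noise is strongly
  correlated across neighboring electrodes, which typically makes cluster
  tests *more* conservative than on this synthetic model.
* The interaction is instantaneous and multiplicative; physiological
  nonlinearities with latency or saturation would spread intermodulation
  energy across more components (e.g. $2f_1 - f_2$).
* Equal-weight interpolation and the schematic 2-D montage geometry are
  idealizations; no spherical geometry is modeled.
* The cluster-forming threshold and the single two-tailed max-|mass| null
  are conventions; alternatives (per-tail nulls, TFCE, size-based mass) are
  not implemented.
* Inter-trial coherence is not implemented; the power analysis is the sole
  spectral statistic.
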