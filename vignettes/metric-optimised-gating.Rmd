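---
title: "Metric-optimised gating: model, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-optimised gating: model, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mogflow)
```

## The problem

Phase-contrast (PC) cine MR measures blood flow by encoding through-plane
velocity into the phase difference between two interleaved acquisitions:
a pixel moving at velocity $v$ acquires phase $\pi v/\mathrm{VENC}$ in the
flow-encoded image relative to the flow-compensated one, and summing
$v \cdot A_{\mathrm{pixel}}$ over the vessel cross-section gives the
instantaneous flow. Cine PC needs cardiac gating, but no usable fetal ECG
exists inside the magnet: the fetus is electrically insulated and the
maternal ECG contaminates any signal. Metric-optimised gating (MOG) solves
this retrospectively. Each k-space segment is acquired continuously for
longer than one heartbeat, so every cardiac phase is sampled; the data are
then reconstructed under *hypothetical* trigger times generated from
candidate heart rates, and an image metric quantifying mis-gating artefact
selects the hypothesis — and hence the reconstruction — that best matches
the true rhythm.

`mogflow` implements the full chain: a segmented two-encoding k-space
acquisition simulator with known ground truth, the entropy-driven gating
search, cine reconstruction and flow integration, the fetal
shunt-accounting arithmetic for the distribution of the circulation, and
the agreement statistics (Pearson/regression and Bland–Altman) used to
validate paired flow measurements.

## The gating model

A constant heart rate is assigned to each half of the acquisition
(`TriggerHypothesis`), so a hypothesis is a pair $(h_1, h_2)$ in bpm.
Cardiac phase is the fractional part of the cumulative phase

$$\phi(t) = \begin{cases} t\,h_1/60 & t \le t_{\mathrm{mid}} \\
t_{\mathrm{mid}}\,h_1/60 + (t - t_{\mathrm{mid}})\,h_2/60 & t >
t_{\mathrm{mid}},\end{cases}$$

continuous across the midpoint: the pending fraction of a cycle carries
over rather than resetting, which keeps the hypothesis a two-parameter
family. Two intervals are the default; the same machinery applies per
interval if the acquisition is split further, at proportional cost.

Each measured k-space line is assigned to phase bin
$\lfloor \mathrm{frac}(\phi)\, n_{\mathrm{phases}} \rfloor$ (half-open
bins). Multiple lines landing in the same (k-row, phase, encode) cell are
complex-averaged. A cell left empty — possible when the oversample window
covers less than one hypothetical cycle — is filled from the nearest
occupied phase bin of the same k-row and encode in cyclic distance, the
forward neighbour winning ties; the number of fills is reported so a
reconstruction that needed them is never silently trusted. Inverse 2D
Fourier transforms per phase and encode give the cine, and the
phase-difference of the two encodes gives velocity (principal value only:
aliased velocities are flagged at simulation time, not unwrapped).

## The metric

The metric is Shannon entropy over a user-drawn region containing the
target vessel and its ghosting band. With ROI magnitudes $m_j$ pooled
across all cardiac phases, $p_j = m_j/\sum_k m_k$ and
$E = -\sum_j p_j \log p_j$. $E$ is scale-invariant, zero for a single
bright pixel, and maximal ($\log N$) for a uniform region. Mis-gating
replicates the pulsatile vessel along the phase-encode direction and dims
the coherent vessel signal, spreading magnitude across the region and
raising $E$; the accepted reconstruction minimises it. The metric is
evaluated on the magnitudes of the flow-encoded frames, the encoding in
which the pulsatile phase modulation (and hence the ghosting) lives;
velocity images were rejected as the metric substrate because their
background is noise-dominated phase. Because entropy measures
*concentration against the background*, the metric region must be
signal-sparse around the vessel — a bright uniform background sits at the
entropy maximum already and mis-gating can then move the metric the wrong
way. The ROI is therefore drawn as a strip along the full phase-encode
extent at the vessel's read-out columns, covering the ghost band, over
low-signal surroundings.

## The search

The entropy surface over $(h_1, h_2)$ is mapped exhaustively at 1 bpm over
the physiological band 110–180 bpm (`metricMap`), in deterministic order,
exactly as a clinician reviews the map before accepting a fit. A flatness
statistic $(\max - \min)/\mathrm{mean}$ guards the degenerate case: a
non-pulsatile target yields a flat map (flatness below $10^{-3}$) whose
argmin is noise, and the map is flagged uninformative.

Sub-bpm refinement is exhaustive too: a 0.1 bpm grid over ±2 bpm around
the coarse argmin, then a pattern search (single-rate and joint ±0.1 bpm
moves) until the improvement drops below $10^{-6}$. Two properties of the
surface force this design, both visible in simulation. First, bin
assignments flip discretely as rates change, so the surface is rugged at
sub-bpm scale and a descent from the coarse argmin stalls on spurious
dips; the basin around the true rates is only a few tenths of a bpm wide,
narrower than the coarse step. Second, hypotheses trading $h_1$ against
$h_2$ while preserving the average rate form a shallow valley, so
single-coordinate moves alone are blind along the valley floor — the
pattern search includes joint moves for that reason. The compiled search
core makes the exhaustive stages affordable by two exact factorisations:
the inverse FFT along the read-out dimension commutes with complex
averaging, so each measured line is transformed once and only the image
columns the ROI touches are reconstructed; and first-half cell sums depend
only on $h_1$, so they are cached across the $h_2$ sweep. The test suite
pins the compiled path to the plain R reference pipeline
(`binMeasurements` → `reconstructCine` → `imageEntropy`) on toy
acquisitions.

## What the simulator emulates, and what it does not

`PhantomSpec`/`acquire` implement the forward model the gating search
inverts: circular vessels carrying a parabolic (Poiseuille) through-plane
profile scaled so the lumen-mean velocity follows a named waveform;
two encodings interleaved line by line with timestamps advancing by TR;
k-space lines sampled from the DFT of the frame rendered at the true
cardiac phase of each timestamp; additive complex Gaussian k-space noise.
Beat times come from a constant, two-level, or bounded random-walk rate
model. The waveform library covers the qualitative patterns of the major
fetal vessels: brisk systolic arterial ejection, late-systolic ductal
flow, continuous-diastolic descending aortic flow, a biphasic caval
pattern with brief reversal at atrial contraction, continuous venous flow,
and an antegrade-systolic/retrograde-diastolic branch-pulmonary pattern.

Deliberate design choices, fixed once:

* **Geometry and contrast.** Lumen edges are rendered with 4× supersampled
  area weighting. Each vessel sits in a static bright tissue sleeve
  (default 2 mm, same signal as blood) over a dark background (5% of
  lumen signal). The sleeve is what makes flow integration honest: a
  bright lumen against dark surroundings lets edge pixels' phase be
  dominated by the (bright) moving spins, overestimating flow by several
  percent at 3–5 pixels per diameter, while the ghost strip away from the
  vessel stays dark so the entropy metric keeps its direction.
* **Velocity scale.** Default peak lumen-mean velocity 60 cm/s at VENC
  150 cm/s: the parabolic centre-line maximum (twice the mean) then stays
  at 80% of VENC, clear of aliasing. Scaling a waveform beyond VENC wraps
  the phase and warns.
* **Noise.** SNR is defined on a single reconstructed frame:
  `noiseSdForSNR` converts a target lumen SNR into the k-space noise SD
  (with an unnormalised forward FFT, image-domain noise is k-space SD
  divided by matrix size).
* **Rendering.** Frames are rendered at cardiac phase quantised to 1/720
  cycle so repeated phases share one render; this is far below the
  temporal resolution of any protocol simulated.

Omitted on purpose: slice-profile and relaxation effects (including
inflow enhancement, so vessel *magnitude* is static and all gating
information lives in the phase modulation — strictly harder than real
arterial data, where pulsatile magnitude adds ghosting energy), flow
displacement artefacts, eddy-current background phase, parallel imaging,
fetal motion, and 3D acquisition. Passing the simulation suite therefore
shows the gating search recovers rhythm and flow from k-space timing and
velocity-phase structure alone; it does not certify behaviour under bulk
motion or background-phase errors, which real fetal studies must manage
separately.

## Study conditions and problem sizes

The standard validation configuration (`simStudy`) is a 6 mm vessel at
1.25 mm pixels — the fetal protocol's in-plane resolution, 4.8 pixels per
diameter, within the 3–8 px/diameter range regarded as sufficient for PC
flow accuracy — on a 64×64 matrix over an 80 mm field of view, TR
6.55 ms, VENC 150 cm/s. One view per segment gives 64 segments of 0.7 s,
a 44.8 s scan emulating the segment count and duration of the fetal
per-vessel acquisitions at reduced matrix size. The oversample window
exceeds the longest R-R in the 110–180 bpm band (0.545 s). Searches use
10 phase bins — the true phase count of the published protocol (R-R
520 ms at 52.4 ms resolution) — and final cines are interpolated to 15
calculated phases, the published convention. The packaged experiments run
20 seeded recoveries with rates drawn uniformly from 120–160 bpm and
single-frame SNR cycling noiseless/40/20, a two-level 130/150 bpm
recovery, and an end-to-end flow comparison at SNR 20 against the
analytic ground truth $\bar{f} = \overline{w}\,v_{\mathrm{peak}}\,\pi
R^2$.

## Flow integration and its biases

`flowCurve` sums masked velocities times pixel area per phase; the mean
over uniformly spaced phases equals the cyclic trapezoidal mean. Masks
are static across the cycle (no contour tracking), either user-supplied
or the simulator's centre-inside lumen mask. Two small systematic effects
are worth knowing. Partial-volume weighting: with the tissue sleeve the
dense-rendered flow integral sits within a fraction of a percent of the
analytic truth at 4.8 px/diameter. Phase binning: complex-averaging
k-space within a phase bin mixes systolic phase angles nonlinearly and
shaves a few percent off the cycle mean at 10 bins; the effect shrinks
with narrower bins and is covered by the end-to-end accuracy margin.

## Fetal shunt accounting

With mean flows indexed to estimated fetal weight (from segmented volume
via $0.12 + 1.031 \times V_{\mathrm{ml}}$ grams), the derivation chain
is: CVO $= 1.03\,(\mathrm{MPA} + \mathrm{AAo})$, the 3% standing in for
coronary flow; indirect PBF $= \mathrm{MPA} - \mathrm{DA}$; FO $=$ CVO
$-$ MPA $-$ PBF, i.e. left-ventricular filling not supplied by the lungs;
direct PBF $= \mathrm{RPA} + \mathrm{LPA}$ where both branches were
measured. The FO–PBF regression deliberately uses *direct* PBF so the
response is independent of the derived predictor. Negative derived values
are physiologically meaningful (net retrograde flow) and are flagged,
never clipped. Report tables round half away from zero at the last step
only; cohort summaries are sample mean ± SD ($n-1$), computed pairwise
over the subjects with each quantity available. Whether published tables
indexed before or after rounding is unknowable from print; comparisons
therefore allow ±1 in the final integer.

## Numerical choices

* Bin rule $\lfloor \mathrm{frac}(\phi)\,n\rfloor$ with half-open bins;
  a phase of exactly 1.0 cannot occur (fractional part), and the floor is
  clamped to $n-1$ against floating-point spill.
* Empty-cell fill: nearest occupied cyclic phase, forward preferred on
  ties; deterministic and reported.
* Flatness threshold $10^{-3}$ relative range separates genuinely flat
  (static-object) maps, which sit at machine-precision flatness, from
  informative maps, which sit orders of magnitude above it.
* Refinement tolerance $10^{-6}$ absolute entropy change; entropy values
  for realistic ROIs are $O(1{-}10)$ nats.
* Limits of agreement at bias ± 1.96 SD; both bias ± SD and the limits
  are reported, since published summaries quote mean difference ± SD.
* Pearson p-values from $t = r\sqrt{(n-2)/(1-r^2)}$, two-sided, $n-2$ df.

## Limitations

The two-interval rate model tolerates slow drift, not beat-to-beat
variability; the random-walk simulations quantify the degradation but no
per-beat correction is attempted. The entropy surface is rugged, so the
search cost is dominated by exhaustive evaluation; segment counts beyond
two rate intervals would square the grid. No background-phase correction,
vessel tracking, automatic segmentation, DICOM handling, or unwrapping is
provided. The acquisition container serialises to CSV/YAML and cines to
NIfTI; no scanner-native formats are read.
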