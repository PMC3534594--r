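# mogflow

Metric-optimised gating (MOG) and flow quantification for fetal
phase-contrast cine MR, in R.

Fetal blood-flow measurement by phase-contrast (PC) MR has no usable
cardiac trigger: the fetal ECG is electrically shielded by the mother.
MOG removes the trigger requirement retrospectively. Each k-space segment
is acquired continuously for longer than one heartbeat, the data are
reconstructed under hypothetical trigger trains generated from candidate
heart rates — one constant rate per half of the acquisition,
$(h_1, h_2)$, with cardiac phase continuous across the midpoint — and the
hypothesis minimising an image-entropy metric of mis-gating artefact,

$$E = -\sum_j p_j \log p_j, \qquad p_j = m_j \Big/ \sum_k m_k,$$

over the ROI magnitudes $m_j$ of the flow-encoded frames across all
cardiac phases, is accepted. Velocity comes from the phase difference of
the two encodings, $v = \mathrm{VENC}\cdot\Delta\phi/\pi$, and vessel
flow from $\sum_{\mathrm{mask}} v \cdot A_{\mathrm{pixel}}$ per phase.

The package provides, as S4 classes with plain-text I/O:

* a **segmented k-space acquisition simulator** (`PhantomSpec`,
  `acquire`) — pulsatile vessels with parabolic profiles and
  vessel-typical waveforms, two interleaved velocity encodings, timestamped
  lines, beat-time ground truth, complex Gaussian noise;
* the **MOG search** (`metricMap`, `mogOptimize`) — exhaustive entropy
  map over 110–180 bpm, compiled grid evaluation, sub-bpm refinement,
  flatness diagnostics, cine reconstruction and phase interpolation;
* **flow quantification** (`flowCurve`, `meanFlow`) and NIfTI/CSV export;
* **fetal shunt accounting** (`deriveFlows`, `percentCVO`,
  `cohortSummary`, `foPbfRelationship`) — combined ventricular output
  (CVO = 1.03·(MPA+AAo)), indirect pulmonary blood flow (PBF = MPA−DA),
  foramen ovale shunt (FO = CVO−MPA−PBF), weight indexing, %CVO, with the
  twelve-subject late-gestation cohort table shipped as a fixture;
* **agreement statistics** (`agreementReport`, `blandAltman`) — Pearson
  correlation, regression, Bland–Altman bias and limits of agreement;
* a command-line tool (`exec/mogflow`) with `simulate`, `mog`, `flow`,
  `cohort` and `agree` subcommands over CSV/YAML/NIfTI files.

## Worked example

Cohort arithmetic from the shipped per-subject table (flows in ml/min/kg):

```r
library(mogflow)
d <- deriveFlows(readSubjectTable())
round(d[d$subject %in% c(1, 12),
        c("subject", "mpa", "aao", "da", "cvo", "pbf_indirect", "fo")])
#>    subject mpa aao  da cvo pbf_indirect  fo
#> 1        1 278 155 188 446           90  78
#> 12      12 229 177 223 418            6 183
```

Subject 1's combined ventricular output is 446 ml/min/kg (MPA 278 plus
AAo 155, plus 3% for coronary flow); 90 ml/min/kg reaches the lungs
(MPA − DA) and 78 ml/min/kg crosses the foramen ovale. Cohort summaries
and the inverse FO–PBF relationship:

```r
cohortSummary(d, c("mpa", "aao", "fo", "cvo"))   # mean / SD / n
#>   quantity mean  sd  n
#>        mpa  327  68 12
#>        aao  198  38 12
#>         fo  107  54 12
#>        cvo  540 101 12
fit <- foPbfRelationship(readSubjectTable())
#> PBF = -0.84 x FO + 170.47  (R = -0.91, p = 0.002, n = 8)
```

The less blood a fetus passes through its lungs, the more crosses the
foramen ovale to fill the left heart — the two left-ventricular inflow
sources trade off almost one for one.

End-to-end simulation — acquire an ungated scan of a 6 mm pulsatile
vessel at single-frame SNR 20, recover the rhythm, and integrate flow:

```r
st  <- simStudy(snr = 20)
acq <- acquire(st$spec,
               HeartRateProfile("constant", 142, duration_s = st$duration_s),
               st$protocol, seed = 42)
res <- mogOptimize(acq, st$roi)
#> accepted rates: (141.9, 142.1) bpm; entropy 8.0104; flatness 0.016
fc <- flowCurve(res$cine, st$mask)
meanFlow(fc)
#> mean flow 192.2 ml/min (ground truth 189.7)
```

The true 142 bpm rhythm is recovered to 0.1 bpm from k-space timing
alone, and the integrated mean flow lands within 1.5% of the analytic
ground truth.

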