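---
title: "Methods: normative band-power mapping and abnormality lateralisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative band-power mapping and abnormality lateralisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models, the defaults and the design choices
behind `eegnorm`, in the spirit of a methods section: what is computed,
under which assumptions, and what the synthetic validation does and does
not demonstrate.

## The model

For each cortical region $i$ and band $j$ (delta 1–4, theta 4–8, alpha
8–13, beta 13–30, gamma 30–47.5 Hz), relative band power is
$x_{ij} = P_{ij} / \sum_j P_{ij}$, with $P_{ij}$ the Welch PSD integrated
over the band. A normative map is the healthy-cohort mean $\mu_{ij}$ and
sample SD $\sigma_{ij}$ (denominator $n-1$) of $x_{ij}$. Patient
abnormality is $z_{ij} = (x_{ij}-\mu_{ij})/\sigma_{ij}$, summarised per
region by $\max_j |z_{ij}|$ because no band is privileged a priori.
Lateralisation compares this indicator between the hemisphere ipsilateral
and contralateral to the epileptogenic side over homologous temporal
pairs: per pair, paired differences $d_p$ across patients give Cohen's
$d_z = \bar d / s_d$ and $t = d_z\sqrt n$. Both are reported: the
literature's phrase "paired t-test effect size" is ambiguous between them,
and they differ only by $\sqrt n$.

The analysis is restricted to 0.5–47.5 Hz: above that, scalp signal is
strongly attenuated by skin/bone conductivity and contaminated by mains
artifact. Relative (not absolute) power removes the per-subject global
scale, which scalp recordings cannot calibrate.

## Processing chain and its defaults

1. **Resampling** to 250 Hz (anti-alias low-pass at 80% of the target
   Nyquist, polyphase).
2. **Band-pass** 0.5–47.5 Hz, Butterworth order 4 applied
   forward–backward. The filter family/order is not dictated by the
   method; zero-phase Butterworth is chosen for a flat passband and no
   phase distortion, and the order is configurable.
3. **Common average reference** over good EEG channels. Bad channels are
   excluded from the average, the projector and the inverse — never
   interpolated.
4. **Cardiac SSP.** R-peaks are detected on the ECG channel
   (Pan-Tompkins-like: 5–35 Hz band-pass, squaring, 150 ms centred
   envelope, adaptive threshold at mean + 2 SD, 0.3 s refractory period).
   Epochs centred on the beats are averaged and the left singular vectors
   of the average form the artifact basis; `k = 1` component is projected
   out by default. Clinical practice selects components by inspection;
   here the explained-variance fractions are reported and `k` is a
   parameter — no specific selection rule is claimed to match manual
   choices. Ocular artifacts are deliberately not removed (eyes-closed
   recordings; the detector is unreliable for them and removal risks
   deleting biological signal).
5. **Settling discard**: the first 30 s are dropped.
6. **sLORETA.** Minimum-norm kernel $T = G^\top(GG^\top+\lambda C)^{-1}$
   with $\lambda = \mathrm{tr}(GG^\top)/(n_{ch}\,\mathrm{snr}^2)$,
   standardized per source by $\sqrt{\mathrm{diag}(TG)}$. Noise covariance
   defaults to identity (no empty-room recordings exist for EEG) and the
   assumed amplitude SNR defaults to 3; both are explicit parameters, not
   claims about any particular dataset. For noiseless probes (as in the
   zero-localisation-error validation) the natural choice is a high SNR,
   i.e. $\lambda \to 0$, where the standardized peak provably sits at the
   true source.
7. **Sign-flip ROI averaging.** Constrained sources on opposite sulcal
   walls reconstruct with opposite signs; within each region every source
   series is multiplied by the sign of its normal's projection on the
   region's principal orientation (first singular vector of the
   orientation matrix) before averaging. The overall sign of a region's
   series is arbitrary; all downstream quantities are power-based, so it
   cannot affect results (tested).
8. **Spectra.** One continuous 60-s epoch per recording (earliest valid
   placement), Welch PSD with 2-s Hann windows and 50% overlap, density
   scaling. Band integration is trapezoidal over the bins with
   $f_{min} \le f < f_{max}$; the half-open rule resolves the shared
   edges at 4, 8, 13 and 30 Hz, and the last band keeps 47.5 Hz. The
   normalisation denominator for relative power is the sum of the five
   band powers for that region.

## The synthetic study

No clinical recordings ship with the package; a generator produces a
study-scale synthetic cohort in which every stage has a known answer.

* **Geometry.** Sensors on a unit sphere (30 scalp positions), ~400
  sources on a cortical shell at radius 0.85, partitioned into 114
  regions: 54 mirrored left/right pairs plus 6 unpaired midline regions —
  the asymmetric-atlas situation that forces the symmetry analysis to
  drop unpaired regions — with the 13 most inferior lateral pairs
  labelled temporal. Orientations are radial with tangential jitter; 20%
  of sources are polarity-flipped (opposite sulcal wall), enough to make
  naive ROI averaging fail and the sign-flip step necessary, while
  keeping the gyral-dominated character of scalp EEG.
* **Leadfield.** Default "smooth-random": three spatially smooth random
  field components contracted with each source's orientation — linear in
  orientation like a physical gain, full row rank, but not a conductor
  model (volume conduction modelling is out of scope). An analytic
  homogeneous-sphere dipole model (Legendre series) is provided where
  localisation physics matters.
* **Source dynamics.** Each region carries one time series: per-band
  Gaussian noise shaped in the frequency domain by the squared order-4
  Butterworth band-pass magnitude (the spectrum a zero-phase filter
  would impose — synthesized spectrally for speed and exact
  calibration), weighted by the planted topography, plus a $1/f$
  background (exponent 1, 0.4 relative power, flattened below 0.5 Hz).
  The planted topography encodes the healthy pattern: alpha rising
  posteriorly, delta anteriorly and in temporal regions, theta
  frontal-midline, beta central, gamma low with a mild fronto-central
  bump. Every band has recoverable spatial structure, and homologous
  regions get identical profiles, so left–right symmetry is exact in
  truth.
* **Ground truth definition.** The planted relative band power is defined
  as the *expectation of the analysis measurement*: each component's line
  spectrum is smeared by the squared spectral window of the 2-s Hann
  taper and integrated with the same trapezoidal half-open rule the
  spectral stage uses. Defining truth through the measurement operator
  makes calibration tests compare like with like; defining it as raw
  spectral mass would conflate generator bias with estimator bias
  (Welch's window bias is real, and identical for data and truth).
* **Subject variability** is a lognormal factor per subject and band
  (log-SD 0.07) shared across regions, plus spectral estimation noise.
  The source study does not quantify healthy inter-subject variance; this
  free choice is set so that a 17-subject cohort pins normative means to
  about ±2 percentage points per cell — consistent with the
  near-perfect epoch reproducibility such maps exhibit — while keeping
  $\sigma_{ij}$ comfortably non-degenerate. Real cohorts are likely more
  variable; the parameter is configurable and the lateralisation
  analysis does not depend on its exact value.
* **Sensor model.** Gain-projected region signals, 5% white sensor noise,
  and a rank-1 cardiac artifact: one fixed random topography driven by a
  quasi-periodic QRS-like template train at ~1.1 Hz with 3% interval
  jitter, at twice the clean-signal RMS. Rank-1 by construction means one
  SSP component can remove it exactly, giving the SSP stage a known
  answer. An ECG channel carries the same train. Patients differ from
  controls only by multiplying the planted *delta* power in the affected
  temporal regions of their epileptogenic hemisphere (default factor 3 in
  the two most anterior temporal pairs; the left:right split of sides
  follows the 14:8 clinical proportion). The effect must be
  band-specific: a band-uniform power factor would cancel exactly in
  relative power. Delta is chosen to mirror interictal temporal slowing.

## What the validation shows — and what it does not

With sensor effects excluded (maps computed from the source-space region
series), a 17-subject cohort recovers every planted normative cell to
within 0.02 and non-overlapping 30-s epochs give rank correlations above
0.99 — the stationarity benchmark for the epoch-robustness analysis.
Through the full 30-channel chain, however, the inverse has rank 30 for
114 regions: source leakage mixes neighbouring spectra and biases each
region's relative power toward the global mean (mean absolute deviation
~0.03 at these settings). This is volume-conduction physics, not an
implementation defect; it is why patients are z-scored against a
normative map built by the *same* chain, so the leakage bias largely
cancels in $z$, attenuating but not invalidating planted effects — the
full-chain cohort still shows positive ipsilateral effect sizes in the
affected pairs. Synthetic validation therefore demonstrates correctness
and calibration of the pipeline, not that scalp EEG resolves 114 regions
independently.

Calibration of the lateralisation test is checked at the band-power-table
level (simulating recordings adds nothing to a question about the
statistic): with no planted effect, the per-pair paired $t$ holds its
nominal 5% level across 500 simulated 22-patient cohorts, scored against
a normative map built from a large (n = 400) healthy sample. The large
reference is deliberate: with a small reference cohort, the shared error
in $\hat\sigma_{ij}$ induces correlation across patients and inflates the
cross-patient paired test — a property of the statistic worth knowing,
not a bug to hide; the package keeps the clinical 17-subject default for
mapping while using the large reference to isolate the test's own
calibration.

Numerical conventions worth stating: sample SD everywhere ($n-1$);
Spearman correlation is Pearson on average-tied ranks and errors on
constant input; zero normative SD raises an error naming the cells rather
than producing infinities; zero-variance paired differences flag the
effect size as undefined; robustness/symmetry correlations pool the
region × band vector, so each region contributes one point per band; the
six unpaired regions are metadata of the parcellation, not hard-coded
names. Problem sizes used in the shipped analyses (400 sources, 200 for
the localisation benchmark, 500 replicate cohorts) were chosen as the
smallest at which the corresponding property is stable; all are
configurable upward.

## Known limitations

* The leadfield is a surrogate, not a boundary-element model; absolute
  localisation accuracy claims cannot be made from it.
* Eyes-open states, ocular artifacts and MR-gradient artifacts are not
  modelled; the artifact model is rank-1 cardiac only.
* Age/sex covariates are not modelled in the normative map.
* Cross-modality comparison operates on any two normative maps with
  shared region labels; acquiring real MEG/iEEG references is outside the
  package's scope.
* Subcortical structures (hippocampus, amygdala) are excluded by design:
  their signal attenuates too strongly to reach scalp sensors reliably.
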