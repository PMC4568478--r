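---
title: "Methods: DSC-MRI perfusion deconvolution and territory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSC-MRI perfusion deconvolution and territory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dynamic susceptibility contrast (DSC) MRI tracks a gadolinium bolus
through the brain with rapid T2\*-weighted imaging. Around
revascularization surgery (the motivating setting is the STA-MCA bypass
for moyamoya disease), the clinically interesting quantity is not an
absolute perfusion number but the *asymmetry* between the surgical and
the contralateral hemisphere, summarised per vascular territory, and how
that asymmetry changes from the pre-operative to the intra-operative
scan. A large immediate rise of the relative cerebral blood flow (CBF)
at the terminal MCA territory flags patients at risk of cerebral
hyperperfusion syndrome (CHS).

`dscperf` implements this analysis end to end, and — because no patient
data ship with it — pairs it with a digital phantom and cohort generator
whose ground truth is known exactly, so every stage can be validated
quantitatively.

## Signal and concentration model

The measured signal in a voxel is modelled as
\[ S(t) = S_0\, e^{-k\, TE\, C(t)} + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2), \]
with echo time $TE$ and an arbitrary relaxivity constant $k$ (set to 1:
only relative values are analysed downstream, so absolute calibration
drops out). Inversion is the standard
$C(t) = -\log(S/S_0)/(k\,TE)$, with:

* baseline $S_0$ = mean of the first `n_baseline = 8` frames (12 s at
  $\Delta t$ = 1.5 s — the bolus is injected after scan start);
* brain mask = voxels with $S_0$ above 10% of the 99th-percentile
  $S_0$;
* negative concentrations retained (clipping them would bias the AIF
  peak and the deconvolution input);
* non-positive signal floored at 1% of $S_0$ before the log, counted in
  a QC field.

Noise is Gaussian on the *signal* (magnitude MR noise at high SNR), not
on concentration; through the log it becomes heteroscedastic in $C$,
which is the realistic behaviour — deep signal dips carry noisier
concentration samples.

## Tissue model and the phantom

Tissue concentration follows the bolus-passage convolution
\[ C_v(t) = F \,\Delta t \sum_{\tau \le t}
   AIF(t - \tau - \text{delay})\, R(\tau), \qquad
   R(\tau) = e^{-\tau/\text{MTT}}, \]
an exponential residue (the conventional well-mixed single-compartment
choice; it makes CBV = CBF × MTT exact by construction). The arterial
input is a gamma-variate bolus, peak-normalised so that
`amplitude` is the peak concentration, with mode at $t_0+\alpha\beta$
(defaults $t_0$ = 15 s, $\alpha$ = 3, $\beta$ = 1.5 s).

The phantom atlas is a rectangular brain (default 32×32×10 voxels, 60
frames at $\Delta t$ = 1.5 s, TE = 30 ms) split into left/right
hemispheres, each carrying the five analysed territories (ACA
central/terminal, MCA central/terminal, PCA terminal), plus a dedicated
artery block holding the pure AIF and a background rim — 12 labels in
all. Default territory values (CBF 40–55 units, MTT 4.5–6 s) are
gray-matter-like and hemispherically symmetric.

Two scale constants tie flow units to signal contrast:

* `dsc_flow_scale()` (= 1/300) converts the nominal flow values to the
  per-second units of the convolution;
* the AIF `amplitude` (= 90) fixes the arterial peak.

They were chosen once so the simulated dynamics mimic a double-dose
(0.2 mmol/kg) clinical acquisition: tissue signal drops of roughly
20–70%, an arterial drop to under 10% of baseline, and arterial peak
concentration about twice the highest tissue peak. Reconstruction
divides by the same flow scale, so maps come out on the nominal input
scale, and relative values are independent of both constants.

What the phantom deliberately does **not** emulate: anatomy, slice
geometry of the original acquisition, partial-volume effects, contrast
recirculation, dispersion, motion. Passing tests therefore demonstrate
correctness of the *computational* chain under the stated forward
model, not robustness to those physical effects.

## AIF selection

The histogram-based search is made deterministic: per masked voxel the
features are peak concentration, time-to-peak, and a first-moment
transit-time proxy (first moment of the positive curve minus the
arrival time, defined as the first crossing of 20% of peak). Candidates
are voxels in the lowest `ttp_quantile = 0.1` of TTP *and* lowest
`mtt_quantile = 0.2` of the transit proxy; the `n_aif = 10` candidates
with the highest peak are averaged (ties broken by lower TTP, then
voxel order). An optional ROI mask stands in for a manual location
check, and a guard rejects selections whose mean peak is not clearly
arterial (below 1.5× the median masked peak) rather than silently
returning a tissue AIF. All knobs sit in the run configuration.

## Deconvolution

Discretising the convolution gives $C = A\,(F R)$ with
$A_{ij} = \Delta t\, AIF_{i-j+1}$ (lower-triangular Toeplitz, "simple"
mode) or, in "circulant" mode, the zero-padded AIF embedded in a
circulant matrix of dimension $2n$ (padding one full series length —
the standard anti-aliasing choice). The inversion is a truncated-SVD
pseudoinverse: singular values below `truncation` × (largest singular
value) are dropped.

Parameters per voxel: CBF is the maximum of $F R(t)$ over **all** time
points of the solution (in circulant mode including the padded tail,
which makes the estimate exactly invariant under cyclic delays); CBV is
the area under the positive part of $F R(t)$ within the acquisition
window; MTT = CBV/CBF. Negative SVD oscillations are zeroed before the
area integral but not before the peak. Voxels with a non-positive peak
are flagged and excluded from regional means.

Numerical choices that were genuinely open:

* **Quadrature.** The rectangle rule $\Delta t \sum F R$ overestimates
  the area of a sampled exponential by $+27\%$ at MTT = 3 s,
  $\Delta t$ = 1.5 s; the default is therefore trapezoidal (true area
  under the sampled curve), which brings the noise-free MTT bias below
  2.1% across the MTT 3–12 s range. The rectangle rule remains
  available as `quadrature = "rectangle"`.
* **Truncation defaults.** Fixed at 0.2 (simple) and 0.03 (circulant).
  The circulant value is the minimiser of the median absolute CBF error
  in a calibration sweep at baseline SNR 50 over CBF ∈ {20..80} ×
  MTT ∈ {3..12 s}; harder truncation (e.g. the 0.1 sometimes quoted for
  circulant SVD) is dominated by truncation bias (≈ 20% median error
  here). Truncated-SVD regularisation trades noise amplification
  against systematic underestimation, so the right strength depends on
  the noise level: noise-free validation experiments explicitly pass
  `truncation = 1e-6`, where the inversion of the (identical) discrete
  forward operator is exact.
* **CBV normalisation.** CBV is taken directly as the residue area (no
  AIF-area renormalisation); the integral identity
  area$(C_v)$/area$(AIF)$ = $F \cdot$ MTT is a tested property of the
  forward model.
* $F$ is treated as constant per voxel over the scan.

Known limitation, measured rather than hidden: with a fixed truncation
at the clinical operating point, per-voxel CBF errors at baseline SNR
50 have a median around 12% over the full physiological grid (worst in
short-MTT and very-high-CBV corners); this matches the error magnitudes
the DSC literature reports for truncated-SVD methods at a 1.5 s frame
interval. Relative (side-to-side) territory values are far more
accurate because the bias is common to both hemispheres. Similarly, the
simple-mode CBF under bolus delay is *below* its zero-delay value at
every tested delay but follows a sawtooth rather than a strictly
monotone decline — hard-truncation oscillation, visible in
`delay_experiment()`.

## Territory statistics

Regional means are arithmetic means over atlas labels (flagged voxels
excluded). Relative values are surgical-side over contralateral
regional means; percentage increase is the signed
$100\,(\text{intra} - \text{pre})/\text{pre}$ per subject, and group
percentage increases are means of per-subject changes (not the change
of the group means — with a 14.3% mean subject-level change the two
differ visibly at n = 5). Comparisons per parameter × territory: paired
two-tailed t-tests pre vs intra (all patients and per group), and
pooled-variance independent t-tests CHS vs non-CHS on the intra values
and on the percentage increases (Welch available as a flag).
Benjamini–Hochberg correction at FDR q = 0.2 is applied per parameter
over the 15-test family (5 territories × three test types), matching
the per-table structure of the reported results; the family composition
is configurable.

## The simulated cohort

The default cohort is 5 CHS and 9 non-CHS subjects. Each subject's
intra-operative surgical-side territory CBF is the pre-operative value
times $(1 + \text{effect} + e_i)$, $e_i \sim N(0, 0.07)$, with effect
+0.143 at MCA-terminal for CHS and 0 for non-CHS; the contralateral
side is untouched, CBV follows the central volume principle, MTT is
unchanged. Under this design the across-group percentage-increase test
at MCA-terminal has a theoretical power near 0.93 at $\alpha$ = 0.05
(effect/SD ≈ 2.0, n = 5 vs 9), which the simulation reproduces.
`simulate_cohort()` materialises image sessions; matching
`simulate_cohort_summaries()` produces the exact sidecar-implied
relative values without imaging, which is what the power and
calibration studies iterate on (1 000 cohort replicates at image level
would add nothing but deconvolution noise to a statistics question).

Problem sizes used by the packaged studies: full-pipeline checks run on
20×20×6 to 32×32×10 phantoms; recovery studies use 16-cell truth grids
with 40 noisy replicates per cell; power uses 200 simulated cohorts and
calibration 1 000 (5 000 independent territory draws per test type).

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical seeds give bit-identical phantoms, and
`run_session()` output is a deterministic function of its inputs and
configuration. The numbered scripts under `analysis/` replay the whole
study; `scripts/acceptance.R --seed N --out f.json` recomputes the
headline numbers from scratch.
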