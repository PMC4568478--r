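# dscperf

Perfusion-weighted MRI analysis for revascularization surgery: from a raw
4D dynamic-susceptibility-contrast (DSC) bolus-tracking series to voxelwise
CBF/CBV/MTT maps, vascular-territory asymmetry statistics, and group
comparisons that separate cerebral hyperperfusion syndrome (CHS) sessions
from controls.

## Who this is for

Quantitative-imaging researchers studying cerebral hemodynamics around
STA-MCA bypass (e.g. in moyamoya disease), where the clinically useful
readout is *semiquantitative*: the ratio of each territory's perfusion on
the surgical side to its contralateral homologue, and how that ratio
changes from the pre-operative to the intra-operative scan. The package
also ships a digital phantom and paired-cohort simulator with exact ground
truth, so the entire chain is testable without patient data.

## The model

Tissue contrast concentration follows the bolus-passage convolution

    C_v(t) = F Δt Σ_τ AIF(t − τ) R(τ),        R(τ) = exp(−τ/MTT)

with flow `F`, arterial input function `AIF(t)` and residue function
`R(t)`. Discretized, this is a linear system `C = A (F·R)` with `A` the
Δt-scaled AIF operator — lower-triangular Toeplitz ("simple" mode) or a
zero-padded block-circulant embedding ("circulant" mode, insensitive to
bolus delay). The system is inverted by a truncated-SVD pseudoinverse;
then per voxel

* CBF = peak of `F·R(t)`,
* CBV = area under the (positive part of) `F·R(t)`,
* MTT = CBV / CBF (central volume principle).

Maps are averaged over a left/right vascular-territory atlas
(ACA-central/terminal, MCA-central/terminal, PCA-terminal), converted to
surgical/contralateral relative values and per-subject percentage
increases `100·(intra − pre)/pre`, and compared with paired and
pooled-variance independent t-tests under Benjamini–Hochberg FDR control
(q = 0.2, one 15-test family per parameter).

## Worked example

```r
library(dscperf)

# a symmetric 32x32x10 phantom at baseline SNR 50, bolus at 15 s
ses  <- simulate_phantom_session(phantom_spec(seed = 17))
conc <- signal_to_concentration(ses$series, estimate_baseline(ses$series))
aif  <- select_aif_voxels(conc, compute_curve_features(conc))
maps <- compute_maps(conc, aif)                    # circulant SVD, trunc 0.03
m    <- regional_means(maps, ses$atlas)
relative_parameters(m, surgical_side = "left")
```

```
     territory relative_cbf relative_cbv relative_mtt
1 ACA-terminal     1.002031    0.9958440    0.9939774
2  ACA-central     1.002329    0.9995555    0.9972890
3  MCA-central     1.010086    1.0001101    0.9902694
4 MCA-terminal     1.000713    0.9994690    0.9964199
5 PCA-terminal     1.010286    0.9989389    0.9892813
```

The phantom is hemispherically symmetric, so every relative value sits
within about 1% of 1.0 — the residual scatter is acquisition noise, and
the systematic deconvolution bias cancels between hemispheres. The same
objects feed the cohort layer: `simulate_cohort()` builds paired pre/intra
sessions for 5 CHS subjects (+14.3% surgical-side MCA-terminal CBF
intra-operatively) and 9 controls, and `run_cohort()` emits the three
relative-CBF/CBV/MTT comparison tables with BH-corrected p-values.

The numbered scripts under `analysis/` replay the whole study: phantom
construction, single-session mapping, cohort tables, and the method
validation experiments (parameter recovery, noise robustness, delay
sensitivity, statistical power and calibration), writing their outputs
under `results/`.

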