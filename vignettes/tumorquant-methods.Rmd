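---
title: "Quantitative tumor imaging with tumorquant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative tumor imaging with tumorquant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tumorquant` implements the quantitative arm of a preclinical multimodal
imaging study of tumor xenografts: voxelwise pharmacokinetic mapping of
dynamic contrast-enhanced MRI (DCE-MRI), flip-angle-corrected variable
flip angle (VFA) T1 mapping, erosion-shell segmentation of the tumor into
periphery and core, whole-section immunofluorescence physiology metrics,
PET activity-per-volume quantification, caliper tumor volumes, and the
group statistics (mean ± SE, one-way ANOVA, Newman–Keuls) used to compare
treatment arms. Because studies of this kind rarely deposit raw images,
the package ships a synthetic-phantom generator that produces every
pipeline input with known ground truth; all correctness claims are
closure properties (simulate forward, invert, compare) rather than
comparisons against any external dataset.

# Signal models

## SPGR and variable flip angle T1 mapping

All MR scans are modelled as spoiled gradient-echo (SPGR) acquisitions:

$$S = M_0 \sin\alpha \,\frac{1 - E_1}{1 - E_1 \cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

`fitT1Vfa()` estimates $(T_1, M_0)$ per voxel from three scans at nominal
angles 10°, 20°, 50° (TR = 144 ms) via the standard linearisation
$S/\sin\alpha = E_1 (S/\tan\alpha) + M_0(1-E_1)$, so the regression slope
is $E_1$. The linearised solution is closed-form, exactly invertible on
noiseless input (the suite checks $T_1 \in [200, 4000]$ ms to relative
error below $10^{-8}$), and deliberately not followed by a nonlinear
refinement: the refinement would change nothing on noiseless data and
obscures the failure modes we flag. Voxels whose slope leaves $(0,1)$ —
non-enhancing air, pure noise, or $TR \gg T_1$ — are flagged `fitOk =
FALSE` with `NA` parameters; flagged voxels are excluded from every
downstream computation rather than silently propagated.

## Transmit-field (flip-angle) correction

Surface-coil transmission makes the actual flip angle a voxelwise
multiple $\kappa$ of the nominal one. Three long-TR scans at nominal
145°, 180°, 215° bracket the signal null at 180°; `fitFlipAngleMap()`
fits $S(\alpha_{nom}) = A\,|\sin(\kappa\,\alpha_{nom})|$ per voxel. For
fixed $\kappa$ the amplitude is closed-form, so the fit is a 1D search in
$\kappa$ (coarse 0.01 grid over [0.5, 1.5], then local refinement to
tolerance $10^{-10}$). The long-TR (460 ms) calibration scans are treated
as purely $|\sin|$-weighted, ignoring their residual T1 weighting; this
is the usual double-angle-family approximation, and its residual bias is
second-order at TR comparable to or above T1. Voxels with degenerate
signals or a minimiser on the search boundary fall back to $\kappa = 1$
(uncorrected) and are flagged. The fitted $\kappa$ map corrects both the
VFA T1 fit and the dynamic-series inversion.

## Concentration and the extended Kety model

Contrast-agent concentration is assumed to act linearly on the
relaxation rate, $R_1(t) = R_{1,0} + r_1 C(t)$. `signalToConcentration()`
fixes the voxel's equilibrium scale from the mean of the 20 pre-contrast
frames and the native $T_1$, inverts the SPGR equation per frame for
$E_1(t)$, and converts to concentration. Frames whose inversion leaves
the valid domain ($E_1 \notin (0,1)$) are marked invalid. The relaxivity
default is $r_1 = 3.9\,\mathrm{s^{-1}mM^{-1}}$ (a gadodiamide-at-7T
literature value); it is a pure scale factor on concentration, is
user-overridable, and cancels exactly in all closure tests.

Tissue kinetics follow the three-parameter extended Kety (extended
Tofts) model,

$$C_t(t) = v_p C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
e^{-(K^{trans}/v_e)(t-\tau)}\,d\tau,$$

driven by a population arterial input function. The study's own
population AIF is not published, so the AIF is an explicit, swappable
bi-exponential $C_p(t) = D(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ whose
defaults are the classic population-average gadolinium clearance
parameters ($a_1 = 3.99$, $a_2 = 4.78$ kg/L, $m_1 = 0.144$,
$m_2 = 0.0111$ min$^{-1}$, $D = 0.3$ mmol/kg). Absolute $K^{trans}$
values therefore depend on the configured AIF; every accuracy statement
in the package is a forward/inverse closure under the *same* AIF and so
is AIF-independent. Because $C_p$ is a sum of exponentials, the
convolution is evaluated in closed form per exponential term (with the
removable singularity at $k_{ep} = m_i$ handled by its limit), not by
Riemann summation; the suite verifies agreement with a dt = 0.01 s
trapezoid quadrature to better than $10^{-4}$ mM.

One property worth stating precisely: $C_t$ is monotone in $v_p$, and
monotone in $K^{trans}$ *at fixed* $k_{ep}$, but it is **not** globally
monotone in $K^{trans}$ at fixed $v_e$ — raising $K^{trans}$ raises
$k_{ep} = K^{trans}/v_e$ and accelerates late washout, so late-time
concentrations can decrease. The tests assert the monotonicity
statements that are actually true of the model.

## Voxelwise fitting

`fitKetyVoxelwise()` runs bounded nonlinear least squares per voxel
(L-BFGS-B with analytic gradients) with bounds $K^{trans} \in [0,
5]$ min$^{-1}$, $v_e \in [10^{-3}, 1]$, $v_p \in [0, 1]$ and the joint
constraint $v_e + v_p \le 1$ via a smooth penalty. A 4 × 2 grid of
$(K^{trans}, v_e)$ starts with $v_p = 0.02$ is scored first and the three
best starts are optimised fully; the multi-start guards against the
shallow local minima that washout/uptake trade-offs create. Voxels that
fail to converge or end at a $K^{trans}$/$v_e$ bound are flagged; a $v_p$
estimate of exactly 0 is *not* flagged, because vanishing plasma volume
is a legitimate physiological value. At the study's 15.6 s frame
interval, $v_p$ is the weakest-identified parameter (the bolus peak is
under-sampled); the suite documents this by checking that its
Monte-Carlo error exceeds that of $K^{trans}$.

The per-tumor summary is the **median $K^{trans}$ over viable tissue**:
voxels inside the mask that are fit-OK *and* enhancing. "Enhancing" means
peak concentration above 3× the pre-contrast concentration SD (the
factor is configurable), plus a tiny absolute floor so exactly-flat
curves never qualify; this reproduces the exclusion of unmapped,
non-enhancing regions from per-tumor medians.

# Periphery versus core: erosion shells

`erodeShells()` segments the 3D tumor mask into single-voxel-thick
concentric shells by iterated binary erosion: shell $k$ is the voxel set
removed at erosion step $k$. The structuring element defaults to
6-connectivity (face neighbours); 18 and 26 are available. With the
6-connected element, the shell index equals the city-block distance to
the mask complement, which the tests verify against an independent
lattice-distance computation. Erosion is lattice-based and ignores voxel
anisotropy (0.3 × 0.3 × 1 mm in the target protocol) — shells are "one
voxel thick", not "one millimetre thick"; this matches the cited
morphological practice and is listed as a limitation.

`peripheryCoreSplit()` accumulates shells outermost-first until the
cumulative count first reaches one third of the in-mask voxels
(periphery = outer one-third of voxels, core = the rest) and averages
$K^{trans}$ over fit-OK voxels of each set. The split is resolved at
whole-shell granularity: shells are the natural unit of the
segmentation, and fractional-shell splitting would manufacture precision
the method does not have. Ties at exactly $N/3$ go to the periphery
(the `>=` in the rule).

# Whole-section immunofluorescence metrics

A `SectionImageSet` holds co-registered channels (perfusion dye,
CD31/endothelium, EF5/hypoxia, Ki67/proliferation, TUNEL/apoptosis,
nuclear counterstain) with tumor-boundary, necrosis and artifact masks;
necrosis is an *input* mask, drawn against H&E in practice — automating
it is out of scope. The five metrics:

* `positiveFraction()`: percent of viable pixels (tumor − necrosis −
  artifact) at or above a per-channel threshold. Thresholds are fixed
  numbers in the configuration for determinism, with Otsu-within-viable
  as the automatic alternative.
* `perfusedVesselFraction()`: CD31⁺Hoechst⁺ pixels over CD31⁺ pixels. No
  vessel pixels is an *undefined result* (a classed R condition), never
  0 — the distinction matters in small necrotic sections.
* `meanVesselDistance()`: the exact Euclidean distance transform of the
  vessel set (`EBImage::distmap`), averaged over viable pixels and
  scaled to microns; short distances mean high microvessel density.
  Whether necrotic pixels should be included in the average is
  ambiguous in the field; the default averages viable pixels only, with
  an `includeNecrosis` switch.
* `necroticFraction()`: necrotic over total tumor pixels.
* `alignChannels()`: integer-pixel translation maximising normalised
  cross-correlation within a bounded window, applied before
  quantification. Re-imaging drift of the same physical section is
  translational, so rotation/scaling are out of scope. A shift is only
  applied when the correlation peak is distinct (best ≥ 0.2 and ≥ 1.05×
  the second peak outside the best peak's 3 × 3 neighbourhood);
  otherwise the channel stays put with a warning.

# PET and caliper volumes

`avidRoi()` is the reproducible surrogate for manual ROI placement:
voxels above a configurable fraction (default 0.4) of the maximum
activity, reduced to the largest 6-connected component.
`activityPerVolume()` divides total ROI activity by ROI physical volume.
No decay or partial-volume correction is applied; the scan delay is
provenance only. `caliperVolume()` is the prolate-ellipsoid formula
$\pi/6\,a b^2$ with $a \ge b$ enforced.

# Statistics

`summarizeGroups()` reports mean ± SE. `oneWayAnova()` is the standard
equal-variance F test (delegated to `stats::oneway.test`; the suite
checks it against first-principles sums of squares to $10^{-10}$).
`newmanKeuls()` implements the stepwise studentized-range procedure:
means sorted, spans of $r$ means tested against $q(\alpha, r, df)$ with
SE $\sqrt{MSE/\tilde n}$ ($\tilde n$ = harmonic mean group size for
unequal groups), widest spans first, with the containment rule — pairs
nested in a non-significant span are never declared significant.
Range-distribution quantiles come from R's `ptukey`/`qtukey` (numerical
integration of the range distribution), avoiding table lookups. Under a
complete null with three groups, the procedure's family-wise error is
the single widest-span test's level, and the Monte-Carlo suite confirms
a rate statistically consistent with α = 0.05. As in common practice for
this design, no additional multiplicity correction is applied across
metrics or time points.

`runCohortReport()` applies this machinery per stratum (metric × tumor
line × day) and emits summaries, ANOVA, all pairwise decisions, and
convenience flags versus the control and comparator arms.

# The synthetic-data generator

`makeDcePhantom()` builds an ellipsoidal tumor (semi-axes 40% of the
grid) with an enhancing rim: the outer `rimFraction` of the normalised
radius carries `ktransRim`, the interior `ktransCore`. The default
`rimFraction = 0.15` makes the rim occupy roughly the outer third of
tumor *voxels*, aligning the painted contrast with what the shell split
measures. The phantom generates signals through exactly the forward
chain the fitters invert — extended Kety concentration, linear
$R_1$–concentration coupling, SPGR signal at $\kappa$-scaled angles, VFA
scans at the same ground truth, and $|\sin|$-model calibration scans —
so at `noiseSd = 0` the whole pipeline is an identity up to optimiser
tolerance, and the suite demands voxelwise recovery within 0.1%. Noise
is additive Gaussian on the magnitude signal; Rician noise (the correct
low-SNR magnitude model) is a noted extension, adequate here because
recovery tests run at moderate-to-high SNR. The acquisition defaults are
the study protocol constants (calibration 145/180/215° at TE/TR
3.5/460 ms; VFA 10/20/50° at 2.7/144 ms; dynamic 25° at 2.7/9 ms, 15.6 s
per frame, 20 + 150 frames); scan noise levels are not reported in such
protocols, so the phantom SNR is a free configuration choice.

`makeSectionPhantom()` paints channels so every metric recovers ground
truth exactly up to one-pixel count rounding: necrosis as the first
$\lfloor f \cdot n \rceil$ tumor pixels in raster order, vessels as
distinct random viable pixels with an exact perfused subset, Ki67/TUNEL
as exact painted counts, and EF5 positive exactly where the distance to
the nearest *perfused* vessel exceeds `hypoxiaDistanceUm` — coupling the
hypoxia readout to vascular geometry the way the biology couples them.
Painted positives are 200 on a background of 10, so the default fixed
threshold 100 separates them with no ambiguity. What the phantom does
*not* emulate: stain texture, autofluorescence, uneven illumination,
cell-scale structure, or imperfect manual masks — passing tests show the
*metrics* are computed correctly, not that thresholding real stains is
trivial.

`makeGroupCohort()` draws per-tumor metrics from log-normal
distributions with per-arm multiplicative effects (log-normal because
volumes and rates are positive and right-skewed). The default effect
pattern mirrors the study design being emulated: a metronomic arm with
10-fold smaller volumes, 2-fold elevated $K^{trans}$ and reduced
hypoxia, an anti-angiogenic arm with reduced vessel density but
unchanged volume and $K^{trans}$, and n = 8 per arm with log-scale SD
0.25 (a moderate ~25% coefficient of variation typical of xenograft
cohorts).

# Numerical choices and problem sizes

* Flip-angle search interval [0.5, 1.5], grid step 0.01, refinement
  tolerance $10^{-10}$; boundary minimisers are treated as failures.
* Kety fit: L-BFGS-B `factr = 1e3`, `pgtol = 1e-12`, 500 iterations,
  penalty weight $10^3$ on $\max(0, v_e + v_p - 1)^2$.
* Convolution singularity switch at $|k_{ep} - m_i| < 10^{-9}
  \max(k_{ep}, m_i, 1)$.
* The test suite and acceptance script size their simulations to run on
  one CPU in a few minutes: 500-voxel recovery studies, 32 × 32 × 16
  default phantom grids, 16³ shell-oracle masks, 64–200 px section
  phantoms, 1000–2000 Monte-Carlo statistics replicates. These sizes are
  the package's own verification design; the methods scale linearly in
  voxel count.

# Known limitations

* The AIF is a configured population model; absolute $K^{trans}$ values
  are only comparable across analyses sharing an AIF.
* Additive Gaussian (not Rician) noise in the phantom.
* Lattice-based shells ignore voxel anisotropy.
* Histology alignment is translation-only; pixels assumed square and
  isotropic.
* Necrosis segmentation and PET ROI placement are reproducible
  surrogates (input masks, threshold components) for manual steps.
* No model selection across kinetic models (Patlak, two-compartment
  exchange) and no individually measured AIFs.
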