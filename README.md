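# tumorquant

Quantitative multimodal imaging analysis for preclinical tumor xenograft
studies, written for imaging scientists and analysts who need the full
measurement chain — not just the model fit — to be reproducible and
testable.

Anti-angiogenic and metronomic-chemotherapy experiments are read out
with a combination of DCE-MRI pharmacokinetics, FDG-PET uptake,
whole-section immunofluorescence, caliper volumes and multi-arm group
statistics. `tumorquant` implements that entire readout as one audited
pipeline:

* **DCE-MRI pharmacokinetic mapping.** Per-voxel fitting of the extended
  Kety (Tofts) model
  `C_t(t) = v_p C_p(t) + Ktrans ∫ C_p(τ) exp(-(Ktrans/v_e)(t-τ)) dτ`
  against a configurable bi-exponential population AIF, with the
  convolution evaluated in closed form. Native T1 comes from a
  three-scan variable-flip-angle (VFA) SPGR fit, corrected per voxel by
  a transmit-field (flip-angle) map estimated from three long-TR scans
  bracketing the 180° signal null. Per-tumor summary: median Ktrans over
  viable (fit-OK, enhancing) tissue.
* **Periphery vs core.** Erosion-based concentric single-voxel shells of
  the tumor mask; mean Ktrans over the outer one-third of voxels
  (periphery) versus the inner two-thirds (core).
* **Histology metrics.** EF5+/Ki67+/TUNEL+ pixel fractions of viable
  tissue, perfused-vessel fraction (CD31+Hoechst+/CD31+), mean
  distance-to-nearest-vessel (exact Euclidean distance transform), and
  necrotic fraction, with channel alignment and necrosis/artifact
  exclusion.
* **PET.** Activity per unit tumor volume in a threshold-defined avid
  ROI; caliper volumes `π/6·a·b²`.
* **Statistics.** Mean ± SE, one-way ANOVA, and Newman–Keuls stepwise
  studentized-range post-hoc comparisons with the containment rule.
* **Synthetic phantoms.** Every input can be simulated with known ground
  truth (`makeDcePhantom`, `makeSectionPhantom`, `makeGroupCohort`), so
  the whole chain is verified by forward/inverse closure.

## Worked example

Simulate a small noisy DCE phantom (ellipsoidal tumor, enhancing rim
Ktrans = 0.3/min, core 0.1/min, transmit scale κ = 0.9), run the mapping
chain, and contrast periphery with core:

```r
library(tumorquant)

spec <- phantomSpec(gridShape = c(16, 16, 10), noiseSd = 2)
ph   <- makeDcePhantom(spec)
acq  <- acquisitionParams()

fa   <- fitFlipAngleMap(ph$cal, acq, ph$mask)
t1   <- fitT1Vfa(ph$vfa, fa, acq, ph$mask)
conc <- signalToConcentration(ph$dyn, t1, fa, mask = ph$mask)
pk   <- fitKetyVoxelwise(conc, ph$aif, ph$mask)
pk
#> PKParameterMap: 16 x 16 x 10 voxels; 680 fit OK
#>   median Ktrans (fit OK): 0.1054 /min; median ve: 0.300; median vp: 0.0494

medianKtransViable(pk, ph$mask)
#> [1] 0.1054     # /min — the core dominates the voxel count

split <- peripheryCoreSplit(erodeShells(ph$mask), pk)
c(split$peripheryKtrans, split$coreKtrans)
#> [1] 0.2863 0.1040   # enhancing rim vs poorly perfused core
```

The fitted flip-angle map recovers the simulated miscalibration (median
κ 0.9000) and the T1 map the simulated native T1 (median 1797 ms against
a ground truth of 1800 ms at this noise level). Section phantoms behave
the same way — painted ground truth comes back from the metric code:

```r
sec <- makeSectionPhantom(sectionPhantomSpec())
computeSectionMetrics(sec$set)
#>   ef5Fraction ki67Fraction tunelFraction perfusedVesselFraction
#> 1    10.58642           30             5                     70
#>   meanVesselDistanceUm necroticFraction
#> 1             17.96335               20
```

`runFullPipeline(defaultPipelineConfig(), "out/")` runs every stage end
to end and writes NIfTI maps, CSV tables and a provenance JSON. A thin
command-line front end lives in `inst/scripts/tumorquant.R`
(`run` / `simulate` / `report` subcommands).

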