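#' @import methods
NULL

#' Acquisition parameters for the DCE-MRI protocol
#'
#' Holds the spoiled-gradient-echo acquisition constants of the three scan
#' types used by the pipeline: the long-TR flip-angle calibration scans, the
#' three-scan variable-flip-angle (VFA) series for native T1, and the dynamic
#' T1-weighted series. Defaults correspond to a 7 T small-animal protocol:
#' calibration TE/TR = 3.5/460 ms at nominal angles 145/180/215 degrees,
#' VFA TE/TR = 2.7/144 ms at 10/20/50 degrees, and a dynamic series at
#' TE/TR = 2.7/9 ms, 25 degrees, 15.6 s per frame with 20 pre-contrast and
#' 150 post-contrast frames.
#'
#' @slot trCal,trVfa,trDyn repetition times in ms
#' @slot teCal,teVfa,teDyn echo times in ms (provenance; the signal model is
#'   TE-independent after normalisation)
#' @slot flipCal nominal calibration flip angles in degrees (length 3)
#' @slot flipVfa nominal VFA flip angles in degrees (length 3)
#' @slot flipDyn nominal dynamic flip angle in degrees
#' @slot frameInterval seconds per dynamic frame
#' @slot nPre,nPost pre- and post-contrast dynamic frame counts
#' @export
setClass("AcquisitionParams",
  representation(
    trCal = "numeric", trVfa = "numeric", trDyn = "numeric",
    teCal = "numeric", teVfa = "numeric", teDyn = "numeric",
    flipCal = "numeric", flipVfa = "numeric", flipDyn = "numeric",
    frameInterval = "numeric", nPre = "integer", nPost = "integer"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  tims <- c(object@trCal, object@trVfa, object@trDyn,
            object@flipCal, object@flipVfa, object@flipDyn,
            object@frameInterval)
  if (any(!is.finite(tims)) || any(tims <= 0))
    msg <- c(msg, "all repetition times, flip angles and the frame interval must be strictly positive")
  if (object@nPre < 2L)
    msg <- c(msg, "nPre must be >= 2 (baseline averaging needs multiple pre-contrast frames)")
  if (object@nPost < 1L)
    msg <- c(msg, "nPost must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Bi-exponential population arterial input function
#'
#' Plasma contrast-agent concentration model
#' \eqn{C_p(t) = D (a_1 e^{-m_1 t} + a_2 e^{-m_2 t})} for \eqn{t \ge} onset
#' and 0 before, with \eqn{t} in minutes past bolus arrival. \eqn{D} is the
#' injected dose in mmol/kg; the amplitudes are in mM per unit dose so that
#' \eqn{C_p} is in mM. The default decay parameters are the classic
#' population-average bi-exponential clearance values; the dose default is
#' 0.3 mmol/kg gadodiamide.
#'
#' @slot dose injected dose (mmol/kg)
#' @slot a1,a2 amplitudes (mM per unit dose)
#' @slot m1,m2 decay rates (per minute)
#' @slot onsetTime bolus arrival time (seconds from acquisition start)
#' @export
setClass("AIFModel",
  representation(dose = "numeric", a1 = "numeric", a2 = "numeric",
                 m1 = "numeric", m2 = "numeric", onsetTime = "numeric")
)

setValidity("AIFModel", function(object) {
  msg <- character()
  if (object@a1 < 0 || object@a2 < 0) msg <- c(msg, "amplitudes must be >= 0")
  if (object@m1 <= 0 || object@m2 <= 0) msg <- c(msg, "decay rates must be > 0")
  if (object@dose <= 0) msg <- c(msg, "dose must be > 0")
  if (object@onsetTime < 0) msg <- c(msg, "onsetTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' 4D dynamic contrast-enhanced signal series
#'
#' @slot signal 4D array (x, y, z, frame), arbitrary scanner units
#' @slot frameTimes frame start times in seconds, strictly increasing
#' @slot acq the [AcquisitionParams-class] the series was acquired with
#' @export
setClass("DynamicSeries",
  representation(signal = "array", frameTimes = "numeric",
                 acq = "AcquisitionParams")
)

setValidity("DynamicSeries", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4L) msg <- c(msg, "signal must be a 4D array (x, y, z, frame)")
  else {
    if (d[4] != length(object@frameTimes))
      msg <- c(msg, "frame count must equal length(frameTimes)")
    if (d[4] != object@acq@nPre + object@acq@nPost)
      msg <- c(msg, "frame count must equal nPre + nPost")
  }
  if (any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' A stack of 3D scans acquired at several nominal flip angles
#'
#' Container shared by the flip-angle calibration scans (long TR, angles
#' bracketing the 180-degree signal null) and the variable-flip-angle T1
#' series (short TR, low angles).
#'
#' @slot signal 4D array (x, y, z, angle)
#' @slot nominalFlip nominal flip angles in degrees, one per 4th-dim slab
#' @slot tr repetition time in ms
#' @export
setClass("MultiFlipScans",
  representation(signal = "array", nominalFlip = "numeric", tr = "numeric")
)

setValidity("MultiFlipScans", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4L) msg <- c(msg, "signal must be a 4D array (x, y, z, angle)")
  else if (d[4] != length(object@nominalFlip))
    msg <- c(msg, "4th dimension must match number of nominal flip angles")
  if (any(object@nominalFlip <= 0)) msg <- c(msg, "flip angles must be positive")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-voxel actual/nominal flip-angle scale map
#'
#' kappa is the multiplicative transmit-field scale such that the actual
#' flip angle is kappa times the nominal angle. Voxels whose calibration fit
#' failed carry kappa = 1 (graceful degradation to the uncorrected fit) and
#' fitOk = FALSE.
#'
#' @slot kappa 3D numeric array
#' @slot fitOk 3D logical array
#' @export
setClass("FlipAngleMap",
  representation(kappa = "array", fitOk = "array")
)

setValidity("FlipAngleMap", function(object) {
  msg <- character()
  if (!identical(dim(object@kappa), dim(object@fitOk)))
    msg <- c(msg, "kappa and fitOk must share one shape")
  ok <- object@fitOk
  if (any(ok) && (any(!is.finite(object@kappa[ok])) || any(object@kappa[ok] <= 0)))
    msg <- c(msg, "kappa must be finite and > 0 wherever fitOk")
  if (length(msg)) msg else TRUE
})

#' Per-voxel native T1 map from the variable-flip-angle fit
#'
#' @slot t1 native longitudinal relaxation time, ms
#' @slot m0 equilibrium-signal scale, arbitrary units
#' @slot fitOk logical validity flag; voxels with a regression slope outside
#'   (0, 1) or non-finite inputs are flagged FALSE and must not be used
#' @export
setClass("T1Map",
  representation(t1 = "array", m0 = "array", fitOk = "array")
)

setValidity("T1Map", function(object) {
  msg <- character()
  if (!identical(dim(object@t1), dim(object@m0)) ||
      !identical(dim(object@t1), dim(object@fitOk)))
    msg <- c(msg, "t1, m0 and fitOk must share one shape")
  ok <- object@fitOk
  if (any(ok)) {
    if (any(!is.finite(object@t1[ok])) || any(object@t1[ok] <= 0))
      msg <- c(msg, "t1 must be finite and > 0 wherever fitOk")
    if (any(object@m0[ok] < 0))
      msg <- c(msg, "m0 must be >= 0 wherever fitOk")
  }
  if (length(msg)) msg else TRUE
})

#' Contrast-agent concentration time series
#'
#' @slot conc 4D array (x, y, z, frame), mM
#' @slot valid 4D logical array; FALSE where the SPGR inversion left its
#'   valid domain or the voxel's T1 fit failed
#' @slot baselineR1 3D array of native relaxation rates, 1/s
#' @slot relaxivity contrast-agent longitudinal relaxivity r1, 1/s/mM
#' @slot frameTimes seconds
#' @slot acq acquisition constants
#' @export
setClass("ConcentrationSeries",
  representation(conc = "array", valid = "array", baselineR1 = "array",
                 relaxivity = "numeric", frameTimes = "numeric",
                 acq = "AcquisitionParams")
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  if (!identical(dim(object@conc), dim(object@valid)))
    msg <- c(msg, "conc and valid must share one shape")
  if (length(dim(object@conc)) != 4L)
    msg <- c(msg, "conc must be 4D")
  if (object@relaxivity <= 0) msg <- c(msg, "relaxivity must be > 0")
  if (any(!is.finite(object@conc[object@valid])))
    msg <- c(msg, "conc must be finite wherever valid")
  if (length(msg)) msg else TRUE
})

#' Per-voxel extended Kety parameter map
#'
#' Voxelwise estimates of the three extended Kety (Tofts) parameters:
#' Ktrans (volume transfer constant, per minute), ve (fractional
#' extravascular-extracellular volume) and vp (fractional plasma volume),
#' with the residual sum of squares of each fit, a validity flag, and an
#' enhancement flag used by the viable-tissue median.
#'
#' @slot ktrans 3D array, per minute
#' @slot ve,vp 3D arrays, dimensionless fractions
#' @slot rss 3D array, residual sum of squares (mM^2)
#' @slot fitOk 3D logical; FALSE where the fit failed to converge or stuck
#'   at a ktrans/ve bound
#' @slot enhancing 3D logical; TRUE where peak concentration exceeded the
#'   enhancement threshold over the pre-contrast noise
#' @export
setClass("PKParameterMap",
  representation(ktrans = "array", ve = "array", vp = "array",
                 rss = "array", fitOk = "array", enhancing = "array")
)

setValidity("PKParameterMap", function(object) {
  msg <- character()
  dims <- list(dim(object@ktrans), dim(object@ve), dim(object@vp),
               dim(object@rss), dim(object@fitOk), dim(object@enhancing))
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    msg <- c(msg, "all parameter arrays must share one shape")
  ok <- object@fitOk
  if (any(ok)) {
    if (any(object@ktrans[ok] < 0)) msg <- c(msg, "ktrans must be >= 0 where fitOk")
    if (any(object@ve[ok] <= 0 | object@ve[ok] > 1))
      msg <- c(msg, "ve must be in (0, 1] where fitOk")
    if (any(object@vp[ok] < 0 | object@vp[ok] > 1))
      msg <- c(msg, "vp must be in [0, 1] where fitOk")
    if (any(object@ve[ok] + object@vp[ok] > 1 + 1e-8))
      msg <- c(msg, "ve + vp must be <= 1 where fitOk")
  }
  if (length(msg)) msg else TRUE
})

#' Concentric single-voxel-thick shell labelling of a tumor mask
#'
#' shellIndex is 0 outside the mask; inside, shell 1 is the outermost layer
#' (voxels removed by the first binary erosion), shell 2 the next, and so on
#' inward. The union of the shells is exactly the mask.
#'
#' @slot shellIndex 3D integer array
#' @slot nShells total number of shells
#' @slot connectivity structuring-element connectivity used (6, 18 or 26)
#' @export
setClass("ShellLabeling",
  representation(shellIndex = "array", nShells = "integer",
                 connectivity = "integer")
)

setValidity("ShellLabeling", function(object) {
  msg <- character()
  si <- object@shellIndex
  if (any(si < 0L)) msg <- c(msg, "shellIndex must be >= 0")
  if (length(object@nShells) != 1L || object@nShells < 1L)
    msg <- c(msg, "nShells must be a single positive integer")
  else if (max(si) != object@nShells)
    msg <- c(msg, "max shellIndex must equal nShells")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (length(msg)) msg else TRUE
})

#' Co-registered multi-channel immunofluorescence section
#'
#' One whole tumor cryosection: named 2D intensity channels imaged
#' separately on the same section (perfusion dye, endothelial marker,
#' hypoxia marker, proliferation marker, apoptosis marker, nuclear
#' counterstain), plus the manually drawn tumor-boundary, necrosis and
#' artifact masks.
#'
#' @slot channels named list of numeric matrices, all one shape; canonical
#'   names: hoechst_perfusion, cd31, ef5, ki67, tunel, counterstain
#' @slot pixelSizeUm microns per pixel (square pixels)
#' @slot tumorMask,necrosisMask,artifactMask logical matrices; necrosis is a
#'   subset of the tumor mask
#' @export
setClass("SectionImageSet",
  representation(channels = "list", pixelSizeUm = "numeric",
                 tumorMask = "matrix", necrosisMask = "matrix",
                 artifactMask = "matrix")
)

setValidity("SectionImageSet", function(object) {
  msg <- character()
  if (length(object@channels) < 1L || is.null(names(object@channels)))
    msg <- c(msg, "channels must be a non-empty named list")
  shp <- dim(object@tumorMask)
  shapesOk <- all(vapply(object@channels,
                         function(ch) identical(dim(ch), shp), logical(1)))
  if (!shapesOk || !identical(dim(object@necrosisMask), shp) ||
      !identical(dim(object@artifactMask), shp))
    msg <- c(msg, "all channels and masks must share one shape")
  else if (any(object@necrosisMask & !object@tumorMask))
    msg <- c(msg, "necrosisMask must be a subset of tumorMask")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Reconstructed PET volume
#'
#' @slot activity 3D array, activity units per voxel, non-negative
#' @slot voxelVolumeMm3 voxel volume in mm^3
#' @slot injectedDose injected tracer dose (provenance)
#' @slot scanDelayMin minutes between injection and scan (provenance only;
#'   no decay correction is applied)
#' @export
setClass("PETVolume",
  representation(activity = "array", voxelVolumeMm3 = "numeric",
                 injectedDose = "numeric", scanDelayMin = "numeric")
)

setValidity("PETVolume", function(object) {
  msg <- character()
  if (length(dim(object@activity)) != 3L)
    msg <- c(msg, "activity must be a 3D array")
  if (any(object@activity < 0)) msg <- c(msg, "activity must be >= 0")
  if (object@voxelVolumeMm3 <= 0) msg <- c(msg, "voxelVolumeMm3 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a DCE-MRI digital phantom
#'
#' Describes an ellipsoidal tumor with an enhancing rim (outer shell of
#' elevated Ktrans) and a core, plus the ground-truth tissue and transmit
#' parameters from which the full forward signal chain is generated.
#'
#' @slot gridShape voxel counts per axis (length 3)
#' @slot voxelSize mm per axis (length 3)
#' @slot rimFraction fraction of the tumor radius forming the rim
#' @slot ktransRim,ktransCore transfer constants, per minute
#' @slot ve,vp fractional volumes in (0, 1] and [0, 1)
#' @slot t1Ms ground-truth native T1, ms
#' @slot kappaTrue ground-truth transmit scale (actual/nominal flip angle)
#' @slot m0Scale equilibrium signal amplitude, arbitrary units
#' @slot noiseSd Gaussian noise SD on the magnitude signal, same units as m0Scale
#' @slot seed RNG seed
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 rimFraction = "numeric", ktransRim = "numeric",
                 ktransCore = "numeric", ve = "numeric", vp = "numeric",
                 t1Ms = "numeric", kappaTrue = "numeric", m0Scale = "numeric",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape <= 0L))
    msg <- c(msg, "gridShape must be three strictly positive counts")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths")
  if (object@rimFraction < 0 || object@rimFraction > 1)
    msg <- c(msg, "rimFraction must be in [0, 1]")
  if (object@ktransRim < 0 || object@ktransCore < 0)
    msg <- c(msg, "ktrans values must be >= 0")
  if (object@ve <= 0 || object@ve > 1) msg <- c(msg, "ve must be in (0, 1]")
  if (object@vp < 0 || object@vp > 1) msg <- c(msg, "vp must be in [0, 1]")
  if (object@ve + object@vp > 1) msg <- c(msg, "ve + vp must be <= 1")
  if (object@t1Ms <= 0) msg <- c(msg, "t1Ms must be > 0")
  if (object@kappaTrue <= 0) msg <- c(msg, "kappaTrue must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of an immunofluorescence section phantom
#'
#' @slot imageShape pixel counts (rows, cols)
#' @slot nVessels number of vessel objects
#' @slot perfusedFractionTrue fraction of vessels carrying perfusion dye
#' @slot hypoxiaDistanceUm pixels farther than this from the nearest
#'   perfused vessel are painted hypoxia-marker positive
#' @slot necrosisFractionTrue fraction of tumor area painted necrotic
#' @slot ki67FractionTrue,tunelFractionTrue positive fractions of viable
#'   tissue painted for the proliferation and apoptosis channels
#' @slot pixelSizeUm microns per pixel
#' @slot seed RNG seed
#' @export
setClass("SectionPhantomSpec",
  representation(imageShape = "integer", nVessels = "integer",
                 perfusedFractionTrue = "numeric", hypoxiaDistanceUm = "numeric",
                 necrosisFractionTrue = "numeric", ki67FractionTrue = "numeric",
                 tunelFractionTrue = "numeric", pixelSizeUm = "numeric",
                 seed = "integer")
)

setValidity("SectionPhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape <= 0L))
    msg <- c(msg, "imageShape must be two strictly positive counts")
  if (object@nVessels < 0L) msg <- c(msg, "nVessels must be >= 0")
  fr <- c(object@perfusedFractionTrue, object@necrosisFractionTrue,
          object@ki67FractionTrue, object@tunelFractionTrue)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must be in [0, 1]")
  if (object@hypoxiaDistanceUm <= 0)
    msg <- c(msg, "hypoxiaDistanceUm must be > 0")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})
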