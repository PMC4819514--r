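#' @include AllClasses.R acquisition.R aif.R pk-model.R
NULL

#' Specify a DCE-MRI digital phantom
#'
#' An ellipsoidal tumor (semi-axes 40% of the grid) whose outer
#' `rimFraction` of the normalised radius forms an enhancing rim of
#' elevated Ktrans around a lower-Ktrans core — the rim/core contrast seen
#' in poorly perfused tumors. Default voxel size 0.3 x 0.3 x 1 mm.
#'
#' @param gridShape voxel counts per axis
#' @param voxelSize mm per axis
#' @param rimFraction fraction of the tumor radius forming the rim
#' @param ktransRim,ktransCore per-minute transfer constants
#' @param ve,vp fractional volumes
#' @param t1Ms ground-truth native T1 (ms)
#' @param kappaTrue ground-truth flip-angle scale
#' @param m0Scale equilibrium signal amplitude (arbitrary units)
#' @param noiseSd additive Gaussian noise SD on the magnitude signal
#' @param seed RNG seed
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 16L),
                        voxelSize = c(0.3, 0.3, 1),
                        rimFraction = 0.15,
                        ktransRim = 0.3, ktransCore = 0.1,
                        ve = 0.3, vp = 0.05,
                        t1Ms = 1800, kappaTrue = 0.9, m0Scale = 1000,
                        noiseSd = 0, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, rimFraction = rimFraction,
      ktransRim = ktransRim, ktransCore = ktransCore, ve = ve, vp = vp,
      t1Ms = t1Ms, kappaTrue = kappaTrue, m0Scale = m0Scale,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# normalised ellipsoid radius (1 at the surface) on the phantom grid
ellipsoidRadius <- function(gridShape) {
  ctr <- (gridShape + 1) / 2
  semi <- 0.4 * gridShape
  x <- (seq_len(gridShape[1]) - ctr[1]) / semi[1]
  y <- (seq_len(gridShape[2]) - ctr[2]) / semi[2]
  z <- (seq_len(gridShape[3]) - ctr[3]) / semi[3]
  sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))
}

#' Generate the full DCE-MRI forward chain with known ground truth
#'
#' Builds an ellipsoidal rim/core tumor and generates every input of the T1
#' and pharmacokinetic mapping pipeline by the exact forward chain the
#' fitters invert: tissue concentration from the extended Kety model with
#' the ground-truth parameter map, \eqn{R_1(t) = R_{1,0} + r_1 C(t)},
#' dynamic SPGR signal at the kappa-scaled dynamic flip angle, a
#' three-angle VFA series at the same ground-truth T1 and kappa, and
#' long-TR flip-angle calibration scans modelled as
#' \eqn{A |\sin(\kappa \alpha_{nom})|}. Pre-contrast frames carry zero
#' contrast agent. Gaussian noise of SD `noiseSd` is then added to every
#' signal; with `noiseSd = 0` the chain is exactly invertible.
#'
#' @param spec a [PhantomSpec-class]
#' @param aif an [AIFModel-class]; the default places bolus onset at the
#'   first post-contrast frame
#' @param acq an [AcquisitionParams-class]
#' @param relaxivity contrast-agent r1 relaxivity used in the forward
#'   chain, 1/s/mM
#' @return list with `dyn` ([DynamicSeries-class]), `vfa` and `cal`
#'   ([MultiFlipScans-class]), `truth` ([PKParameterMap-class]), `mask`,
#'   and the ground-truth `t1Map` / `kappaMap` arrays
#' @export
makeDcePhantom <- function(spec, aif = NULL, acq = acquisitionParams(),
                           relaxivity = 3.9) {
  stopifnot(is(spec, "PhantomSpec"), is(acq, "AcquisitionParams"))
  if (is.null(aif))
    aif <- aifModel(onsetTime = acq@nPre * acq@frameInterval)
  gs <- spec@gridShape
  if (any(gs < 3L))
    stop("grid too small for an ellipsoidal tumor phantom (need >= 3 voxels per axis)")
  rho <- ellipsoidRadius(gs)
  mask <- rho <= 1
  rim <- mask & rho > (1 - spec@rimFraction)

  ktrans <- array(0, gs)
  ktrans[mask] <- spec@ktransCore
  ktrans[rim] <- spec@ktransRim
  veA <- array(NA_real_, gs); veA[mask] <- spec@ve
  vpA <- array(NA_real_, gs); vpA[mask] <- spec@vp
  truth <- new("PKParameterMap", ktrans = ktrans, ve = veA, vp = vpA,
               rss = array(0, gs), fitOk = mask,
               enhancing = mask & (ktrans > 0 | spec@vp > 0))

  tt <- frameTimes(acq)
  nFrame <- length(tt)
  ctRim <- ketyForward(spec@ktransRim, spec@ve, spec@vp, aif, tt)
  ctCore <- ketyForward(spec@ktransCore, spec@ve, spec@vp, aif, tt)

  r10 <- 1000 / spec@t1Ms   # 1/s
  aDyn <- spec@kappaTrue * acq@flipDyn
  dynSig <- array(0, c(gs, nFrame))
  coreIdx <- which(mask & !rim); rimIdx <- which(rim)
  for (f in seq_len(nFrame)) {
    vol <- array(0, gs)
    t1Rim <- 1000 / (r10 + relaxivity * ctRim[f])
    t1Core <- 1000 / (r10 + relaxivity * ctCore[f])
    vol[rimIdx] <- spgrSignal(spec@m0Scale, t1Rim, acq@trDyn, aDyn)
    vol[coreIdx] <- spgrSignal(spec@m0Scale, t1Core, acq@trDyn, aDyn)
    dynSig[, , , f] <- vol
  }

  vfaSig <- array(0, c(gs, length(acq@flipVfa)))
  for (j in seq_along(acq@flipVfa)) {
    vol <- array(0, gs)
    vol[mask] <- spgrSignal(spec@m0Scale, spec@t1Ms, acq@trVfa,
                            spec@kappaTrue * acq@flipVfa[j])
    vfaSig[, , , j] <- vol
  }

  calSig <- array(0, c(gs, length(acq@flipCal)))
  for (j in seq_along(acq@flipCal)) {
    vol <- array(0, gs)
    vol[mask] <- spec@m0Scale *
      abs(sin(spec@kappaTrue * acq@flipCal[j] * pi / 180))
    calSig[, , , j] <- vol
  }

  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    dynSig <- dynSig + stats::rnorm(length(dynSig), 0, spec@noiseSd)
    vfaSig <- vfaSig + stats::rnorm(length(vfaSig), 0, spec@noiseSd)
    calSig <- calSig + stats::rnorm(length(calSig), 0, spec@noiseSd)
  }

  t1Map <- array(NA_real_, gs); t1Map[mask] <- spec@t1Ms
  kappaMapA <- array(NA_real_, gs); kappaMapA[mask] <- spec@kappaTrue

  list(dyn = new("DynamicSeries", signal = dynSig, frameTimes = tt,
                 acq = acq),
       vfa = new("MultiFlipScans", signal = vfaSig,
                 nominalFlip = acq@flipVfa, tr = acq@trVfa),
       cal = new("MultiFlipScans", signal = calSig,
                 nominalFlip = acq@flipCal, tr = acq@trCal),
       truth = truth, mask = mask, t1Map = t1Map, kappaMap = kappaMapA,
       aif = aif, relaxivity = relaxivity)
}
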