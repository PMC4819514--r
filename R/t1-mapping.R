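#' Fit a per-voxel flip-angle (transmit) scale map
#'
#' Estimates the multiplicative flip-angle scale kappa in each masked voxel
#' from three long-TR scans acquired at nominal angles bracketing the
#' 180-degree signal null. The measured signals are modelled as
#' \eqn{S(\alpha_{nom}) = A\,|\sin(\kappa\,\alpha_{nom})|} and
#' \eqn{(A, \kappa)} solved by least squares: for fixed kappa the amplitude
#' has the closed form \eqn{A = \sum S_i g_i / \sum g_i^2}
#' (\eqn{g_i = |\sin(\kappa\alpha_i)|}), so the fit is a 1D minimisation
#' over kappa, done on a coarse grid followed by local refinement. The
#' long-TR acquisition is treated as T1-insensitive; residual T1 weighting
#' is a second-order effect at TR much larger than the dynamic TR.
#'
#' Voxels with all-zero or non-finite signals, or whose minimiser lands on
#' the search boundary, are flagged and assigned kappa = 1 so downstream
#' fits degrade gracefully to the uncorrected case.
#'
#' @param calScans a [MultiFlipScans-class] with at least three angles
#' @param acq an [AcquisitionParams-class] (consistency checks)
#' @param mask 3D logical array of voxels to fit
#' @param kappaRange search interval for kappa
#' @return a [FlipAngleMap-class]; kappa = 1 and fitOk = FALSE outside the
#'   mask and wherever the fit failed
#' @export
fitFlipAngleMap <- function(calScans, acq, mask,
                            kappaRange = c(0.5, 1.5)) {
  stopifnot(is(calScans, "MultiFlipScans"))
  angles <- calScans@nominalFlip
  if (length(angles) < 3L)
    stop("flip-angle calibration needs at least three nominal angles")
  d <- dim(calScans@signal)
  if (!identical(d[1:3], dim(mask)))
    stop("mask grid does not match calibration scans")
  alphaRad <- angles * pi / 180

  idx <- which(mask)
  kappa <- array(1, dim = d[1:3])
  ok <- array(FALSE, dim = d[1:3])
  if (length(idx) == 0L)
    return(new("FlipAngleMap", kappa = kappa, fitOk = ok))

  smat <- matrix(0, length(idx), length(angles))
  for (j in seq_along(angles)) {
    vol <- calScans@signal[, , , j]
    smat[, j] <- vol[idx]
  }
  finiteRow <- apply(is.finite(smat), 1L, all)
  nonzeroRow <- rowSums(abs(smat)) > 0
  fitRows <- which(finiteRow & nonzeroRow)

  if (length(fitRows)) {
    sfit <- smat[fitRows, , drop = FALSE]
    # coarse grid: rss(kappa) = sum(S^2) - A^2 * sum(g^2), vectorised over voxels
    grid <- seq(kappaRange[1], kappaRange[2], by = 0.01)
    g <- abs(sin(outer(grid, alphaRad)))          # |grid| x angles
    gg <- rowSums(g * g)
    proj <- sfit %*% t(g)                          # voxels x |grid|
    rssGrid <- rowSums(sfit * sfit) - sweep(proj^2, 2L, gg, "/")
    best <- max.col(-rssGrid, ties.method = "first")

    rssOne <- function(k, s) {
      gi <- abs(sin(k * alphaRad))
      a <- sum(s * gi) / sum(gi * gi)
      sum((s - a * gi)^2)
    }
    step <- 0.01
    kap <- numeric(length(fitRows))
    okRow <- logical(length(fitRows))
    for (r in seq_along(fitRows)) {
      lo <- max(kappaRange[1], grid[best[r]] - step)
      hi <- min(kappaRange[2], grid[best[r]] + step)
      opt <- stats::optimize(rssOne, c(lo, hi), s = sfit[r, ], tol = 1e-10)
      kap[r] <- opt$minimum
      # boundary of the search range means the null was not bracketed
      okRow[r] <- kap[r] > kappaRange[1] + 1e-6 &&
                  kap[r] < kappaRange[2] - 1e-6
    }
    kv <- kappa[idx]; ov <- ok[idx]
    kv[fitRows] <- ifelse(okRow, kap, 1)
    ov[fitRows] <- okRow
    kappa[idx] <- kv; ok[idx] <- ov
  }
  new("FlipAngleMap", kappa = kappa, fitOk = ok)
}

#' Fit native T1 by the linearised variable-flip-angle method
#'
#' Per-voxel (T1, M0) from three SPGR scans at different flip angles,
#' with each nominal angle corrected by the voxel's flip-angle scale
#' (actual angle = kappa x nominal). The SPGR equation is linearised as
#' \deqn{S/\sin\alpha = E_1 \, (S/\tan\alpha) + M_0 (1 - E_1)}
#' so the regression slope is \eqn{E_1 = e^{-TR/T_1}} and
#' \eqn{T_1 = -TR / \log E_1}. Voxels whose slope falls outside (0, 1),
#' or with non-finite inputs, are flagged not-OK (their t1/m0 are NA);
#' they are never silently propagated.
#'
#' @param vfaScans a [MultiFlipScans-class] with the VFA series
#' @param faMap a [FlipAngleMap-class]; pass a unit map to fit uncorrected
#' @param acq an [AcquisitionParams-class]
#' @param mask 3D logical array
#' @return a [T1Map-class]
#' @export
fitT1Vfa <- function(vfaScans, faMap, acq, mask) {
  stopifnot(is(vfaScans, "MultiFlipScans"), is(faMap, "FlipAngleMap"))
  d <- dim(vfaScans@signal)
  if (!identical(d[1:3], dim(mask)) || !identical(d[1:3], dim(faMap@kappa)))
    stop("mask / flip-angle map grid does not match VFA scans")
  angles <- vfaScans@nominalFlip
  if (length(angles) < 2L)
    stop("VFA T1 fit needs at least two flip angles")
  tr <- vfaScans@tr

  idx <- which(mask)
  t1 <- array(NA_real_, d[1:3])
  m0 <- array(NA_real_, d[1:3])
  ok <- array(FALSE, d[1:3])
  if (length(idx) == 0L)
    return(new("T1Map", t1 = t1, m0 = m0, fitOk = ok))

  kap <- faMap@kappa[idx]
  nA <- length(angles)
  x <- matrix(0, length(idx), nA)
  y <- matrix(0, length(idx), nA)
  for (j in seq_len(nA)) {
    vol <- vfaScans@signal[, , , j]
    s <- vol[idx]
    a <- kap * angles[j] * pi / 180
    y[, j] <- s / sin(a)
    x[, j] <- s / tan(a)
  }
  xbar <- rowMeans(x); ybar <- rowMeans(y)
  sxx <- rowSums((x - xbar)^2)
  sxy <- rowSums((x - xbar) * (y - ybar))
  e1 <- sxy / sxx
  valid <- is.finite(e1) & e1 > 0 & e1 < 1 &
           apply(is.finite(x) & is.finite(y), 1L, all)
  t1v <- rep(NA_real_, length(idx))
  m0v <- rep(NA_real_, length(idx))
  t1v[valid] <- -tr / log(e1[valid])
  m0v[valid] <- (ybar[valid] - e1[valid] * xbar[valid]) / (1 - e1[valid])
  valid <- valid & is.finite(t1v) & t1v > 0 & is.finite(m0v) & m0v >= 0
  t1v[!valid] <- NA_real_; m0v[!valid] <- NA_real_
  t1[idx] <- t1v; m0[idx] <- m0v; ok[idx] <- valid
  new("T1Map", t1 = t1, m0 = m0, fitOk = ok)
}
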