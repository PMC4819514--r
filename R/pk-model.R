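#' @include AllClasses.R
NULL

# classed condition for quantities that are undefined on the given input
# (e.g. a median over zero viable voxels); callers can catch
# "tumorquantUndefined" specifically.
undefinedResult <- function(msg) {
  stop(structure(class = c("tumorquantUndefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Extended Kety (Tofts) forward model with exact convolution
#'
#' Tissue concentration for the three-parameter extended Kety model,
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)
#'   e^{-(K^{trans}/v_e)(t-\tau)} d\tau,}
#' driven by the bi-exponential population AIF. Because \eqn{C_p} is a sum
#' of exponentials, the convolution has the closed form (per AIF term, with
#' \eqn{k_{ep} = K^{trans}/v_e} and \eqn{\tau} minutes past onset)
#' \deqn{D a_i \frac{e^{-m_i\tau} - e^{-k_{ep}\tau}}{k_{ep} - m_i},}
#' evaluated exactly rather than by Riemann summation; the removable
#' singularity at \eqn{k_{ep} = m_i} uses the limit
#' \eqn{D a_i \tau e^{-k_{ep}\tau}}.
#'
#' @param ktrans volume transfer constant, per minute (>= 0)
#' @param ve fractional extravascular-extracellular volume; must be > 0
#'   whenever ktrans > 0
#' @param vp fractional plasma volume
#' @param aif an [AIFModel-class]
#' @param times seconds from acquisition start, increasing
#' @return tissue concentration in mM at each time
#' @examples
#' aif <- aifModel(onsetTime = 312)
#' tt <- seq(0, 2652, by = 15.6)
#' ct <- ketyForward(0.25, 0.3, 0.05, aif, tt)
#' @export
ketyForward <- function(ktrans, ve, vp, aif, times) {
  if (ktrans < 0) stop("ktrans must be >= 0")
  if (ktrans > 0 && ve <= 0)
    stop("ve = 0 with ktrans > 0 leaves the efflux rate undefined")
  if (vp < 0 || vp > 1) stop("vp must be in [0, 1]")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  cp <- aifConcentration(aif, times)
  if (ktrans == 0) return(vp * cp)
  kep <- ktrans / ve
  tau <- pmax((times - aif@onsetTime) / 60, 0)
  conv <- convTerm(aif@dose * aif@a1, aif@m1, kep, tau) +
          convTerm(aif@dose * aif@a2, aif@m2, kep, tau)
  vp * cp + ktrans * conv
}

# exact convolution of amp*exp(-m*tau) with exp(-kep*tau), per minute
convTerm <- function(amp, m, kep, tau) {
  if (abs(kep - m) < 1e-9 * max(kep, m, 1)) {
    amp * tau * exp(-kep * tau)
  } else {
    amp * (exp(-m * tau) - exp(-kep * tau)) / (kep - m)
  }
}

# d/dkep of convTerm (used by the analytic fit gradient)
convTermDkep <- function(amp, m, kep, tau) {
  if (abs(kep - m) < 1e-6 * max(kep, m, 1)) {
    -amp * tau^2 / 2 * exp(-kep * tau)
  } else {
    d <- kep - m
    amp * (tau * exp(-kep * tau) * d - (exp(-m * tau) - exp(-kep * tau))) / d^2
  }
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Inverts the SPGR signal equation frame by frame, assuming linearity
#' between agent concentration and the longitudinal relaxation rate.
#' Per voxel, the equilibrium scale is fixed from the pre-contrast baseline
#' (mean over the nPre pre-contrast frames) and the native T1; each frame's
#' \eqn{E_1(t)} then follows from
#' \eqn{E_1 = (M\sin\alpha - S)/(M\sin\alpha - S\cos\alpha)} with the
#' kappa-corrected dynamic flip angle, giving
#' \eqn{R_1(t) = -\ln E_1(t) / TR} and
#' \eqn{C(t) = (R_1(t) - R_1(0)) / r_1}.
#'
#' Frames whose inversion leaves the valid SPGR domain (\eqn{E_1}
#' outside (0, 1)) are marked invalid; voxels without a valid T1 fit are
#' entirely invalid and excluded from downstream fitting.
#'
#' @param dyn a [DynamicSeries-class]
#' @param t1map a [T1Map-class] on the same grid
#' @param faMap a [FlipAngleMap-class] on the same grid
#' @param relaxivity contrast-agent r1 relaxivity, 1/s/mM (default 3.9,
#'   gadodiamide at 7 T; override to match the agent and field)
#' @param mask optional 3D logical array restricting the conversion
#' @return a [ConcentrationSeries-class]
#' @export
signalToConcentration <- function(dyn, t1map, faMap, relaxivity = 3.9,
                                  mask = NULL) {
  stopifnot(is(dyn, "DynamicSeries"), is(t1map, "T1Map"),
            is(faMap, "FlipAngleMap"))
  d <- dim(dyn@signal)
  if (!identical(d[1:3], dim(t1map@t1)) ||
      !identical(d[1:3], dim(faMap@kappa)))
    stop("t1map / flip-angle map grid does not match dynamic series")
  acq <- dyn@acq
  if (acq@nPre < 2L) stop("need at least two pre-contrast frames")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])

  use <- mask & t1map@fitOk
  idx <- which(use)
  nFrame <- d[4]
  conc <- array(NA_real_, d)
  valid <- array(FALSE, d)
  baselineR1 <- array(NA_real_, d[1:3])

  if (length(idx)) {
    sig <- matrix(0, length(idx), nFrame)
    for (f in seq_len(nFrame)) {
      vol <- dyn@signal[, , , f]
      sig[, f] <- vol[idx]
    }
    s0 <- rowMeans(sig[, seq_len(acq@nPre), drop = FALSE])
    t1 <- t1map@t1[idx]
    a <- faMap@kappa[idx] * acq@flipDyn * pi / 180
    e10 <- exp(-acq@trDyn / t1)
    bigM <- s0 * (1 - e10 * cos(a)) / (sin(a) * (1 - e10))
    r10 <- 1000 / t1                      # 1/s
    baselineR1[idx] <- r10

    cmat <- matrix(NA_real_, length(idx), nFrame)
    vmat <- matrix(FALSE, length(idx), nFrame)
    msin <- bigM * sin(a)
    for (f in seq_len(nFrame)) {
      s <- sig[, f]
      e1 <- (msin - s) / (msin - s * cos(a))
      okf <- is.finite(e1) & e1 > 0 & e1 < 1
      r1t <- rep(NA_real_, length(s))
      r1t[okf] <- 1000 * (-log(e1[okf])) / acq@trDyn
      cmat[, f] <- (r1t - r10) / relaxivity
      vmat[, f] <- okf
    }
    for (f in seq_len(nFrame)) {
      volC <- conc[, , , f]; volV <- valid[, , , f]
      volC[idx] <- cmat[, f]; volV[idx] <- vmat[, f]
      conc[, , , f] <- volC; valid[, , , f] <- volV
    }
  }
  new("ConcentrationSeries", conc = conc, valid = valid,
      baselineR1 = baselineR1, relaxivity = relaxivity,
      frameTimes = dyn@frameTimes, acq = acq)
}

#' Fit the extended Kety model in every masked voxel
#'
#' Bounded nonlinear least squares of [ketyForward] against each voxel's
#' concentration-time curve. A 4 x 2 grid of (ktrans, ve) starts with
#' vp = 0.02 is scored first; full L-BFGS-B optimisation (analytic
#' gradients) runs from the three best starts and the lowest-RSS solution
#' is kept. Bounds: ktrans in [0, 5]/min, ve in [1e-3, 1], vp in [0, 1],
#' with the joint physiological constraint ve + vp <= 1 enforced by a
#' smooth penalty. Voxels that fail to converge, or finish stuck at a
#' ktrans/ve bound, are flagged not-OK; per-voxel failures never raise.
#'
#' The enhancement flag marks voxels whose peak concentration exceeds
#' `enhancementFactor` times the pre-contrast concentration SD (plus a tiny
#' absolute floor so that exactly-zero curves never count as enhancing);
#' [medianKtransViable] uses it to exclude non-enhancing tissue.
#'
#' @param conc a [ConcentrationSeries-class]
#' @param aif an [AIFModel-class]
#' @param mask 3D logical array; must select at least one voxel
#' @param minValidFrames minimum number of valid frames per voxel
#' @param enhancementFactor multiple of baseline noise SD defining
#'   enhancement
#' @param starts optional list overriding the start grid
#'   (`ktrans`, `ve`, `vp` numeric vectors)
#' @return a [PKParameterMap-class]
#' @export
fitKetyVoxelwise <- function(conc, aif, mask, minValidFrames = 10L,
                             enhancementFactor = 3, starts = NULL) {
  stopifnot(is(conc, "ConcentrationSeries"), is(aif, "AIFModel"))
  d <- dim(conc@conc)
  if (!identical(d[1:3], dim(mask)))
    stop("mask grid does not match concentration series")
  if (!any(mask)) stop("empty mask: no voxels to fit")
  if (is.null(starts))
    starts <- list(ktrans = c(0.02, 0.1, 0.3, 1.0), ve = c(0.1, 0.4),
                   vp = 0.02)

  times <- conc@frameTimes
  nPre <- conc@acq@nPre
  idx <- which(mask)
  shape <- d[1:3]
  ktrans <- array(NA_real_, shape); ve <- array(NA_real_, shape)
  vp <- array(NA_real_, shape); rss <- array(NA_real_, shape)
  ok <- array(FALSE, shape); enh <- array(FALSE, shape)

  lower <- c(0, 1e-3, 0); upper <- c(5, 1, 1)
  startGrid <- as.matrix(expand.grid(ktrans = starts$ktrans,
                                     ve = starts$ve, vp = starts$vp))

  cmat <- matrix(NA_real_, length(idx), length(times))
  vmat <- matrix(FALSE, length(idx), length(times))
  for (f in seq_along(times)) {
    volC <- conc@conc[, , , f]; volV <- conc@valid[, , , f]
    cmat[, f] <- volC[idx]; vmat[, f] <- volV[idx]
  }

  for (v in seq_along(idx)) {
    vi <- idx[v]
    valf <- vmat[v, ]
    if (sum(valf) < minValidFrames) next
    y <- cmat[v, valf]
    tt <- times[valf]
    fit <- fitKetyOne(y, tt, aif, startGrid, lower, upper)
    ktrans[vi] <- fit$par[1]; ve[vi] <- fit$par[2]; vp[vi] <- fit$par[3]
    rss[vi] <- fit$rss
    atBound <- fit$par[1] <= lower[1] + 1e-9 ||
               fit$par[1] >= upper[1] - 1e-6 ||
               fit$par[2] <= lower[2] + 1e-9 ||
               fit$par[2] >= upper[2] - 1e-9
    ok[vi] <- fit$converged && !atBound &&
              fit$par[2] + fit$par[3] <= 1 + 1e-8
    preIdx <- valf & seq_along(times) <= nPre
    preSd <- if (sum(preIdx) >= 2) stats::sd(cmat[v, preIdx]) else 0
    enh[vi] <- max(y) > enhancementFactor * preSd + 1e-9
  }
  new("PKParameterMap", ktrans = ktrans, ve = ve, vp = vp, rss = rss,
      fitOk = ok, enhancing = enh)
}

# single-voxel extended Kety fit: score the start grid, refine best three
fitKetyOne <- function(y, tt, aif, startGrid, lower, upper) {
  cp <- aifConcentration(aif, tt)
  tau <- pmax((tt - aif@onsetTime) / 60, 0)
  d1 <- aif@dose * aif@a1; d2 <- aif@dose * aif@a2
  m1 <- aif@m1; m2 <- aif@m2

  obj <- function(p) {
    kt <- p[1]; vee <- p[2]; vpp <- p[3]
    kep <- kt / vee
    conv <- convTerm(d1, m1, kep, tau) + convTerm(d2, m2, kep, tau)
    r <- vpp * cp + kt * conv - y
    pen <- max(0, vee + vpp - 1)
    sum(r * r) + 1e3 * pen * pen
  }
  grad <- function(p) {
    kt <- p[1]; vee <- p[2]; vpp <- p[3]
    kep <- kt / vee
    conv <- convTerm(d1, m1, kep, tau) + convTerm(d2, m2, kep, tau)
    dconv <- convTermDkep(d1, m1, kep, tau) + convTermDkep(d2, m2, kep, tau)
    r <- vpp * cp + kt * conv - y
    dKt <- conv + kt * dconv / vee
    dVe <- -kt * kep * dconv / vee
    dVp <- cp
    pen <- max(0, vee + vpp - 1)
    c(2 * sum(r * dKt),
      2 * sum(r * dVe) + 2e3 * pen,
      2 * sum(r * dVp) + 2e3 * pen)
  }

  sc <- apply(startGrid, 1L, obj)
  ord <- order(sc)[seq_len(min(3L, nrow(startGrid)))]
  best <- NULL
  for (s in ord) {
    res <- tryCatch(
      stats::optim(startGrid[s, ], obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e3, pgtol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(list(par = c(0, 1e-3, 0), rss = sum(y * y), converged = FALSE))
  list(par = unname(best$par), rss = best$value,
       converged = best$convergence == 0)
}

#' Median Ktrans over viable tumor tissue
#'
#' The per-tumor summary statistic: the median of voxelwise Ktrans over
#' voxels that are inside the tumor mask, have a valid fit, and enhance
#' above the baseline-noise threshold. Non-enhancing or failed ("unmapped")
#' voxels are excluded; their parameter values never influence the result.
#'
#' @param pk a [PKParameterMap-class]
#' @param mask 3D logical tumor mask
#' @return median Ktrans in per-minute units
#' @export
medianKtransViable <- function(pk, mask) {
  stopifnot(is(pk, "PKParameterMap"))
  if (!identical(dim(pk@ktrans), dim(mask)))
    stop("mask grid does not match parameter map")
  viable <- mask & pk@fitOk & pk@enhancing
  if (!any(viable))
    undefinedResult("no viable (fit-OK, enhancing) voxels inside the mask")
  stats::median(pk@ktrans[viable])
}
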