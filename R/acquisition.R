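#' Construct acquisition parameters
#'
#' @param trCal,trVfa,trDyn repetition times in ms for the flip-angle
#'   calibration scans, the VFA T1 scans and the dynamic series
#' @param teCal,teVfa,teDyn echo times in ms (stored for provenance)
#' @param flipCal nominal calibration flip angles, degrees
#' @param flipVfa nominal VFA flip angles, degrees
#' @param flipDyn nominal dynamic flip angle, degrees
#' @param frameInterval seconds per dynamic frame
#' @param nPre,nPost pre- and post-contrast dynamic frame counts
#' @return an [AcquisitionParams-class] object
#' @examples
#' acq <- acquisitionParams()
#' acq@frameInterval   # 15.6 s per dynamic frame
#' @export
acquisitionParams <- function(trCal = 460, trVfa = 144, trDyn = 9,
                              teCal = 3.5, teVfa = 2.7, teDyn = 2.7,
                              flipCal = c(145, 180, 215),
                              flipVfa = c(10, 20, 50),
                              flipDyn = 25, frameInterval = 15.6,
                              nPre = 20L, nPost = 150L) {
  new("AcquisitionParams", trCal = trCal, trVfa = trVfa, trDyn = trDyn,
      teCal = teCal, teVfa = teVfa, teDyn = teDyn,
      flipCal = flipCal, flipVfa = flipVfa, flipDyn = flipDyn,
      frameInterval = frameInterval,
      nPre = as.integer(nPre), nPost = as.integer(nPost))
}

#' Dynamic frame times for an acquisition
#'
#' Frame start times in seconds, 0-based: frame k starts at
#' (k - 1) * frameInterval.
#'
#' @param acq an [AcquisitionParams-class]
#' @return numeric vector of length nPre + nPost
#' @export
frameTimes <- function(acq) {
  (seq_len(acq@nPre + acq@nPost) - 1L) * acq@frameInterval
}

#' Spoiled gradient-echo steady-state signal
#'
#' The SPGR signal equation
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}, \quad
#'       E_1 = e^{-TR/T_1}.}
#' TE-dependent T2* weighting is absorbed into \eqn{M_0}.
#'
#' @param m0 equilibrium signal scale (arbitrary units); recyclable
#' @param t1Ms longitudinal relaxation time, ms
#' @param trMs repetition time, ms
#' @param flipDeg flip angle, degrees
#' @return signal in the units of m0
#' @examples
#' spgrSignal(1000, t1Ms = 1500, trMs = 144, flipDeg = 20)
#' @export
spgrSignal <- function(m0, t1Ms, trMs, flipDeg) {
  a <- flipDeg * pi / 180
  e1 <- exp(-trMs / t1Ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}
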