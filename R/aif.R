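#' Construct a population arterial input function
#'
#' Bi-exponential plasma clearance model scaled by injected dose. The
#' default amplitudes and decay rates are the classic population-average
#' values for gadolinium chelates (a1 = 3.99, a2 = 4.78 kg/L; m1 = 0.144,
#' m2 = 0.0111 per minute); the default dose is 0.3 mmol/kg. All parameters
#' are explicit so a cohort-specific population AIF can be substituted.
#'
#' @param dose injected dose, mmol/kg
#' @param a1,a2 amplitudes, mM per unit dose
#' @param m1,m2 decay rates, per minute
#' @param onsetTime bolus arrival, seconds from acquisition start
#' @return an [AIFModel-class]
#' @export
aifModel <- function(dose = 0.3, a1 = 3.99, a2 = 4.78,
                     m1 = 0.144, m2 = 0.0111, onsetTime = 0) {
  new("AIFModel", dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2,
      onsetTime = onsetTime)
}

#' Evaluate the plasma concentration curve
#'
#' \eqn{C_p(t) = D (a_1 e^{-m_1 \tau} + a_2 e^{-m_2 \tau})} with
#' \eqn{\tau = (t - t_0)/60} minutes past bolus onset, and 0 before onset.
#'
#' @param aif an [AIFModel-class]
#' @param times seconds from acquisition start
#' @return plasma concentration in mM at each time
#' @export
aifConcentration <- function(aif, times) {
  tauMin <- (times - aif@onsetTime) / 60
  cp <- aif@dose * (aif@a1 * exp(-aif@m1 * tauMin) +
                    aif@a2 * exp(-aif@m2 * tauMin))
  cp[tauMin < 0] <- 0
  cp
}
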