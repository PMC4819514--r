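#' @include AllClasses.R
NULL

#' Generate a synthetic multi-arm cohort table
#'
#' Per-tumor metric values drawn from log-normal distributions: each value
#' is `baseline[metric] * effects[[arm]][metric] * exp(N(0, sdLog))`.
#' With `sdLog = 0` the group means equal the specified effects exactly.
#' The default arms and effect pattern emulate a three-arm treatment study
#' read out on day 7: a metronomic-chemotherapy arm with 10-fold smaller
#' volumes, elevated Ktrans and low hypoxia, and an anti-angiogenic arm
#' with reduced vessel density (longer vessel distance) but unchanged
#' Ktrans and volume.
#'
#' @param nPerArm tumors per arm (>= 2)
#' @param effects named list (one element per arm) of named numeric
#'   multiplicative effects per metric; all strictly positive
#' @param baseline named numeric baseline value per metric
#' @param sdLog log-scale noise SD (>= 0)
#' @param line,day labels stored in the table
#' @param seed RNG seed
#' @return data.frame with columns tumorId, line, arm, day, metric, value
#' @export
makeGroupCohort <- function(nPerArm = 8L,
                            effects = list(
                              "Veh-ctrl" = c(volume = 1, ktrans = 1,
                                             ef5Fraction = 1,
                                             vesselDistance = 1),
                              "DC101" = c(volume = 1, ktrans = 1,
                                          ef5Fraction = 1,
                                          vesselDistance = 1.5),
                              "Met-Gem" = c(volume = 0.1, ktrans = 2,
                                            ef5Fraction = 0.3,
                                            vesselDistance = 0.7)),
                            baseline = c(volume = 500, ktrans = 0.1,
                                         ef5Fraction = 20,
                                         vesselDistance = 50),
                            sdLog = 0.25, line = "PaCa8", day = 7L,
                            seed = 1L) {
  if (nPerArm < 2L) stop("nPerArm must be >= 2")
  if (is.null(names(effects))) stop("effects must be a named list (one per arm)")
  if (any(unlist(effects) <= 0)) stop("all effects must be strictly positive")
  if (sdLog < 0) stop("sdLog must be >= 0")
  metrics <- names(baseline)
  if (!all(vapply(effects, function(e) all(metrics %in% names(e)),
                  logical(1))))
    stop("every arm must provide an effect for every baseline metric")
  set.seed(seed)
  rows <- list()
  tumorN <- 0L
  for (arm in names(effects)) {
    for (i in seq_len(nPerArm)) {
      tumorN <- tumorN + 1L
      for (m in metrics) {
        val <- baseline[[m]] * effects[[arm]][[m]] *
          exp(stats::rnorm(1, 0, sdLog))
        rows[[length(rows) + 1]] <- data.frame(
          tumorId = sprintf("T%03d", tumorN), line = line, arm = arm,
          day = day, metric = m, value = val)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
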