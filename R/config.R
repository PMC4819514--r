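#' @include acquisition.R aif.R
NULL

#' Default pipeline configuration
#'
#' The complete configuration schema with defaults: acquisition constants
#' (the 7 T protocol defaults of [acquisitionParams]), AIF parameters,
#' contrast-agent relaxivity, analysis thresholds (per-channel positivity,
#' enhancement factor for the viable-tissue rule, PET ROI fraction),
#' shell structuring-element connectivity, significance level, seed, and
#' the phantom/cohort parameters used in simulation mode.
#'
#' @return nested named list
#' @export
defaultPipelineConfig <- function() {
  list(
    acquisition = list(trCal = 460, trVfa = 144, trDyn = 9,
                       teCal = 3.5, teVfa = 2.7, teDyn = 2.7,
                       flipCal = c(145, 180, 215),
                       flipVfa = c(10, 20, 50), flipDyn = 25,
                       frameInterval = 15.6, nPre = 20L, nPost = 150L),
    aif = list(dose = 0.3, a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111,
               onsetTime = NA),     # NA: bolus at first post-contrast frame
    relaxivity = 3.9,
    thresholds = list(ef5 = 100, ki67 = 100, tunel = 100, cd31 = 100,
                      hoechst_perfusion = 100, enhancementFactor = 3,
                      roiFraction = 0.4),
    connectivity = 6L,
    alpha = 0.05,
    seed = 1L,
    phantom = list(gridShape = c(32L, 32L, 16L), rimFraction = 0.15,
                   ktransRim = 0.3, ktransCore = 0.1, ve = 0.3, vp = 0.05,
                   t1Ms = 1800, kappaTrue = 0.9, m0Scale = 1000,
                   noiseSd = 0),
    section = list(imageShape = c(200L, 200L), nVessels = 30L,
                   perfusedFractionTrue = 0.7, hypoxiaDistanceUm = 40,
                   necrosisFractionTrue = 0.2, ki67FractionTrue = 0.3,
                   tunelFractionTrue = 0.05, pixelSizeUm = 1),
    cohort = list(nPerArm = 8L, sdLog = 0.25)
  )
}

# recursive merge of user values over defaults, rejecting unknown keys
mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      mergeConfig(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

validateConfig <- function(cfg) {
  bad <- character()
  inRange <- function(x, lo, hi) is.numeric(x) && x > lo && x < hi
  if (!inRange(cfg$alpha, 0, 1)) bad <- c(bad, "alpha must be in (0, 1)")
  if (!inRange(cfg$thresholds$roiFraction, 0, 1))
    bad <- c(bad, "thresholds.roiFraction must be in (0, 1)")
  if (!is.numeric(cfg$thresholds$enhancementFactor) ||
      cfg$thresholds$enhancementFactor < 0)
    bad <- c(bad, "thresholds.enhancementFactor must be >= 0")
  if (!cfg$connectivity %in% c(6, 18, 26))
    bad <- c(bad, "connectivity must be 6, 18 or 26")
  if (!is.numeric(cfg$relaxivity) || cfg$relaxivity <= 0)
    bad <- c(bad, "relaxivity must be > 0")
  if (cfg$acquisition$frameInterval <= 0)
    bad <- c(bad, "acquisition.frameInterval must be > 0")
  if (cfg$acquisition$nPre < 2)
    bad <- c(bad, "acquisition.nPre must be >= 2")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  invisible(cfg)
}

#' Load and validate a pipeline configuration from YAML
#'
#' Missing keys take their defaults ([defaultPipelineConfig]); an empty
#' file yields all defaults. Unknown keys and out-of-range values are
#' rejected, listing the offending keys.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- mergeConfig(defaultPipelineConfig(), user)
  validateConfig(cfg)
  cfg
}

#' Save a pipeline configuration as YAML
#'
#' @param cfg configuration list
#' @param path output YAML path
#' @return path, invisibly
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# build S4 parameter objects from the config lists
configAcquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisitionParams(trCal = a$trCal, trVfa = a$trVfa, trDyn = a$trDyn,
                    teCal = a$teCal, teVfa = a$teVfa, teDyn = a$teDyn,
                    flipCal = a$flipCal, flipVfa = a$flipVfa,
                    flipDyn = a$flipDyn, frameInterval = a$frameInterval,
                    nPre = a$nPre, nPost = a$nPost)
}

configAif <- function(cfg, acq) {
  a <- cfg$aif
  onset <- if (is.null(a$onsetTime) || is.na(a$onsetTime))
    acq@nPre * acq@frameInterval else a$onsetTime
  aifModel(dose = a$dose, a1 = a$a1, a2 = a$a2, m1 = a$m1, m2 = a$m2,
           onsetTime = onset)
}
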