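#' @include AllClasses.R histo.R
NULL

#' Specify an immunofluorescence section phantom
#'
#' @param imageShape pixel counts (rows, cols)
#' @param nVessels number of single-pixel vessel objects
#' @param perfusedFractionTrue fraction of vessels carrying perfusion dye
#' @param hypoxiaDistanceUm distance from the nearest perfused vessel
#'   beyond which tissue is painted hypoxia-positive
#' @param necrosisFractionTrue fraction of tumor area painted necrotic
#' @param ki67FractionTrue,tunelFractionTrue painted positive fractions of
#'   viable tissue for the proliferation / apoptosis channels
#' @param pixelSizeUm microns per pixel
#' @param seed RNG seed
#' @return a [SectionPhantomSpec-class]
#' @export
sectionPhantomSpec <- function(imageShape = c(200L, 200L), nVessels = 30L,
                               perfusedFractionTrue = 0.7,
                               hypoxiaDistanceUm = 40,
                               necrosisFractionTrue = 0.2,
                               ki67FractionTrue = 0.3,
                               tunelFractionTrue = 0.05,
                               pixelSizeUm = 1, seed = 1L) {
  new("SectionPhantomSpec", imageShape = as.integer(imageShape),
      nVessels = as.integer(nVessels),
      perfusedFractionTrue = perfusedFractionTrue,
      hypoxiaDistanceUm = hypoxiaDistanceUm,
      necrosisFractionTrue = necrosisFractionTrue,
      ki67FractionTrue = ki67FractionTrue,
      tunelFractionTrue = tunelFractionTrue,
      pixelSizeUm = pixelSizeUm, seed = as.integer(seed))
}

# intensity conventions of the painted channels
.PHANTOM_BG <- 10
.PHANTOM_POS <- 200
.PHANTOM_THR <- 100

#' Generate a section phantom with exactly known metrics
#'
#' Paints a multi-channel section so every whole-section metric recovers
#' its ground truth exactly (up to one-pixel rounding of painted counts):
#' the tumor fills the image minus a margin; the first
#' `round(necrosisFractionTrue * nTumor)` tumor pixels in raster order form
#' the necrotic band; vessels are `nVessels` distinct random viable pixels
#' of which exactly `round(perfusedFractionTrue * nVessels)` are painted
#' perfusion-dye positive; hypoxia-channel pixels are those viable pixels
#' farther than `hypoxiaDistanceUm` from the nearest perfused vessel
#' (anchoring the hypoxia gradient to vascular geometry); proliferation and
#' apoptosis channels get exact painted counts of random viable pixels.
#' Positive pixels have intensity 200 on a background of 10, so the default
#' fixed threshold of 100 separates them exactly.
#'
#' @param spec a [SectionPhantomSpec-class]
#' @return list with `set` (a [SectionImageSet-class]) and `truth`, a list
#'   of the ground-truth metric values (same names/units as
#'   [computeSectionMetrics]); `truth$meanVesselDistanceUm` is computed by
#'   direct nearest-vessel search, independent of the metric code
#' @export
makeSectionPhantom <- function(spec) {
  stopifnot(is(spec, "SectionPhantomSpec"))
  set.seed(spec@seed)
  d <- spec@imageShape
  margin <- pmax(1L, round(0.05 * d))
  tumor <- matrix(FALSE, d[1], d[2])
  tumor[(margin[1] + 1):(d[1] - margin[1]),
        (margin[2] + 1):(d[2] - margin[2])] <- TRUE
  nTumor <- sum(tumor)

  nNecro <- round(spec@necrosisFractionTrue * nTumor)
  necrosis <- matrix(FALSE, d[1], d[2])
  tumorIdxRaster <- which(t(tumor))                  # raster (row-major) order
  rasterToIdx <- function(k) {
    rc <- arrayInd(k, c(d[2], d[1]))                 # (col, row) of transposed
    (rc[, 1] - 1L) * d[1] + rc[, 2]
  }
  if (nNecro > 0)
    necrosis[rasterToIdx(tumorIdxRaster[seq_len(nNecro)])] <- TRUE
  artifact <- matrix(FALSE, d[1], d[2])
  viable <- tumor & !necrosis
  nViable <- sum(viable)
  if (nViable == 0) stop("necrosis fraction leaves no viable tissue")
  if (spec@nVessels > nViable)
    stop("more vessels requested than viable pixels available")

  viableIdx <- which(viable)
  vesselIdx <- sample(viableIdx, spec@nVessels)
  nPerf <- round(spec@perfusedFractionTrue * spec@nVessels)
  perfIdx <- vesselIdx[seq_len(nPerf)]

  cd31 <- matrix(.PHANTOM_BG, d[1], d[2]); cd31[vesselIdx] <- .PHANTOM_POS
  hoechst <- matrix(.PHANTOM_BG, d[1], d[2]); hoechst[perfIdx] <- .PHANTOM_POS

  # hypoxia: viable pixels beyond the distance threshold from any
  # perfused vessel (all hypoxic when nothing is perfused)
  ef5 <- matrix(.PHANTOM_BG, d[1], d[2])
  if (nPerf > 0) {
    perfMask <- matrix(FALSE, d[1], d[2]); perfMask[perfIdx] <- TRUE
    dt <- EBImage::imageData(EBImage::distmap(1 - perfMask,
                                              metric = "euclidean"))
    hyp <- viable & (dt * spec@pixelSizeUm > spec@hypoxiaDistanceUm)
  } else {
    hyp <- viable
  }
  ef5[hyp] <- .PHANTOM_POS

  paintExact <- function(fracTrue) {
    ch <- matrix(.PHANTOM_BG, d[1], d[2])
    k <- round(fracTrue * nViable)
    if (k > 0) ch[sample(viableIdx, k)] <- .PHANTOM_POS
    list(channel = ch, count = k)
  }
  ki67 <- paintExact(spec@ki67FractionTrue)
  tunel <- paintExact(spec@tunelFractionTrue)
  counter <- matrix(.PHANTOM_BG, d[1], d[2])
  counter[tumor] <- .PHANTOM_POS / 2

  set <- new("SectionImageSet",
             channels = list(hoechst_perfusion = hoechst, cd31 = cd31,
                             ef5 = ef5, ki67 = ki67$channel,
                             tunel = tunel$channel, counterstain = counter),
             pixelSizeUm = spec@pixelSizeUm, tumorMask = tumor,
             necrosisMask = necrosis, artifactMask = artifact)

  # ground-truth vessel distance by direct nearest-vessel search
  vr <- arrayInd(vesselIdx, d)
  pv <- arrayInd(viableIdx, d)
  dmin <- rep(Inf, nViable)
  for (v in seq_len(nrow(vr)))
    dmin <- pmin(dmin, sqrt((pv[, 1] - vr[v, 1])^2 + (pv[, 2] - vr[v, 2])^2))
  truth <- list(
    ef5Fraction = 100 * sum(hyp) / nViable,
    ki67Fraction = 100 * ki67$count / nViable,
    tunelFraction = 100 * tunel$count / nViable,
    perfusedVesselFraction = if (spec@nVessels > 0)
      100 * nPerf / spec@nVessels else NA_real_,
    meanVesselDistanceUm = if (spec@nVessels > 0)
      mean(dmin) * spec@pixelSizeUm else NA_real_,
    necroticFraction = 100 * nNecro / nTumor)
  list(set = set, truth = truth)
}
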