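#' @include AllClasses.R pk-model.R
NULL

# shift a matrix by (dr, dc), filling exposed pixels with `fill`
shiftMatrix <- function(m, dr, dc, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  sr <- max(1, 1 + dr):min(d[1], d[1] + dr)
  sc <- max(1, 1 + dc):min(d[2], d[2] + dc)
  if (!length(sr) || !length(sc)) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# normalised cross-correlation of two matrices on the overlap implied by a
# shift of `m` relative to `ref`
nccAtShift <- function(ref, m, dr, dc) {
  d <- dim(ref)
  sr <- max(1, 1 + dr):min(d[1], d[1] + dr)
  sc <- max(1, 1 + dc):min(d[2], d[2] + dc)
  if (length(sr) < 2 || length(sc) < 2) return(NA_real_)
  a <- ref[sr, sc]
  b <- m[sr - dr, sc - dc]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

#' Align separately imaged channels by integer-pixel translation
#'
#' Each non-reference channel is rigidly translated to maximise its
#' normalised cross-correlation with the reference channel over a bounded
#' search window (integer shifts only — re-imaging drift of the same
#' physical section is translational). A shift is only applied when the
#' correlation peak is distinct: the best correlation must exceed
#' `minCorrelation`, and must exceed the second peak (outside the best
#' peak's immediate neighbourhood) by the factor `peakRatio`; otherwise the
#' channel is left unshifted with a warning.
#'
#' @param set a [SectionImageSet-class]
#' @param reference name of the channel the others are aligned to
#' @param maxShift search window half-width in pixels
#' @param minCorrelation minimum acceptable peak correlation
#' @param peakRatio required ratio of best to second-best peak
#' @return the set with channels shifted; applied shifts are attached as
#'   `attr(, "shifts")` (one `c(dr, dc)` per channel)
#' @export
alignChannels <- function(set, reference = "counterstain", maxShift = 10L,
                          minCorrelation = 0.2, peakRatio = 1.05) {
  stopifnot(is(set, "SectionImageSet"))
  if (length(set@channels) < 2L) stop("need at least two channels to align")
  if (!reference %in% names(set@channels))
    stop("reference channel '", reference, "' not present")
  ref <- set@channels[[reference]]
  shiftRange <- -maxShift:maxShift
  shifts <- list()
  for (nm in names(set@channels)) {
    if (nm == reference) { shifts[[nm]] <- c(0L, 0L); next }
    ch <- set@channels[[nm]]
    ncc <- matrix(NA_real_, length(shiftRange), length(shiftRange))
    for (i in seq_along(shiftRange))
      for (j in seq_along(shiftRange))
        ncc[i, j] <- nccAtShift(ref, ch, shiftRange[i], shiftRange[j])
    if (all(is.na(ncc))) {
      warning("channel '", nm, "': no valid correlation; left unshifted")
      shifts[[nm]] <- c(0L, 0L); next
    }
    bestIdx <- which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    best <- ncc[bestIdx[1], bestIdx[2]]
    neigh <- ncc
    neigh[max(1, bestIdx[1] - 1):min(nrow(ncc), bestIdx[1] + 1),
          max(1, bestIdx[2] - 1):min(ncol(ncc), bestIdx[2] + 1)] <- NA
    second <- suppressWarnings(max(neigh, na.rm = TRUE))
    distinct <- is.finite(best) && best >= minCorrelation &&
      (!is.finite(second) || second <= 0 || best / second >= peakRatio)
    if (!distinct) {
      warning("channel '", nm,
              "': correlation peak indistinct; left unshifted")
      shifts[[nm]] <- c(0L, 0L); next
    }
    dr <- shiftRange[bestIdx[1]]; dc <- shiftRange[bestIdx[2]]
    set@channels[[nm]] <- shiftMatrix(ch, dr, dc)
    shifts[[nm]] <- c(dr, dc)
  }
  attr(set, "shifts") <- shifts
  set
}

#' Viable tumor tissue mask
#'
#' Viable tissue = tumor boundary minus necrosis minus imaging artifacts,
#' matching the manual cropping step of whole-section analysis.
#'
#' @param set a [SectionImageSet-class]
#' @return logical matrix
#' @export
viableMask <- function(set) {
  stopifnot(is(set, "SectionImageSet"))
  viable <- set@tumorMask & !set@necrosisMask & !set@artifactMask
  if (!any(viable))
    stop("viable mask is empty: necrosis/artifact masks cover the tumor")
  viable
}

# resolve a threshold rule to a numeric cut for the given pixels:
# a number is used as-is; "otsu" computes Otsu's threshold within the pixels
resolveThreshold <- function(rule, pixels) {
  if (is.numeric(rule)) return(rule)
  if (identical(rule, "otsu")) {
    rng <- range(pixels)
    if (diff(rng) == 0) return(rng[1] + 1)  # constant channel: nothing positive
    return(EBImage::otsu(EBImage::Image(matrix(pixels, ncol = 1)),
                         range = rng))
  }
  stop("threshold rule must be a number or \"otsu\"")
}

#' Positive-pixel fraction of a marker channel
#'
#' Percentage of viable tumor pixels at or above the positivity threshold:
#' the readout used for the hypoxia (EF5), proliferation (Ki67) and
#' apoptosis (TUNEL) markers.
#'
#' @param channel 2D intensity matrix (aligned)
#' @param viable logical matrix of viable tumor pixels
#' @param threshold fixed numeric threshold, or `"otsu"` for Otsu's method
#'   computed within the viable pixels
#' @return percent in \[0, 100\]
#' @export
positiveFraction <- function(channel, viable, threshold) {
  if (!identical(dim(channel), dim(viable)))
    stop("channel and viable mask must share one shape")
  if (!any(viable)) stop("viable mask is empty")
  px <- channel[viable]
  thr <- resolveThreshold(threshold, px)
  100 * sum(px >= thr) / length(px)
}

#' Perfused-vessel fraction
#'
#' Percentage of endothelial-marker-positive (CD31+) pixels that are also
#' perfusion-dye positive (Hoechst+): double-positive pixels over all
#' vessel pixels. Undefined (a classed condition, not 0) when there are no
#' vessel pixels.
#'
#' @param cd31Mask,hoechstMask logical matrices on one grid
#' @return percent in \[0, 100\]
#' @export
perfusedVesselFraction <- function(cd31Mask, hoechstMask) {
  if (!identical(dim(cd31Mask), dim(hoechstMask)))
    stop("masks must share one shape")
  nV <- sum(cd31Mask)
  if (nV == 0) undefinedResult("no CD31+ pixels: perfused fraction undefined")
  100 * sum(cd31Mask & hoechstMask) / nV
}

#' Mean distance to the nearest vessel
#'
#' For every viable pixel, the Euclidean distance to the nearest
#' vessel (CD31+) pixel is computed by an exact distance transform, and the
#' distances are averaged and scaled to microns. A short average distance
#' indicates high microvessel density. Pixels are assumed square.
#'
#' @param cd31Mask logical matrix of vessel pixels (at least one)
#' @param viable logical matrix of pixels to average over
#' @param pixelSizeUm microns per pixel
#' @return mean nearest-vessel distance in microns
#' @export
meanVesselDistance <- function(cd31Mask, viable, pixelSizeUm) {
  if (!identical(dim(cd31Mask), dim(viable)))
    stop("masks must share one shape")
  if (!any(cd31Mask))
    undefinedResult("no CD31+ pixels: vessel distance undefined")
  if (!any(viable)) stop("viable mask is empty")
  dt <- EBImage::imageData(EBImage::distmap(1 - cd31Mask,
                                            metric = "euclidean"))
  mean(dt[viable]) * pixelSizeUm
}

#' Necrotic fraction of the tumor section
#'
#' Percentage of tumor pixels marked necrotic. The necrosis mask is an
#' input (drawn against H&E in practice), not a computed segmentation.
#'
#' @param necrosisMask,tumorMask logical matrices; necrosis must be a
#'   subset of the tumor mask
#' @return percent in \[0, 100\]
#' @export
necroticFraction <- function(necrosisMask, tumorMask) {
  if (!identical(dim(necrosisMask), dim(tumorMask)))
    stop("masks must share one shape")
  nT <- sum(tumorMask)
  if (nT == 0) stop("empty tumor mask")
  if (any(necrosisMask & !tumorMask))
    stop("necrosisMask must be a subset of tumorMask")
  100 * sum(necrosisMask) / nT
}

#' All section metrics for one tumor section
#'
#' Applies the five whole-section metrics to a [SectionImageSet-class]:
#' positive fractions of the hypoxia/proliferation/apoptosis channels over
#' viable tissue, perfused-vessel fraction, mean nearest-vessel distance,
#' and necrotic fraction.
#'
#' @param set a [SectionImageSet-class] (align first if channels drifted)
#' @param thresholds named list of per-channel positivity thresholds
#'   (numbers or `"otsu"`); names among ef5, ki67, tunel, cd31,
#'   hoechst_perfusion
#' @param includeNecrosis include necrotic pixels in the vessel-distance
#'   average (default FALSE: viable pixels only)
#' @return one-row data.frame of metrics (percent / microns)
#' @export
computeSectionMetrics <- function(set,
                                  thresholds = list(ef5 = 100, ki67 = 100,
                                                    tunel = 100, cd31 = 100,
                                                    hoechst_perfusion = 100),
                                  includeNecrosis = FALSE) {
  stopifnot(is(set, "SectionImageSet"))
  viable <- viableMask(set)
  cd31 <- getChannel(set, "cd31")
  cd31Thr <- resolveThreshold(thresholds$cd31, cd31[viable])
  cd31Mask <- cd31 >= cd31Thr & viable
  hoe <- getChannel(set, "hoechst_perfusion")
  hoeThr <- resolveThreshold(thresholds$hoechst_perfusion, hoe[viable])
  hoeMask <- hoe >= hoeThr
  distRegion <- if (includeNecrosis) viable | set@necrosisMask else viable
  data.frame(
    ef5Fraction = positiveFraction(getChannel(set, "ef5"), viable,
                                   thresholds$ef5),
    ki67Fraction = positiveFraction(getChannel(set, "ki67"), viable,
                                    thresholds$ki67),
    tunelFraction = positiveFraction(getChannel(set, "tunel"), viable,
                                     thresholds$tunel),
    perfusedVesselFraction = perfusedVesselFraction(cd31Mask, hoeMask),
    meanVesselDistanceUm = meanVesselDistance(cd31Mask, distRegion,
                                              set@pixelSizeUm),
    necroticFraction = necroticFraction(set@necrosisMask, set@tumorMask)
  )
}
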