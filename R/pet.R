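#' @include AllClasses.R shells.R
NULL

#' Construct a PET volume
#'
#' @param activity 3D non-negative array of per-voxel activity
#' @param voxelVolumeMm3 voxel volume, mm^3
#' @param injectedDose injected tracer dose (provenance)
#' @param scanDelayMin minutes from injection to scan (provenance; no decay
#'   correction is applied)
#' @return a [PETVolume-class]
#' @export
petVolume <- function(activity, voxelVolumeMm3, injectedDose = NA_real_,
                      scanDelayMin = NA_real_) {
  new("PETVolume", activity = activity, voxelVolumeMm3 = voxelVolumeMm3,
      injectedDose = injectedDose, scanDelayMin = scanDelayMin)
}

# largest 6-connected component of a 3D logical mask, by frontier growth
largestComponent3d <- function(mask) {
  offsets <- seOffsets(6L)
  remaining <- mask
  best <- NULL; bestN <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- array(FALSE, dim(mask)); comp[seed] <- TRUE
    repeat {
      grow <- array(FALSE, dim(mask))
      for (r in seq_len(nrow(offsets)))
        grow <- grow | shift3d(comp, offsets[r, 1], offsets[r, 2],
                               offsets[r, 3])
      grow <- grow & remaining & !comp
      if (!any(grow)) break
      comp <- comp | grow
    }
    n <- sum(comp)
    if (n > bestN) { best <- comp; bestN <- n }
    remaining <- remaining & !comp
  }
  best
}

#' Tracer-avid region of interest
#'
#' Reproducible surrogate for manual ROI placement on the actively
#' tracer-avid part of the tumor: voxels with activity at or above
#' `thresholdFraction` times the volume maximum, reduced to their largest
#' 6-connected component.
#'
#' @param pet a [PETVolume-class]
#' @param thresholdFraction fraction of the maximum activity, in (0, 1)
#' @return 3D logical ROI mask
#' @export
avidRoi <- function(pet, thresholdFraction = 0.4) {
  stopifnot(is(pet, "PETVolume"))
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must be in (0, 1)")
  mx <- max(pet@activity)
  if (mx == 0) stop("all-zero PET volume: no avid region")
  largestComponent3d(pet@activity >= thresholdFraction * mx)
}

#' Activity per unit tumor volume
#'
#' Total activity inside the ROI divided by the ROI's physical volume
#' (voxel count times voxel volume); equivalently the mean voxel intensity
#' normalised to volume. Zero-activity voxels outside the ROI never affect
#' the result.
#'
#' @param pet a [PETVolume-class]
#' @param roi non-empty 3D logical mask
#' @param normVolumeMm3 optional externally measured tumor volume (e.g. a
#'   caliper volume) to normalise by instead of the ROI's own volume
#' @return activity per mm^3
#' @export
activityPerVolume <- function(pet, roi, normVolumeMm3 = NULL) {
  stopifnot(is(pet, "PETVolume"))
  if (!identical(dim(roi), dim(pet@activity)))
    stop("roi grid does not match PET volume")
  n <- sum(roi)
  if (n == 0) stop("empty ROI")
  vol <- if (is.null(normVolumeMm3)) n * pet@voxelVolumeMm3
         else normVolumeMm3
  if (vol <= 0) stop("normalisation volume must be > 0")
  sum(pet@activity[roi]) / vol
}

#' Caliper tumor volume
#'
#' The standard prolate-ellipsoid estimate from two perpendicular caliper
#' measurements: \eqn{V = \pi/6 \; a b^2} with `a` the longest tumor
#' dimension and `b` the width.
#'
#' @param a longest dimension, mm
#' @param b width, mm; must satisfy a >= b > 0
#' @return volume in mm^3
#' @examples
#' caliperVolume(10, 6)   # 60 * pi =~ 188.5 mm^3
#' @export
caliperVolume <- function(a, b) {
  if (any(b <= 0)) stop("b must be > 0")
  if (any(a < b)) stop("a must be the longest dimension (a >= b)")
  pi / 6 * a * b^2
}
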