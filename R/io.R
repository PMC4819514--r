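#' @include AllClasses.R
NULL

#' Write a 3D/4D volume as NIfTI-1
#'
#' Axis order (x, y, z\[, t\]); only voxel size is carried in the header
#' (world coordinates beyond pixdim are not used by this pipeline).
#'
#' @param arr numeric array (3D or 4D); NA is written as NaN
#' @param path output path (.nii or .nii.gz)
#' @param voxelSize mm per spatial axis (length 3)
#' @return the path, invisibly
#' @export
writeVolumeNifti <- function(arr, path, voxelSize = c(1, 1, 1)) {
  im <- RNifti::asNifti(arr * 1)   # coerce logical/integer to numeric
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(voxelSize, rep(1, nd - 3))[seq_len(nd)]
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @return numeric array (header discarded except dimensions)
#' @export
readVolumeNifti <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  attributes(a) <- list(dim = dim(a))
  a
}

#' Write a section image set as multi-page TIFF plus mask TIFF
#'
#' Channels are written as consecutive 32-bit float pages of
#' `<stem>_channels.tif` (page order = channel order, recorded in the JSON
#' sidecar); the tumor/necrosis/artifact masks as pages 1-3 of
#' `<stem>_masks.tif`.
#'
#' @param set a [SectionImageSet-class]
#' @param stem output path stem
#' @return named vector of the paths written, invisibly
#' @export
writeSectionTiff <- function(set, stem) {
  chPath <- paste0(stem, "_channels.tif")
  maskPath <- paste0(stem, "_masks.tif")
  tiff::writeTIFF(lapply(set@channels, function(m) m / 255),
                  chPath, bits.per.sample = 32L)
  tiff::writeTIFF(list(set@tumorMask * 1, set@necrosisMask * 1,
                       set@artifactMask * 1), maskPath,
                  bits.per.sample = 32L)
  side <- paste0(stem, "_channels.json")
  jsonlite::write_json(list(channels = names(set@channels),
                            pixelSizeUm = set@pixelSizeUm),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(channels = chPath, masks = maskPath, sidecar = side))
}

#' Read a section image set written by [writeSectionTiff]
#'
#' @param stem the path stem used when writing
#' @return a [SectionImageSet-class]
#' @export
readSectionTiff <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, "_channels.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(stem, "_channels.tif"), all = TRUE)
  channels <- lapply(pages, function(p) p * 255)
  names(channels) <- side$channels
  masks <- tiff::readTIFF(paste0(stem, "_masks.tif"), all = TRUE)
  new("SectionImageSet", channels = channels,
      pixelSizeUm = side$pixelSizeUm,
      tumorMask = masks[[1]] > 0.5, necrosisMask = masks[[2]] > 0.5,
      artifactMask = masks[[3]] > 0.5)
}
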