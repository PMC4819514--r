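#' @include AllClasses.R
NULL

#' Accessors for tumorquant map objects
#'
#' Slot accessors for the parameter-map and labelling classes. Use these
#' instead of direct slot access.
#'
#' @param object a tumorquant S4 object
#' @return the corresponding per-voxel array or scalar
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ktransMap", function(object) standardGeneric("ktransMap"))
#' @rdname accessors
#' @export
setGeneric("veMap", function(object) standardGeneric("veMap"))
#' @rdname accessors
#' @export
setGeneric("vpMap", function(object) standardGeneric("vpMap"))
#' @rdname accessors
#' @export
setGeneric("fitOk", function(object) standardGeneric("fitOk"))
#' @rdname accessors
#' @export
setGeneric("kappaMap", function(object) standardGeneric("kappaMap"))
#' @rdname accessors
#' @export
setGeneric("t1Values", function(object) standardGeneric("t1Values"))
#' @rdname accessors
#' @export
setGeneric("shellIndex", function(object) standardGeneric("shellIndex"))
#' @rdname accessors
#' @export
setGeneric("nShells", function(object) standardGeneric("nShells"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' @rdname accessors
setMethod("ktransMap", "PKParameterMap", function(object) object@ktrans)
#' @rdname accessors
setMethod("veMap", "PKParameterMap", function(object) object@ve)
#' @rdname accessors
setMethod("vpMap", "PKParameterMap", function(object) object@vp)
#' @rdname accessors
setMethod("fitOk", "PKParameterMap", function(object) object@fitOk)
#' @rdname accessors
setMethod("fitOk", "T1Map", function(object) object@fitOk)
#' @rdname accessors
setMethod("fitOk", "FlipAngleMap", function(object) object@fitOk)
#' @rdname accessors
setMethod("kappaMap", "FlipAngleMap", function(object) object@kappa)
#' @rdname accessors
setMethod("t1Values", "T1Map", function(object) object@t1)
#' @rdname accessors
setMethod("shellIndex", "ShellLabeling", function(object) object@shellIndex)
#' @rdname accessors
setMethod("nShells", "ShellLabeling", function(object) object@nShells)
#' @rdname accessors
setMethod("channelNames", "SectionImageSet", function(object) names(object@channels))
#' @rdname accessors
setMethod("getChannel", "SectionImageSet", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no channel named '", name, "'")
  object@channels[[name]]
})

setMethod("show", "PKParameterMap", function(object) {
  d <- dim(object@ktrans)
  nok <- sum(object@fitOk)
  cat("PKParameterMap:", paste(d, collapse = " x "), "voxels;",
      nok, "fit OK\n")
  if (nok > 0)
    cat(sprintf("  median Ktrans (fit OK): %.4f /min; median ve: %.3f; median vp: %.4f\n",
                stats::median(object@ktrans[object@fitOk]),
                stats::median(object@ve[object@fitOk]),
                stats::median(object@vp[object@fitOk])))
})

setMethod("show", "T1Map", function(object) {
  nok <- sum(object@fitOk)
  cat("T1Map:", paste(dim(object@t1), collapse = " x "), "voxels;",
      nok, "fit OK\n")
  if (nok > 0)
    cat(sprintf("  median T1 (fit OK): %.0f ms\n",
                stats::median(object@t1[object@fitOk])))
})

setMethod("show", "FlipAngleMap", function(object) {
  nok <- sum(object@fitOk)
  cat("FlipAngleMap:", paste(dim(object@kappa), collapse = " x "), "voxels;",
      nok, "fit OK\n")
  if (nok > 0)
    cat(sprintf("  median kappa (fit OK): %.4f\n",
                stats::median(object@kappa[object@fitOk])))
})

setMethod("show", "ShellLabeling", function(object) {
  cat("ShellLabeling:", object@nShells, "concentric shells over",
      sum(object@shellIndex > 0L), "voxels (connectivity",
      object@connectivity, ")\n")
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@signal)
  cat("DynamicSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames (", object@acq@nPre, "pre +", object@acq@nPost,
      "post ) at", object@acq@frameInterval, "s/frame\n")
})

setMethod("show", "SectionImageSet", function(object) {
  cat("SectionImageSet:", paste(dim(object@tumorMask), collapse = " x "),
      "px at", object@pixelSizeUm, "um/px; channels:",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  tumor:", sum(object@tumorMask), "px; necrosis:",
      sum(object@necrosisMask), "px; artifact:", sum(object@artifactMask), "px\n")
})

setMethod("show", "AIFModel", function(object) {
  cat(sprintf("AIFModel: Cp(t) = %.2f * (%.2f exp(-%.4f t) + %.2f exp(-%.4f t)) mM (t in min), onset %.1f s\n",
              object@dose, object@a1, object@m1, object@a2, object@m2,
              object@onsetTime))
})
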