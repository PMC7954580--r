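#' @include AllClasses.R
NULL

#' Accessors for glottikym classes
#'
#' Small read-only accessors for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("frameNumbers", function(x) standardGeneric("frameNumbers"))
#' @rdname accessors
#' @export
setMethod("frameNumbers", "FrameStack", function(x) x@frameNumbers)
#' @rdname accessors
#' @export
setMethod("frameNumbers", "Kymogram", function(x) x@frameNumbers)

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname accessors
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Kymogram", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("crossSectionRow", function(x) standardGeneric("crossSectionRow"))
#' @rdname accessors
#' @export
setMethod("crossSectionRow", "Kymogram", function(x) x@crossSectionRow)

#' @rdname accessors
#' @export
setGeneric("vocalizationId", function(x) standardGeneric("vocalizationId"))
#' @rdname accessors
#' @export
setMethod("vocalizationId", "Kymogram", function(x) x@vocalizationId)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureStack", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "GlottalMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("glottisLabel", function(x) standardGeneric("glottisLabel"))
#' @rdname accessors
#' @export
setMethod("glottisLabel", "GlottalMask", function(x) x@glottisLabel)

#' @rdname accessors
#' @export
setGeneric("upperEdge", function(x) standardGeneric("upperEdge"))
#' @rdname accessors
#' @export
setMethod("upperEdge", "EdgePair", function(x) x@upper)
#' @rdname accessors
#' @export
setMethod("upperEdge", "SyntheticTruth", function(x) x@upperEdge)

#' @rdname accessors
#' @export
setGeneric("lowerEdge", function(x) standardGeneric("lowerEdge"))
#' @rdname accessors
#' @export
setMethod("lowerEdge", "EdgePair", function(x) x@lower)
#' @rdname accessors
#' @export
setMethod("lowerEdge", "SyntheticTruth", function(x) x@lowerEdge)

#' @rdname accessors
#' @export
setGeneric("validColumns", function(x) standardGeneric("validColumns"))
#' @rdname accessors
#' @export
setMethod("validColumns", "EdgePair", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("openFlag", function(x) standardGeneric("openFlag"))
#' @rdname accessors
#' @export
setMethod("openFlag", "SyntheticTruth", function(x) x@openFlag)

#' @rdname accessors
#' @export
setMethod("dim", "FrameStack", function(x) dim(x@frames))
#' @rdname accessors
#' @export
setMethod("dim", "Kymogram", function(x) dim(x@pixels))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %dx%d RGB at %g fps (frames %d..%d)\n",
              d[4], d[1], d[2], object@fps,
              min(object@frameNumbers), max(object@frameNumbers)))
})

setMethod("show", "Kymogram", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "Kymogram '%s': %d rows x %d frames, cross-section row %d (frames %d..%d)\n",
    object@vocalizationId, d[1], d[2], object@crossSectionRow,
    min(object@frameNumbers), max(object@frameNumbers)))
})

setMethod("show", "EdgePair", function(object) {
  cat(sprintf("EdgePair: %d columns, %d valid (open) columns\n",
              length(object@upper), sum(object@valid)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d columns, %.1f%% open, f0 %g Hz, seed %d\n",
    length(object@upperEdge), 100 * mean(object@openFlag),
    object@vibration@f0, object@seed))
})

setMethod("show", "GlottalMask", function(object) {
  cat(sprintf("GlottalMask: %dx%d, %d glottal pixels in %d chunks\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              length(object@chunks)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: mode %s, chunk<=%d frames, smooth %d px, Tukey %d px (alpha %.2f), gradient step %d, seed %d\n",
    object@mode, object@chunkMaxFrames, object@smoothingWindow,
    object@tukeyLength, object@tukeyAlpha, object@gradientStep,
    object@masterSeed))
})
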