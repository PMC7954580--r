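#' @import methods
NULL

## ---------------------------------------------------------------------------
## Video substrate
## ---------------------------------------------------------------------------

#' FrameStack: an ordered stack of RGB video frames
#'
#' Holds decoded 8-bit RGB frames as a numeric `H x W x 3 x T` array (values
#' 0--255), the original recording frame numbers (0-based), and the sampling
#' rate. All spatial coordinates in the package are 0-based with the origin at
#' the top-left; frame "x" is the column (left--right) axis.
#'
#' @slot frames numeric array, `H x W x 3 x T`.
#' @slot frameNumbers integer vector of length `T`, strictly increasing.
#' @slot fps frames per second (Hz).
#' @export
setClass("FrameStack",
  slots = c(frames = "array", frameNumbers = "integer", fps = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L || d[3] != 3L)
      return("frames must be an H x W x 3 x T array")
    if (length(object@frameNumbers) != d[4])
      return("frameNumbers length must equal the number of frames")
    if (d[4] > 1L && any(diff(object@frameNumbers) <= 0L))
      return("frameNumbers must be strictly increasing")
    rng <- range(object@frames)
    if (rng[1] < 0 || rng[2] > 255)
      return("channel values must lie in [0, 255]")
    if (length(object@fps) != 1L || object@fps <= 0)
      return("fps must be a positive scalar")
    TRUE
  }
)

#' Construct a FrameStack
#'
#' @param frames `H x W x 3 x T` numeric array (0--255) or a list of
#'   `H x W x 3` arrays.
#' @param frameNumbers original recording indices (0-based); defaults to
#'   `0:(T-1)`.
#' @param fps sampling rate in Hz.
#' @return a [FrameStack-class] object.
#' @export
FrameStack <- function(frames, frameNumbers = NULL, fps = 4000) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    for (i in seq_along(frames))
      if (!identical(dim(frames[[i]]), d))
        stop("frame ", i, " has inconsistent dimensions", call. = FALSE)
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  if (is.null(frameNumbers)) frameNumbers <- seq_len(dim(frames)[4]) - 1L
  new("FrameStack", frames = frames,
      frameNumbers = as.integer(frameNumbers), fps = as.numeric(fps))
}

## ---------------------------------------------------------------------------
## Kymogram and features
## ---------------------------------------------------------------------------

#' Kymogram: a space--time image at one vocal fold cross-section
#'
#' Rows are left--right position within the motion-compensated crop (one row
#' per crop column), columns are time (one per video frame), and the third
#' axis holds the RGB channels. Values are floats in [0, 255]; preprocessing
#' keeps the float representation.
#'
#' @slot pixels numeric `H_k x T x 3` array.
#' @slot crossSectionRow 0-based row of the crop at which the kymogram was cut.
#' @slot frameNumbers integer vector of length `T`, strictly increasing.
#' @slot vocalizationId identifier of the vocalized segment.
#' @export
setClass("Kymogram",
  slots = c(pixels = "array", crossSectionRow = "integer",
            frameNumbers = "integer", vocalizationId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H_k x T x 3 array")
    if (d[1] < 15L)
      return("kymogram height must be >= 15 (Tukey window must fit)")
    if (d[2] < 1L) return("kymogram must have at least one column")
    if (length(object@frameNumbers) != d[2])
      return("frameNumbers length must equal the number of columns")
    if (d[2] > 1L && any(diff(object@frameNumbers) <= 0L))
      return("frameNumbers must be strictly increasing")
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 255)
      return("pixel values must lie in [0, 255]")
    TRUE
  }
)

#' Construct a Kymogram
#'
#' @param pixels `H_k x T x 3` numeric array, values in [0, 255].
#' @param crossSectionRow 0-based crop row of the cross-section.
#' @param frameNumbers original frame numbers (length `T`).
#' @param vocalizationId identifier string.
#' @return a [Kymogram-class] object.
#' @export
Kymogram <- function(pixels, crossSectionRow = 0L, frameNumbers = NULL,
                     vocalizationId = "voc") {
  if (is.null(frameNumbers)) frameNumbers <- seq_len(dim(pixels)[2]) - 1L
  new("Kymogram", pixels = pixels,
      crossSectionRow = as.integer(crossSectionRow),
      frameNumbers = as.integer(frameNumbers),
      vocalizationId = as.character(vocalizationId))
}

#' FeatureStack: per-pixel clustering features
#'
#' Per-chunk min-max normalized features in [0, 1]: normalized red intensity,
#' normalized green intensity, normalized gradient magnitude.
#'
#' @slot values numeric `H_k x T x 3` array in [0, 1], ordered
#'   (red, green, gradient).
#' @slot step gradient step size in pixels.
#' @slot chunks list of `c(start, end)` 1-based column spans over which
#'   normalization was performed.
#' @slot sourceId provenance link to the kymogram's vocalization id.
#' @export
setClass("FeatureStack",
  slots = c(values = "array", step = "integer", chunks = "list",
            sourceId = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[3] != 3L)
      return("values must be an H_k x T x 3 array")
    rng <- range(object@values)
    if (rng[1] < 0 || rng[2] > 1)
      return("feature values must lie in [0, 1]")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Glottis segmentation products
## ---------------------------------------------------------------------------

#' GlottalMask: the segmented glottal region of a kymogram
#'
#' @slot mask logical `H_k x T` matrix, TRUE for glottal pixels.
#' @slot glottisLabel integer vector, the glottis cluster label (1 or 2) per
#'   chunk.
#' @slot chunks list of `c(start, end)` 1-based column spans.
#' @export
setClass("GlottalMask",
  slots = c(mask = "matrix", glottisLabel = "integer", chunks = "list"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@glottisLabel) != length(object@chunks))
      return("one glottis label per chunk required")
    TRUE
  }
)

#' EdgePair: upper and lower glottal edge traces
#'
#' One float row position per kymogram column and side. Columns where no
#' glottal pixel was found (closed phase) carry `valid = FALSE`; after
#' [smoothEdges()] their traces are interpolated but the flags persist.
#'
#' @slot upper numeric row per column (left fold edge).
#' @slot lower numeric row per column (right fold edge).
#' @slot valid logical per column.
#' @export
setClass("EdgePair",
  slots = c(upper = "numeric", lower = "numeric", valid = "logical"),
  validity = function(object) {
    n <- length(object@upper)
    if (length(object@lower) != n || length(object@valid) != n)
      return("upper, lower and valid must have equal length")
    bad <- object@valid & !is.na(object@upper) & !is.na(object@lower) &
      object@upper > object@lower + 1e-9
    if (any(bad)) return("upper must not exceed lower on valid columns")
    TRUE
  }
)

#' Construct an EdgePair
#' @param upper,lower numeric row traces.
#' @param valid logical per column; default all TRUE.
#' @return an [EdgePair-class] object.
#' @export
EdgePair <- function(upper, lower, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(upper))
  new("EdgePair", upper = as.numeric(upper), lower = as.numeric(lower),
      valid = as.logical(valid))
}

## ---------------------------------------------------------------------------
## Synthetic generator models
## ---------------------------------------------------------------------------

#' VibrationModel: kinematics of the synthetic glottal gap
#'
#' The half-gap is a thresholded, envelope-modulated sinusoid:
#' `g(t) = maxHalfWidth * env(t) * max(0, sin(2 pi f0 t / fps + phase) - s) /
#' (1 - s)` where the threshold `s` is found by root-finding so that the
#' fraction of each cycle with `g = 0` equals `closedQuotient`, and `env`
#' ramps linearly 0 to 1 over `onsetFrames` and back to 0 over the last
#' `offsetFrames`.
#'
#' @slot f0 oscillation frequency (Hz).
#' @slot fps sampling rate (Hz).
#' @slot nFrames number of frames (kymogram columns).
#' @slot centerRow glottal midline row (pixels, 0-based).
#' @slot maxHalfWidth maximum half gap (pixels).
#' @slot onsetFrames,offsetFrames envelope ramp lengths (frames).
#' @slot closedQuotient fraction of each cycle with zero gap, in [0, 1).
#' @slot phase phase offset (radians).
#' @export
setClass("VibrationModel",
  slots = c(f0 = "numeric", fps = "numeric", nFrames = "integer",
            centerRow = "numeric", maxHalfWidth = "numeric",
            onsetFrames = "integer", offsetFrames = "integer",
            closedQuotient = "numeric", phase = "numeric"),
  validity = function(object) {
    if (object@f0 <= 0 || object@f0 >= object@fps / 2)
      return("need 0 < f0 < fps/2")
    if (object@maxHalfWidth < 0) return("maxHalfWidth must be >= 0")
    if (object@closedQuotient < 0 || object@closedQuotient >= 1)
      return("closedQuotient must lie in [0, 1)")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    TRUE
  }
)

#' Construct a VibrationModel
#'
#' Defaults describe a vocally normal adult female voice sampled by the
#' package's nominal recording configuration: 4000 fps, f0 = 200 Hz, a
#' 600-frame (150 ms) vocalization with 60-frame (15 ms) onset/offset ramps,
#' midline at row 20 of a 41-row kymogram, 6-pixel maximum half gap and a
#' closed quotient of 0.25.
#'
#' @param f0,fps,nFrames,centerRow,maxHalfWidth,onsetFrames,offsetFrames,closedQuotient,phase
#'   see [VibrationModel-class].
#' @return a [VibrationModel-class] object.
#' @export
VibrationModel <- function(f0 = 200, fps = 4000, nFrames = 600L,
                           centerRow = 20, maxHalfWidth = 6,
                           onsetFrames = 60L, offsetFrames = 60L,
                           closedQuotient = 0.25, phase = 0) {
  new("VibrationModel", f0 = f0, fps = fps, nFrames = as.integer(nFrames),
      centerRow = centerRow, maxHalfWidth = maxHalfWidth,
      onsetFrames = as.integer(onsetFrames),
      offsetFrames = as.integer(offsetFrames),
      closedQuotient = closedQuotient, phase = phase)
}

#' AppearanceModel: photometry of the synthetic kymogram
#'
#' @slot tissueLevel mean tissue intensity per RGB channel (0--255).
#' @slot glottisLevel mean glottal intensity per RGB channel; channel-wise
#'   darker than tissue.
#' @slot illumGradient multiplicative row-wise illumination falloff
#'   coefficient (0 = flat; the bottom row is scaled by `1 - illumGradient`).
#' @slot noiseSd per-channel Gaussian noise SD; blue noisiest
#'   (`blue >= red >= green`).
#' @slot saturationPatchRate expected 3x5 near-saturated patches per 1000
#'   columns.
#' @slot dimming global multiplicative factor in (0, 1].
#' @export
setClass("AppearanceModel",
  slots = c(tissueLevel = "numeric", glottisLevel = "numeric",
            illumGradient = "numeric", noiseSd = "numeric",
            saturationPatchRate = "numeric", dimming = "numeric"),
  validity = function(object) {
    if (length(object@tissueLevel) != 3L || length(object@glottisLevel) != 3L)
      return("tissueLevel and glottisLevel must have 3 channels")
    if (any(object@glottisLevel >= object@tissueLevel))
      return("glottisLevel must be channel-wise darker than tissueLevel")
    if (length(object@noiseSd) != 3L) return("noiseSd must have 3 channels")
    if (object@noiseSd[3] < object@noiseSd[2])
      return("blue noise SD must be >= green noise SD")
    if (object@dimming <= 0 || object@dimming > 1)
      return("dimming must lie in (0, 1]")
    TRUE
  }
)

#' Construct an AppearanceModel
#'
#' Defaults emulate color endoscopic tissue under xenon light: warm bright
#' tissue (200, 160, 140), a dark glottal gap (35, 30, 40), mild row-wise
#' illumination falloff, and sensor noise dominated by the blue channel
#' (SD 6, 4, 12).
#'
#' @param tissueLevel,glottisLevel,illumGradient,noiseSd,saturationPatchRate,dimming
#'   see [AppearanceModel-class].
#' @return an [AppearanceModel-class] object.
#' @export
AppearanceModel <- function(tissueLevel = c(200, 160, 140),
                            glottisLevel = c(35, 30, 40),
                            illumGradient = 0.15,
                            noiseSd = c(6, 4, 12),
                            saturationPatchRate = 5,
                            dimming = 1) {
  new("AppearanceModel", tissueLevel = as.numeric(tissueLevel),
      glottisLevel = as.numeric(glottisLevel),
      illumGradient = illumGradient, noiseSd = as.numeric(noiseSd),
      saturationPatchRate = saturationPatchRate, dimming = dimming)
}

#' SyntheticTruth: generator parameters plus exact ground-truth edges
#'
#' @slot upperEdge,lowerEdge float ground-truth row per column.
#' @slot openFlag logical per column; TRUE where the gap is open.
#' @slot vibration the [VibrationModel-class] used.
#' @slot appearance the [AppearanceModel-class] used.
#' @slot seed integer seed that drives all rendering noise.
#' @export
setClass("SyntheticTruth",
  slots = c(upperEdge = "numeric", lowerEdge = "numeric",
            openFlag = "logical", vibration = "VibrationModel",
            appearance = "AppearanceModel", seed = "integer"),
  validity = function(object) {
    n <- length(object@upperEdge)
    if (length(object@lowerEdge) != n || length(object@openFlag) != n)
      return("edge and flag vectors must have equal length")
    if (any(object@openFlag & object@upperEdge >= object@lowerEdge))
      return("open columns require upperEdge < lowerEdge")
    cl <- !object@openFlag
    if (any(abs(object@upperEdge[cl] - object@vibration@centerRow) > 1e-9) ||
        any(abs(object@lowerEdge[cl] - object@vibration@centerRow) > 1e-9))
      return("closed columns must have both edges at centerRow")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Snake and pipeline configuration
## ---------------------------------------------------------------------------

#' SnakeParams: active-contour parameters
#'
#' @slot alpha elasticity (first-difference) weight.
#' @slot beta rigidity (second-difference) weight.
#' @slot gamma time-step weight (> 0).
#' @slot sigma Gaussian pre-smoothing scale (pixels) for the external field.
#' @slot maxIters iteration cap.
#' @slot tol mean per-node movement threshold (pixels).
#' @export
setClass("SnakeParams",
  slots = c(alpha = "numeric", beta = "numeric", gamma = "numeric",
            sigma = "numeric", maxIters = "integer", tol = "numeric"),
  validity = function(object) {
    if (object@alpha < 0 || object@beta < 0) return("alpha, beta must be >= 0")
    if (object@gamma <= 0) return("gamma must be > 0")
    if (object@tol <= 0) return("tol must be > 0")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  }
)

#' Construct SnakeParams
#' @param alpha,beta,gamma,sigma,maxIters,tol see [SnakeParams-class].
#' @return a [SnakeParams-class] object.
#' @export
SnakeParams <- function(alpha = 0.02, beta = 0.1, gamma = 1.0, sigma = 1.5,
                        maxIters = 200L, tol = 0.01) {
  new("SnakeParams", alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
      maxIters = as.integer(maxIters), tol = tol)
}

#' PipelineConfig: constants and mode of the segmentation pipeline
#'
#' Numeric defaults are the method's operating constants: chunks of at most
#' 50 frames, a 5-pixel moving-average smoothing window, a 15-pixel Tukey
#' window (alpha 0.25), and an 8-pixel gradient step.
#'
#' @slot crossSectionRows integer vector of 0-based crop rows, or `NA` for
#'   automatic placement (`nAutoSections` rows evenly spaced over the middle
#'   60 percent of the crop height).
#' @slot nAutoSections number of automatic cross-sections (default 5).
#' @slot chunkMaxFrames maximum chunk width in frames.
#' @slot smoothingWindow moving-average window (pixels, odd).
#' @slot tukeyLength Tukey window length (pixels, odd).
#' @slot tukeyAlpha Tukey taper fraction.
#' @slot gradientStep gradient feature step (pixels).
#' @slot mode one of `"hybrid"`, `"acm_only"`, `"cluster_only"`.
#' @slot snake a [SnakeParams-class] object.
#' @slot masterSeed integer master seed for all stochastic stages.
#' @export
setClass("PipelineConfig",
  slots = c(crossSectionRows = "integer", nAutoSections = "integer",
            chunkMaxFrames = "integer", smoothingWindow = "integer",
            tukeyLength = "integer", tukeyAlpha = "numeric",
            gradientStep = "integer", mode = "character",
            snake = "SnakeParams", masterSeed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("hybrid", "acm_only", "cluster_only"))
      return("mode must be hybrid, acm_only or cluster_only")
    if (object@chunkMaxFrames < 1L) return("chunkMaxFrames must be >= 1")
    if (object@smoothingWindow < 1L || object@smoothingWindow %% 2L == 0L)
      return("smoothingWindow must be odd and >= 1")
    if (object@tukeyLength < 3L || object@tukeyLength %% 2L == 0L)
      return("tukeyLength must be odd and >= 3")
    if (object@gradientStep < 1L) return("gradientStep must be >= 1")
    TRUE
  }
)

#' Construct a PipelineConfig
#' @param crossSectionRows integer rows or `NA` for automatic placement.
#' @param nAutoSections,chunkMaxFrames,smoothingWindow,tukeyLength,tukeyAlpha,gradientStep,mode,snake,masterSeed
#'   see [PipelineConfig-class].
#' @return a [PipelineConfig-class] object.
#' @export
PipelineConfig <- function(crossSectionRows = NA_integer_,
                           nAutoSections = 5L, chunkMaxFrames = 50L,
                           smoothingWindow = 5L, tukeyLength = 15L,
                           tukeyAlpha = 0.25, gradientStep = 8L,
                           mode = "hybrid", snake = SnakeParams(),
                           masterSeed = 1L) {
  new("PipelineConfig", crossSectionRows = as.integer(crossSectionRows),
      nAutoSections = as.integer(nAutoSections),
      chunkMaxFrames = as.integer(chunkMaxFrames),
      smoothingWindow = as.integer(smoothingWindow),
      tukeyLength = as.integer(tukeyLength), tukeyAlpha = tukeyAlpha,
      gradientStep = as.integer(gradientStep), mode = mode, snake = snake,
      masterSeed = as.integer(masterSeed))
}
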