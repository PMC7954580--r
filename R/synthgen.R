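#' @include AllClasses.R utils.R
NULL

## Fraction of a full cycle during which the rectified, thresholded sinusoid
## max(0, sin(theta) - s) is zero. The sojourn time of sin(theta) <= s over
## one period gives 1/2 + asin(s)/pi; the threshold for a requested closed
## quotient is found by root-finding on this monotone function rather than
## assumed in closed form.
closedFractionOfThreshold <- function(s) 0.5 + asin(s) / pi

solveClosedThreshold <- function(closedQuotient) {
  if (closedQuotient <= 0) return(-1)
  uniroot(function(s) closedFractionOfThreshold(s) - closedQuotient,
          lower = -1, upper = 1 - 1e-12, tol = 1e-12)$root
}

#' Ground-truth glottal edge waveform for a vibration model
#'
#' Builds the half-gap `g(t) = maxHalfWidth * env(t) *
#' max(0, sin(2 pi f0 t/fps + phase) - s) / (1 - s)`, where the threshold `s`
#' is solved numerically so the closed fraction of each cycle equals
#' `closedQuotient`, and `env` ramps linearly 0 to 1 over `onsetFrames` and
#' back to 0 over the final `offsetFrames`. Edges are
#' `centerRow -/+ g(t)`.
#'
#' @param vm a [VibrationModel-class].
#' @param appearance an [AppearanceModel-class] stored with the truth
#'   (rendering uses it); defaults to [AppearanceModel()].
#' @param seed integer seed stored with the truth and used by the renderers.
#' @return a [SyntheticTruth-class].
#' @export
edgeWaveform <- function(vm, appearance = AppearanceModel(), seed = 1L) {
  n <- vm@nFrames
  tIdx <- seq_len(n) - 1
  s <- solveClosedThreshold(vm@closedQuotient)
  osc <- pmax(0, sin(2 * pi * vm@f0 * tIdx / vm@fps + vm@phase) - s) / (1 - s)
  env <- rep(1, n)
  if (vm@onsetFrames > 0L) {
    m <- min(vm@onsetFrames, n)
    env[seq_len(m)] <- pmin(env[seq_len(m)], (seq_len(m) - 1) /
                              max(1L, vm@onsetFrames))
  }
  if (vm@offsetFrames > 0L) {
    m <- min(vm@offsetFrames, n)
    idx <- n - seq_len(m) + 1L
    env[idx] <- pmin(env[idx], (seq_len(m) - 1) / max(1L, vm@offsetFrames))
  }
  g <- vm@maxHalfWidth * env * osc
  g[g < 1e-9] <- 0            # half-gaps below numerical resolution are closed
  new("SyntheticTruth",
      upperEdge = vm@centerRow - g, lowerEdge = vm@centerRow + g,
      openFlag = g > 0, vibration = vm, appearance = appearance,
      seed = as.integer(seed))
}

## Noiseless per-column profile: H x 3 values for one column with edges
## (u, l), including linear blending of the boundary pixels by the subpixel
## coverage of the glottal interval (u, l) over each pixel's [r-0.5, r+0.5]
## footprint, the row-wise illumination falloff and the global dimming.
columnProfile <- function(u, l, open, app, height) {
  r <- seq_len(height) - 1
  cov <- if (open) clamp(pmin(r + 0.5, l) - pmax(r - 0.5, u), 0, 1) else
    rep(0, height)
  illum <- (1 - app@illumGradient * r / max(1, height - 1)) * app@dimming
  out <- matrix(0, height, 3)
  for (ch in 1:3) {
    base <- app@tissueLevel[ch] +
      cov * (app@glottisLevel[ch] - app@tissueLevel[ch])
    out[, ch] <- base * illum
  }
  out
}

## Poisson-placed 3x5 near-saturated patches; returns the image with patches
## burned in (value 255 on all channels). Patch count ~ Poisson(rate/1000 * T).
addSaturationPatches <- function(img, rate) {
  H <- dim(img)[1]; T <- dim(img)[2]
  nPatch <- rpois(1, rate * T / 1000)
  if (nPatch > 0) {
    for (i in seq_len(nPatch)) {
      r0 <- sample.int(max(1L, H - 2L), 1)
      c0 <- sample.int(max(1L, T - 4L), 1)
      rows <- r0:min(H, r0 + 2L); cols <- c0:min(T, c0 + 4L)
      img[rows, cols, ] <- 255
    }
  }
  img
}

#' Render a synthetic kymogram from ground truth
#'
#' Pixels strictly inside the glottal gap take the glottis level, the rest
#' the tissue level, with boundary pixels linearly blended by subpixel edge
#' coverage; each column is modulated by the row-wise illumination falloff
#' and global dimming, then per-channel Gaussian noise and Poisson-placed
#' 3x5 saturation patches (value 255) are added and values are clipped to
#' [0, 255]. Rendering is a pure function of the truth's seed.
#'
#' @param truth a [SyntheticTruth-class].
#' @param height kymogram height in pixels (rows); the edges must lie within
#'   `[0, height)`.
#' @param vocalizationId identifier recorded in the kymogram.
#' @return a [Kymogram-class].
#' @export
renderKymogram <- function(truth, height = 41L, vocalizationId = "synthetic") {
  if (any(truth@upperEdge < 0) || any(truth@lowerEdge > height - 1))
    stop("ground-truth edges fall outside the image height", call. = FALSE)
  app <- truth@appearance
  n <- length(truth@upperEdge)
  img <- array(0, dim = c(height, n, 3))
  for (tcol in seq_len(n)) {
    img[, tcol, ] <- columnProfile(truth@upperEdge[tcol],
                                   truth@lowerEdge[tcol],
                                   truth@openFlag[tcol], app, height)
  }
  img <- withSeed(truth@seed, {
    for (ch in 1:3) {
      if (app@noiseSd[ch] > 0)
        img[, , ch] <- img[, , ch] +
          matrix(rnorm(height * n, sd = app@noiseSd[ch]), height, n)
    }
    if (app@saturationPatchRate > 0)
      img <- addSaturationPatches(img, app@saturationPatchRate)
    img
  })
  Kymogram(clamp(img, 0, 255), crossSectionRow = 0L,
           vocalizationId = vocalizationId)
}

#' Render a synthetic frame stack whose kymograms reproduce the truth
#'
#' Builds full video frames containing a moving crop window; within the crop,
#' the left--right axis (crop columns) carries the glottal profile so that
#' [extractKymogram()] at `crossSectionRows[1]` reproduces
#' [renderKymogram()] exactly in the noiseless case. Edges may tilt linearly
#' along the anteroposterior axis (`edgeSlope` pixels of midline shift per
#' crop row). Crop windows can be jittered by up to `jitterPx` pixels per
#' frame to exercise registration; the scene moves with the window.
#'
#' @param truth a [SyntheticTruth-class].
#' @param frameShape `c(H, W)` of the full frames.
#' @param cropShape `c(height, width)` of the crop window; `width` is the
#'   kymogram height.
#' @param crossSectionRows 0-based crop rows at which kymograms will be cut;
#'   the first is the reference row for the truth.
#' @param origin `c(top, left)` 0-based base position of the crop window.
#' @param edgeSlope midline shift per crop row (pixels), default 0.
#' @param jitterPx integer window jitter amplitude (pixels), default 0.
#' @param vocalizationId identifier.
#' @return list with `stack` ([FrameStack-class]) and `windows`
#'   (crop-window data.frame).
#' @export
renderFrameStack <- function(truth, frameShape = c(64L, 64L),
                             cropShape = c(11L, 41L),
                             crossSectionRows = 5L,
                             origin = c(20L, 10L), edgeSlope = 0,
                             jitterPx = 0L,
                             vocalizationId = "synthetic") {
  app <- truth@appearance
  n <- length(truth@upperEdge)
  ch <- cropShape[1]; cw <- cropShape[2]
  if (any(crossSectionRows < 0L | crossSectionRows >= ch))
    stop("crossSectionRows must lie within the crop height", call. = FALSE)
  if (any(truth@upperEdge < 0) || any(truth@lowerEdge > cw - 1))
    stop("ground-truth edges fall outside the crop width", call. = FALSE)
  refRow <- crossSectionRows[1]

  seeds <- deriveSeeds(truth@seed, 2L)
  jit <- if (jitterPx > 0L)
    withSeed(seeds[1], matrix(sample(seq.int(-jitterPx, jitterPx),
                                     2L * n, replace = TRUE), n, 2L))
  else matrix(0L, n, 2L)

  H <- frameShape[1]; W <- frameShape[2]
  bgIllum <- (1 - app@illumGradient * (seq_len(W) - 1) / max(1, W - 1)) *
    app@dimming
  frames <- array(0, dim = c(H, W, 3L, n))
  windows <- data.frame(frame_number = seq_len(n) - 1L,
                        top = origin[1] + jit[, 1],
                        left = origin[2] + jit[, 2],
                        height = ch, width = cw)
  if (any(windows$top < 0L) || any(windows$left < 0L) ||
      any(windows$top + ch > H) || any(windows$left + cw > W))
    stop("crop window (with jitter) exceeds the frame bounds", call. = FALSE)

  for (tcol in seq_len(n)) {
    fr <- array(0, dim = c(H, W, 3L))
    for (chn in 1:3)
      fr[, , chn] <- matrix(app@tissueLevel[chn] * bgIllum, H, W,
                            byrow = TRUE)
    top <- windows$top[tcol]; left <- windows$left[tcol]
    for (r in seq_len(ch)) {
      shift <- edgeSlope * ((r - 1) - refRow)
      prof <- columnProfile(truth@upperEdge[tcol] + shift,
                            truth@lowerEdge[tcol] + shift,
                            truth@openFlag[tcol], app, cw)
      fr[top + r, (left + 1):(left + cw), ] <- prof
    }
    frames[, , , tcol] <- fr
  }
  frames <- withSeed(seeds[2], {
    for (chn in 1:3) {
      if (app@noiseSd[chn] > 0)
        frames[, , chn, ] <- frames[, , chn, ] +
          array(rnorm(H * W * n, sd = app@noiseSd[chn]), dim = c(H, W, n))
    }
    frames
  })
  list(stack = FrameStack(clamp(frames, 0, 255), fps = truth@vibration@fps),
       windows = windows)
}

#' Appearance model for a named quality tier
#'
#' Two tiers mirror the contrast between decent-quality and challenging
#' (dim, noisy) kymograms: `"decent"` is the default appearance;
#' `"challenging"` dims the scene to 0.35, doubles the per-channel noise and
#' quadruples the saturation-patch rate.
#'
#' @param tier `"decent"` or `"challenging"`.
#' @return an [AppearanceModel-class].
#' @export
appearanceTier <- function(tier = c("decent", "challenging")) {
  tier <- match.arg(tier)
  base <- AppearanceModel()
  if (tier == "decent") return(base)
  AppearanceModel(tissueLevel = base@tissueLevel,
                  glottisLevel = base@glottisLevel,
                  illumGradient = base@illumGradient,
                  noiseSd = base@noiseSd * 2,
                  saturationPatchRate = base@saturationPatchRate * 4,
                  dimming = 0.35)
}

#' Generate one synthetic vocalization (truth + kymogram)
#'
#' Convenience wrapper: default vibration model, tiered appearance, seeded
#' rendering.
#'
#' @param seed integer seed.
#' @param tier `"decent"` or `"challenging"`.
#' @param vm optional [VibrationModel-class]; default [VibrationModel()].
#' @param height kymogram height.
#' @param vocalizationId identifier.
#' @return list with `truth` ([SyntheticTruth-class]) and `kymogram`
#'   ([Kymogram-class]).
#' @export
syntheticVocalization <- function(seed, tier = "decent",
                                  vm = VibrationModel(), height = 41L,
                                  vocalizationId = sprintf("voc%05d", seed)) {
  truth <- edgeWaveform(vm, appearance = appearanceTier(tier), seed = seed)
  list(truth = truth,
       kymogram = renderKymogram(truth, height = height,
                                 vocalizationId = vocalizationId))
}

#' Serialize a SyntheticTruth to JSON
#' @param truth a [SyntheticTruth-class].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeTruthJSON <- function(truth, path) {
  vm <- truth@vibration; app <- truth@appearance
  obj <- list(
    upper_edge = truth@upperEdge, lower_edge = truth@lowerEdge,
    open_flag = truth@openFlag, seed = truth@seed,
    vibration = list(f0 = vm@f0, fps = vm@fps, n_frames = vm@nFrames,
                     center_row = vm@centerRow,
                     max_half_width = vm@maxHalfWidth,
                     onset_frames = vm@onsetFrames,
                     offset_frames = vm@offsetFrames,
                     closed_quotient = vm@closedQuotient, phase = vm@phase),
    appearance = list(tissue_level = app@tissueLevel,
                      glottis_level = app@glottisLevel,
                      illum_gradient = app@illumGradient,
                      noise_sd = app@noiseSd,
                      saturation_patch_rate = app@saturationPatchRate,
                      dimming = app@dimming))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SyntheticTruth from JSON written by [writeTruthJSON()]
#' @param path JSON path.
#' @return a [SyntheticTruth-class].
#' @export
readTruthJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  vm <- VibrationModel(f0 = o$vibration$f0, fps = o$vibration$fps,
                       nFrames = o$vibration$n_frames,
                       centerRow = o$vibration$center_row,
                       maxHalfWidth = o$vibration$max_half_width,
                       onsetFrames = o$vibration$onset_frames,
                       offsetFrames = o$vibration$offset_frames,
                       closedQuotient = o$vibration$closed_quotient,
                       phase = o$vibration$phase)
  app <- AppearanceModel(tissueLevel = o$appearance$tissue_level,
                         glottisLevel = o$appearance$glottis_level,
                         illumGradient = o$appearance$illum_gradient,
                         noiseSd = o$appearance$noise_sd,
                         saturationPatchRate =
                           o$appearance$saturation_patch_rate,
                         dimming = o$appearance$dimming)
  new("SyntheticTruth", upperEdge = o$upper_edge, lowerEdge = o$lower_edge,
      openFlag = o$open_flag, vibration = vm, appearance = app,
      seed = as.integer(o$seed))
}
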