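# Shared fixtures: everything is generated in code at test time.

# a flat-valued kymogram (H x T, one value per channel)
flatKymogram <- function(H = 15L, T = 10L, values = c(128, 128, 128)) {
  px <- array(0, dim = c(H, T, 3L))
  for (ch in 1:3) px[, , ch] <- values[ch]
  Kymogram(px)
}

# a seeded random-valued kymogram
randomKymogram <- function(H = 21L, T = 30L, seed = 1L) {
  set.seed(seed)
  Kymogram(array(runif(H * T * 3, 0, 255), dim = c(H, T, 3L)))
}

# noiseless appearance (no noise, no patches, flat illumination by default)
noiselessAppearance <- function(illumGradient = 0, dimming = 1) {
  AppearanceModel(noiseSd = c(0, 0, 0), saturationPatchRate = 0,
                  illumGradient = illumGradient, dimming = dimming)
}

# a noiseless synthetic vocalization used across modules
noiselessVocalization <- function(seed = 7L, vm = VibrationModel(),
                                  illumGradient = 0) {
  truth <- edgeWaveform(vm, appearance = noiselessAppearance(illumGradient),
                        seed = seed)
  list(truth = truth, kymogram = renderKymogram(truth))
}

# brute-force minimum-SSE 2-partition of <= 12 points (enumeration oracle)
bruteForceTwoPartition <- function(points) {
  N <- nrow(points)
  bestSSE <- Inf; bestAssign <- NULL
  for (code in 1:(2^(N - 1) - 1)) {     # point 1 fixed in group 1
    assign <- c(1L, as.integer(intToBits(code))[seq_len(N - 1)] + 1L)
    sse <- 0
    for (g in 1:2) {
      p <- points[assign == g, , drop = FALSE]
      if (nrow(p) == 0L) { sse <- Inf; break }
      sse <- sse + sum(sweep(p, 2, colMeans(p), "-")^2)
    }
    if (sse < bestSSE) { bestSSE <- sse; bestAssign <- assign }
  }
  list(assign = bestAssign, sse = bestSSE)
}

# do two 2-class labelings define the same partition (up to label swap)?
samePartition <- function(a, b) {
  all(a == b) || all(a == (3L - b))
}
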