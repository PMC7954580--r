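# glottikym

Automated detection of the vibrating vocal fold edges in **high-speed
videoendoscopy (HSV)** recordings of connected speech.

HSV cameras record the larynx at ~4000 fps; quantifying vocal fold vibration
(the core of objective voice assessment) requires locating the edges of both
folds in every frame — far too much data for manual annotation, and
connected-speech recordings lack the labels supervised segmenters need.
`glottikym` implements an unsupervised *hybrid* method operating on
**kymograms** (space–time images cut at cross-sections of the folds: rows =
left–right position, columns = time), where the glottal gap is a dark
oscillating band between two bright tissue edges:

1. **Chunked two-class k-means.** Each kymogram is split into chunks of at
   most 50 frames; within each chunk every pixel is described by three
   features — red intensity, green intensity, and the step-8 gradient
   magnitude of the green channel (blue is too noisy on color HSV sensors) —
   min–max normalized per chunk, and partitioned by k-means (k-means++
   seeding, Euclidean distance *d* = ‖I(x, y) − c_k‖, centroids updated as
   member means, 5 restarts).
2. **Glottis identification.** The glottal midline is the first moment of
   inertia of the inverted green channel,
   M₁ = Σ (255 − G(x, y))·y / Σ (255 − G(x, y)); the majority cluster label
   within ±12 px of it is tissue, the other is the glottis; glottis-labelled
   pixels within ±7 px seed an 8-connected flood fill that grows the glottal
   mask (rejecting disconnected bright-patch debris).
3. **Active-contour refinement.** The mask's upper/lower edge traces,
   spline-smoothed, initialize two coupled open snakes (one node per column,
   elasticity α + rigidity β internal energy, semi-implicit update
   y⁺ = (A + γI)⁻¹(γy − f_ext), external field −|∇(G_σ∗green)|²) that settle
   on the exact edges. Cluster initialization is what makes the snake robust
   on dim, noisy recordings where an uninformed snake fails.
4. **Registration** maps detected kymogram edges back to video-frame
   coordinates through the per-frame motion-compensation crop windows.

Because clinical HSV is not distributable, the package ships a **synthetic
kymogram/frame-stack generator** with exact ground-truth edges (oscillating
gap with onset/offset envelopes and closed phases, illumination falloff,
channel-dependent noise, saturation patches, dim variants) that makes the
whole pipeline testable, plus a validation suite that scores detected edges
against that truth.

## Worked example

```r
library(glottikym)

## one synthetic vocalization (150 ms at 4000 fps, f0 = 200 Hz) + ground truth
voc <- syntheticVocalization(seed = 42L, tier = "decent")
voc$kymogram
#> Kymogram 'voc00042': 41 rows x 600 frames, cross-section row 0 (frames 0..599)

## hybrid segmentation
res <- runKymogram(voc$kymogram, PipelineConfig(masterSeed = 42L))
round(res$momentLine, 2)      # glottal midline (row)
#> 20.68
res$iterations                # snake iterations to convergence
#> 23

## score against the generator's exact edges (open-phase columns only)
scoreVocalization(res$edges, voc$truth)
#> $medianAbsError  0.307      # pixels
#> $fracWithin1px   0.956
#> $success         TRUE       # median error within one pixel
```

The median detected edge sits 0.31 px from the true edge; the vocalization
meets the one-pixel success criterion. A small validation suite comparing
the hybrid method with a flat-initialized active contour (`acm_only`):

```r
runValidationSuite(n = 4, tierMix = 0.5, masterSeed = 1)
#> EvalReport: 8 vocalization runs, master seed 1
#>      mode        tier n successRate medianError totalIterations
#>  acm_only         all 4         0.5   1.7891448             526
#>    hybrid         all 4         1.0   0.3535090              82
#>  acm_only      decent 2         1.0   0.3307486             341
#>    hybrid      decent 2         1.0   0.2966015              40
#>  acm_only challenging 2         0.0   3.3488365             185
#>    hybrid challenging 2         1.0   0.4493706              42
```

On challenging (dim, noisy) kymograms the flat-initialized contour fails
where the hybrid still localizes the edges — at a fraction of the snake
iterations, since it starts next to the answer.

Real recordings enter as an uncompressed 24-bit RGB AVI or a numbered
PNG/TIFF sequence plus a crop-window CSV
(`frame_number,top,left,height,width`) from upstream motion compensation:

```r
stack   <- readFrameStack("recording.avi", frameRange = c(32709, 35061))
windows <- readCropWindows("windows.csv", frameDim = dim(stack)[1:2])
out     <- runVocalization(stack, windows, PipelineConfig(masterSeed = 1L))
writeEdgeTable(out$edgeTable, "edges.csv")
```

A thin CLI wraps the same functions
(`inst/cli/glottikym synth|run|validate|eval`).

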