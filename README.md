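# motiflow

Quantitative analysis of **intracellular motility** from time-lapse
microscopy of a single, already-segmented cell. `motiflow` estimates dense
optical flow with a variational model whose smoothness term adapts between
total-variation (L1) and quadratic (L2, Horn–Schunck) regularization,
summarizes each flow field as a histogram of oriented optical flow (HOOF),
and grades videos into motility classes from the distances between
successive histograms.

For whom: cell biologists and image analysts who have cropped, segmented
single-cell clips (phase contrast or similar) and want per-video motility
descriptors that can be visualized, embedded, and classified — plus a fully
synthetic benchmark with ground-truth motion to validate every stage.

## The model

For consecutive frames the displacement field **u** = (u, v) minimizes

    E(u, v) = ∫ ½ (Iₓu + I_y v + Iₜ)² + (α/p) (|∇u|ᵖ + |∇v|ᵖ) dΩ,

with a per-pixel exponent

    p(x, y) = 1 + 1 / (1 + |∇(G_σ ∗ I)|²)  ∈ (1, 2].

Near intensity edges (large smoothed gradient) p → 1: the regularizer is
total variation and preserves motion discontinuities at the cell border.
In flat regions p → 2: quadratic regularization recovers smooth interior
motion. The solver iterates diagonally semi-implicit gradient-descent
steps (stable for any step size, same fixed points as the Euler–Lagrange
equations) and blends the TV and quadratic updates per pixel with convex
weights (2 − p) and (p − 1). The per-iteration kernel is compiled (Rcpp).

Downstream, each flow field is reduced to a 16-bin orientation histogram
(magnitude-weighted, normalized), and a video's **motility feature
vector** is the sequence of Euclidean distances between successive
histograms. Cohorts of feature vectors are embedded by classical MDS and
classified with a linear SVM.

## Worked example

Generate a synthetic cell video with known internal motion, solve the
flow, and inspect the recovered motion and its descriptors:

```r
library(motiflow)

spec <- synthetic_spec(motion_model = "translation",
                       motion_magnitude = 0.5, noise_sd = 0,
                       n_frames = 2, seed = 3)
vid <- generate_video(spec)

flow <- solve_flow(vid$seq, 1,
                   solver_config(mode = "adaptive", max_iter = 3000,
                                 tol = 1e-7))
#> Warning: flow solve did not reach tol = 1e-07 within 3000 iterations; ...
flow
#> <flow_field> 64 x 64, |mean| = 0.1091, max |.| = 0.5561 px/frame

gt  <- vid$flows[[1]]
epe <- sqrt((flow$u - gt$u)^2 + (flow$v - gt$v)^2)
mean(epe[vid$core])
#> [1] 0.06147468
```

The mean endpoint error over the cell core is ≈ 0.06 px for a true
displacement of 0.5 px/frame. (The warning reports that the relative-change
stopping rule was not met within the iteration cap; the slowly diffusing
background halo keeps the metric above tight tolerances long after the
cell-interior flow has stabilized, as the endpoint error shows.) Velocity
and histogram descriptors:

```r
mean_velocity(flow)
#> <velocity_stats> mean 0.1091 px/frame over 4096 px (threshold 0.0001)

h <- hoof(flow)          # 16-bin orientation histogram, sums to 1
fv <- feature_vector(vid$seq)   # successive-HOOF distances per video
```

End-to-end motility grading on the built-in synthetic cohort (3 classes ×
40 videos, magnitudes 0.2 / 0.6 / 1.2 px/frame):

```r
coh <- generate_cohort(n_per_class = 40, seed = 1)
fvs <- lapply(coh$videos, function(v) feature_vector(v$seq))
cf  <- cohort_features(fvs, coh$labels)
classify_cohort(cf, seed = 1)
#> <grading_result> accuracy 91.7% on 60 held-out videos (60 trained)
#>           predicted
#> truth      slight moderate dramatic
#>   slight       19        1        0
#>   moderate      0       18        2
#>   dramatic      0        2       18
```

Flow fields can be exchanged in Middlebury `.flo` format (`write_flo()` /
`read_flo()`) and rendered with the flow color wheel or a blue-to-red
speed map (`color_code()`, `plot_flow()`). A thin command-line front end
over these functions is installed at `inst/cli/motiflow`.

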