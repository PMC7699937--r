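# drtb — stomatal segmentation from spacing statistics

Stomata are the pores through which a leaf breathes: CO₂ in, water vapor
out. Counting and mapping them in epidermis micrographs is a routine but
laborious step in plant physiology, and most automatic detectors lean on
color or texture, which varies wildly across species, stains and
microscopes. One thing that does not vary much is *where* stomata sit:
development spaces them out, so their centers behave like a homogeneous
planar point process whose nearest-neighbour (and Delaunay edge) distances
follow a Rayleigh law,

    R(d | σ) = (d / σ²) · exp(−d² / 2σ²).

`drtb` implements Delaunay–Rayleigh Threshold Binarization: it segments
stomata by scanning **every** binarization threshold of a preprocessed grey
image and keeping the one whose segmented-region centroids *look most like
stomata geometrically*,

    l̂ = argmin over (l, σ) of RMSD( p(d | l), R(d | σ) ),

where `p(d | l)` is the edge-length histogram of the Delaunay tessellation
built on the centroids found at threshold `l` (regions are first cleaned by
an area floor and a robust median/MAD outlier filter,
`MAD = 1.4826 · median |r − median r|`, cutoff 3). Preprocessing converts
the RGB micrograph to `F = rescale(Pˢ ⊘ M(∂t Pᴿ))`: Perona–Malik
anisotropic diffusion `∂t` of the red channel, mean-shift intensity
quantization `M`, and elementwise (Hadamard) division of the HSV saturation
channel by the result. Detection quality is scored by the standard
center-distance protocol: PPV = TP/(TP+FP), TPR = TP/(TP+FN).

The package is aimed at plant scientists who want a detector that does not
need training data, and at methodologists interested in spatial-statistics
segmentation criteria. A seeded synthetic generator (Poisson/hard-core
point patterns rendered as stomata-like micrographs with known ground
truth) makes every stage testable without any external image database.

## Worked example

```r
library(drtb)

## a synthetic micrograph with known stomata positions
fx  <- synth_preset("clean", seed = 4)      # ~110 planted stomata, 800x800
F   <- preprocess_pipeline(fx$image)        # grey image in [0, 1]
seg <- drtb_segment(F)                      # 99-level scan + optimum

seg$best
#>   level sigma       rmsd bin_width n_regions n_triangles valid
#> 1  0.01   2.9 0.01542563  23.59644       111         209  TRUE

ev <- evaluate_detections(fx$truth, seg$centroids[, c("x", "y")], radius = 10)
unlist(ev[c("TP", "FP", "FN", "ppv", "tpr")])
#>  TP  FP  FN ppv tpr
#> 111   0   0   1   1
```

Reading the output: the scan selected binarization level 0.01 (on this
noise-free control image every level below the blob plateau yields the same
111 regions, and ties resolve to the smallest level), the best-fitting
Rayleigh scale is σ ≈ 2.9 in histogram-bin units (multiply by `bin_width`,
here ≈ 23.6 px/bin, for pixels), and the RMSD between the edge-length
frequencies and the Rayleigh mass is ≈ 0.015 — the magnitude expected for a
hundred-region tessellation. All 111 planted stomata are recovered within
10 px with no false positives.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/drtb.R synth    --outdir demo --preset clean --seed 4
Rscript inst/cli/drtb.R segment  --input demo/image.png --outdir demo/out
Rscript inst/cli/drtb.R evaluate --pred demo/out/centroids.csv \
                                 --truth demo/truth.csv --radius 10
```

`segment` writes `centroids.csv` (x, y, area, region_id), `scan.csv`
(level, sigma, rmsd, n_regions, n_triangles), `summary.json`, the final
`mask.png` and an `overlay.png` with centroid dots and moment-fitted
ellipses.

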