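# ndlesion

Density-based detection of skin-lesion borders in dermoscopy-style RGB
images.

Automated lesion border detection is the first step of most dermoscopy
image analysis pipelines, and the hard cases are well known: low contrast
between lesion and surrounding skin, fuzzy and irregular borders, hairs.
`ndlesion` approaches the problem as density-based clustering of pixels and
provides, in one package:

* **`dbscan()`** — a reference DBSCAN over image pixels with pluggable
  metrics (Euclidean, Manhattan, and the normalized colour–spatial
  distance). A pixel is a core point when at least `MinPts` other pixels
  lie within `eps` of it; clusters are maximal density-connected sets,
  everything else is noise.
* **`fdbld_cluster()`** — a boundary-accelerated variant. Every core
  point's neighbourhood is wrapped in its convex hull ("primitive
  cluster"); hulls are unioned into the cluster boundary Γ, and region
  queries are fired only for *leading points* within an `eps`-width inner
  band of Γ — interior pixels whose queries cannot change the cluster are
  skipped. In spatial (binary-image) mode its labelling is exactly equal
  to DBSCAN's.
* **The normalized distance (ND)** — the joint pixel metric

  `d(i,j) = sqrt( (1/w1)(w3ΔR² + w4ΔG² + w5ΔB²)/(3·255²) + (1/w2)(Δx² + Δy²)/(w² + h²) )`

  with `1/w1 + 1/w2 = 1` (defaults `w1 = w2 = 2`). It normalizes colour
  differences by the three-channel 8-bit range and spatial differences by
  the image diagonal, so the clusterer works directly on colour images —
  no binarisation step, no information loss from thresholding. A
  multispectral generalization covers any channel count.
* **`segment_lesion()`** — two end-to-end pipelines: `mode = "binary"`
  (intermeans threshold → spatial clustering of the dark foreground, the
  classic baseline) and `mode = "nd"` (colour clustering of all pixels,
  threshold-free), followed by lesion-cluster selection (drop
  border-spanning and speckle clusters, keep the darkest) and contour
  extraction.
* **Evaluation metrics** — precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
  and the XOR border error `BE = 100·|AB ⊕ MB|/|MB|` comparing the
  automatic border AB against a manual/ground-truth border MB.
* **A phantom generator** — `make_suite()` renders seeded dermoscopy-like
  images (skin background, irregular blurred darker lesion, optional
  hairs) with exact ground-truth masks, so every claim in the package is
  testable without clinical data.

## Worked example

```r
library(ndlesion)

# a low-contrast phantom: violaceous lesion, luminance gap ~1.5 noise sd
ph <- render_phantom(phantom_config(seed = 7, lesion = c(190L, 160L, 185L)))

# colour pipeline (no thresholding anywhere)
res <- segment_lesion(ph$image, mode = "nd")
res
#> <lesion_result [nd, ok]: 1760 lesion pixel(s), 11 contour ring(s)>

evaluate_masks(res$mask, ph$mask)[c("precision", "recall", "border_error")]
#> $precision
#> [1] 0.9880682
#>
#> $recall
#> [1] 0.9581267
#>
#> $border_error
#> [1] 5.344353

# binary baseline on the same image: the gray-level threshold carries
# little information here
res_bin <- segment_lesion(ph$image, mode = "binary")
evaluate_masks(res_bin$mask, ph$mask)$border_error
#> [1] 11.23967
```

The colour pipeline recovers the lesion at a border error of ~5.3% of the
lesion area (precision 0.99, recall 0.96), roughly halving the error of
the thresholding baseline on the same image — the phantom's lesion differs
from skin chromatically but barely in luminance, which is exactly the
regime the normalized distance is designed for. On high-contrast phantoms
the two pipelines swap ranks, since a global threshold is near-optimal
there.

A command-line front end wrapping the same functions ships in
`inst/cli/ndlesion.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ndlesion.R", package="ndlesion"))')" \
    segment --input img.png --mode nd --out-mask mask.png --stats stats.json
```

with subcommands `synth`, `cluster`, `segment`, `eval`, `bench`.

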