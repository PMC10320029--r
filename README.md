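# ShearFuse

Multimodal medical image fusion in the non-subsampled shearlet domain.

Clinical reading often needs two complementary brain scans at once: a
pseudo-color **functional** image (PET/SPECT) showing metabolic activity, and
a grayscale **structural** image (MRI) showing anatomy. ShearFuse merges a
registered pair into one color image for radiologists and for researchers
benchmarking pixel-level fusion rules.

## Method

For a registered pair (functional RGB `F`, structural grayscale `S`):

1. **IHS split** — `F` is mapped by a fixed invertible linear transform to an
   intensity plane `I = (R+G+B)/3` plus two chroma carriers `(R−G)/√2`,
   `(R+G−2B)/√6`; only `I` is fused, so color is preserved.
2. **NSST decomposition** — `I` and `S` are each split by a shift-invariant
   non-subsampled shearlet transform into one low-frequency sub-band (LFS)
   and, per scale, directional high-frequency sub-bands (HFS); all at full
   resolution, with analysis filters that sum to one at every frequency.
3. **LFS fusion (structural information)** — weighted mean with weights
   `SI = exp(α·|LFS − ID|)`, `ID = mean + median` of the band; pixels
   deviating from a band's intensity density carry structure and dominate,
   sharply for large α (default α = 4).
4. **HFS fusion (PCA)** — each matching directional band pair is combined
   with weights from the principal eigenvector of its 2×2 covariance matrix,
   normalized to sum to one.
5. **Inverse NSST + IHS** — fused bands are summed back into a fused
   intensity, which replaces `I`; the inverse IHS matrix returns RGB.

Quality metrics: standard deviation, entropy (8-bit scale), SSIM (11×11
Gaussian window, σ = 1.5) and structural content, each reported against both
sources. A seeded phantom generator provides registered PET-like/MRI-like
pairs so everything is testable without clinical data.

## Worked example

```r
library(ShearFuse)

p   <- phantomPair(size = 256, seed = 7)   # registered functional/structural pair
res <- fusePair(p$functional, p$structural, fusionConfig())
res
#> FusionResult: 256 x 256 x 3 fused image
#>   alpha = 4, scales = 3, directions [4, 8, 16]
#>   value range before clipping: [-0.1678, 1.109]

str(qualityReport(res, p$functional, p$structural), digits.d = 4)
#> List of 4
#>  $ sd     : num 50.91
#>  $ entropy: num 6.132
#>  $ ssim   :List of 3
#>   ..$ structural: num 0.8066
#>   ..$ functional: num 0.4837
#>   ..$ mean      : num 0.6451
#>  $ sc     :List of 3
#>   ..$ structural: num 1.462
#>   ..$ functional: num 0.6339
#>   ..$ mean      : num 1.048

writeOutputImage(res, "fused.png")         # clipped to [0, 1] on write
```

The fused image keeps the phantom's color coding while absorbing the
structural texture: its standard deviation (50.9 on the 0–255 scale) and
entropy (6.1 bits) reflect the added contrast and information, the SSIM of
0.81 against the structural source shows anatomy is carried over, and a
structural content above 1 means the fused image's energy stays below the
structural reference's. The intensity-substitution step can leave the
unclipped range (here −0.17 to 1.11); values are clipped only when writing.

### Command line

```sh
Rscript inst/cli/shearfuse synth --out-dir pair/ --seed 7
Rscript inst/cli/shearfuse fuse \
    --functional pair/functional.png --structural pair/structural.png \
    --out fused.png --metrics report.json
```

Exit codes: 2 missing/unreadable file, 3 unregistered (shape-mismatched)
pair, 4 invalid configuration.

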