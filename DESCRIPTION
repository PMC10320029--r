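Package: ShearFuse
Title: Multimodal Medical Image Fusion in the Non-Subsampled Shearlet Domain
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fuses a registered pair of brain images -- a pseudo-color
    functional scan (PET/SPECT-like) and a grayscale structural scan
    (MRI-like) -- into a single color image. The functional image is split
    into intensity and chroma planes by a linear IHS transform; the
    intensity plane and the structural image are decomposed with a
    shift-invariant non-subsampled shearlet transform; low-frequency
    sub-bands are fused by an exponential structural-information weighting
    and high-frequency directional sub-bands by principal-component
    eigenweights; the fused intensity is recombined with the original
    chroma planes. Includes fusion-quality metrics (standard deviation,
    entropy, SSIM, structural content), a seeded phantom generator for
    registered image pairs, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    png,
    tiff,
    jsonlite,
    optparse,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
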