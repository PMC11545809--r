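Package: ms2burst
Title: Quantification of Transcriptional Bursting from MS2-MCP Live-Imaging Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, tracks and quantifies nascent-transcription dots in
    two-channel live-imaging movies of syncytial Drosophila embryos carrying an
    MS2/MCP-GFP reporter. Provides maximum-intensity projection, photobleaching
    correction, nuclear-cycle stage splitting, threshold-based dot detection
    with per-stage min-max brightness normalization, centroid-proximity
    identity tracking with gap tolerance, tissue-level and per-nucleus burst
    metrics (telegraph-model ON runs and OFF gaps), and a case-versus-control
    statistical battery (exact/approximate Mann-Whitney U, mean-difference
    permutation test, variance-gated t-test, variance comparison). Includes a
    synthetic-movie generator with a two-state promoter model, Gaussian-PSF
    rendering and full ground truth, so the whole pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    withr,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
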