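Package: heartseg
Title: Noise-Robust Heart Sound Segmentation from Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the primary heart sounds (S1 and S2) in single-channel
    phonocardiogram recordings using a Shannon-energy envelope. Candidate
    sound lobes are located by thresholding the normalized average Shannon
    energy, validated against physiological duration and split-sound rules,
    and identified sequentially from an anchor pair using envelope
    correlation together with running cardiac-cycle and systolic-interval
    estimates. A noise-robust mode detects high-energy artifact lobes by
    their area z-scores, crops them, and segments each remaining clean
    interval independently. Includes midpoint-based sensitivity and accuracy
    metrics, a synthetic phonocardiogram generator with exact ground truth,
    WAV and tab-separated annotation input/output, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
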