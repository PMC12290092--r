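Package: laminarlfp
Title: Laminar LFP Analysis with Spline Inverse Current-Source Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of depth-resolved (laminar) extracellular recordings
    from high-density probes in cortex: spline inverse current-source-density
    (iCSD) estimation from depth-ordered local field potentials, short-time
    Fourier spectral analysis with depth-resolved power in dB re 1 mV^2/Hz,
    a z-scored band-power detector for epileptiform episodes with padded
    data exclusion, baseline-subtracted peristimulus time histograms by
    cortical layer, and exact Wilcoxon rank-sum comparison of per-session
    scalars between groups. Includes a forward-model simulator of laminar
    sessions with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
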