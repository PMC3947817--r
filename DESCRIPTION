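Package: veinverify
Title: Palm Vein Verification with Matched Filters, Wavelet and LBPV
    Features, and Locality Preserving Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A palm-vein biometric verification pipeline: oriented zero-sum
    Gaussian matched filters enhance the curvilinear vessel pattern of
    near-infrared palm images; global features are built from level-3
    wavelet approximation coefficients (WLPP) and local features from
    variance-weighted local binary pattern histograms (LBPV), both reduced
    by locality preserving projections; verification uses nearest-neighbour
    distances under four metrics, weighted-sum score fusion, and FAR/FRR/EER
    evaluation. Includes a synthetic vein-image generator so the full
    pipeline can be exercised and benchmarked without access to
    license-gated palm databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
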