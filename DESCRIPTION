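Package: qssnmr
Title: Quantitative Carbon-13 Solid-State NMR of Fat-Based Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and quantification of one-dimensional carbon-13
    solid-state NMR spectra of cocoa-based and other fat-based products.
    Covers the full analysis chain from free-induction decay to solid fat
    content: exponential apodization, Fourier transformation, phase
    correction, windowed integration, inversion-recovery multiexponential
    T1 fitting, Ernst-angle steady-state magnetization modelling for
    low-flip-angle acquisition schemes, triacylglyceride-to-sucrose
    quantification, and beta-polymorph assignment from the solid methylene
    line.  Includes a seeded generator of synthetic cocoa-product spectra,
    FIDs and inversion-recovery series with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
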