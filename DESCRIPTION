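Package: popspectral
Title: Spectral Estimation of Wright's Inbreeding Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact spectral estimation of Wright's inbreeding coefficient F_ST
    and Nei's among-population diversity D_ST from the singular values of the
    between-population genotype matrix, for K discrete populations. Implements
    the between/within decomposition of the centered (and scaled) genotype
    matrix, PCA-based approximation of mean F_ST with its separation condition,
    Marchenko-Pastur diagnostics for the residual spectrum and a detection
    threshold for population structure, a Beta-Bernoulli F-model simulator with
    closed-form expectations, and adjusted F_ST for surrogate genotypes obtained
    from latent factor regression on covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
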