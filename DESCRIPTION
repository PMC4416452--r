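Package: isopls
Title: Retrieving Foliar delta15N from Leaf Reflectance Spectra by Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric inference chain for retrieving the foliar nitrogen
    stable-isotope signature (delta15N, permil vs AIR) from fresh-leaf
    reflectance spectra: detector splice-jump correction, standard normal
    variate transformation, Savitzky-Golay first-derivative spectra, NIPALS
    PLS1 regression with autoscaling, 10-fold random-segment cross-validation
    with first-minimum factor selection, influential-outlier screening,
    iterated jackknife (Martens) uncertainty-test wavelength elimination, and
    variable-importance-in-projection (VIP) scores. Includes a synthetic
    leaf-spectra generator emulating a 15N greenhouse labeling design (isotope
    signature independent of other leaf traits) and a field gradient design
    (isotope signature covarying with nitrogen content), so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
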