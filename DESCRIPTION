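Package: vpstoich
Title: Viral Protein Stoichiometry and Capsid Heterogeneity Analysis for rAAV
Version: 0.1.0
Authors@R:
    person("Analytical", "Biophysics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of recombinant adeno-associated virus (rAAV)
    capsid composition and particle heterogeneity. Implements capillary gel
    electrophoresis (CGE) peak quantification with 214 nm molar extinction
    coefficients, a multinomial 60-subunit capsid assembly and mass model,
    charge detection mass spectrometry (CDMS) calibration and mass histogram
    analysis, isopycnic cesium chloride density gradient physics (band
    position, width and two-speed resolution), potency normalization and
    stoichiometry-potency correlation, melting temperature extraction from
    differential scanning fluorimetry, and seeded synthetic data generators
    emulating all of the above for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
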