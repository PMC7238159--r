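Package: amorphkin
Title: Crystallization Kinetics and Dielectric Relaxation Analysis of
    Amorphous Pharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of the physical stability of amorphous
    drugs from calorimetric and dielectric measurements. Implements the
    Avrami-Avramov treatment of isothermal crystallization kinetics
    (induction time, characteristic crystallization time, dimensionality
    exponent by two estimators) applied to DSC exotherms and to the decay
    of the static dielectric permittivity; Havriliak-Negami and Cole-Cole
    deconvolution of broadband dielectric spectra with dc conductivity;
    Kohlrausch-Williams-Watts master curves by time-temperature
    superposition; Vogel-Fulcher-Tammann and Arrhenius temperature
    dependences with derived glass-transition temperature, fragility and
    activation energies; and the Hempel heat-capacity-step extrapolation
    for monomolecular loading capacity of a drug on mesoporous silica.
    Includes synthetic-data generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
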