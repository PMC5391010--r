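Package: cardioec
Title: Multi-Scale Modelling of Cardiac Excitation-Contraction Coupling in
    Healthy and Failing Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates human ventricular myocyte electrophysiology with a
    modified Grandi-Pasqualini-Bers ionic model extended by a late sodium
    current, couples the resulting calcium transient to the
    Niederer-Hunter-Smith myofilament model to generate isometric active
    tension, and places both on a healthy-to-failing continuum through
    multiplicative ion-channel remodelling (impact) factors.  Extracts
    standard action-potential, calcium-transient and tension biomarkers
    from simulated traces, and provides the Holzapfel-Ogden orthotropic
    constitutive law for passive myocardium together with a thick-walled
    sphere left-ventricle surrogate for qualitative pump-function trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
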