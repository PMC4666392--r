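Package: filamentforge
Title: Geometric Modelling of RecA Presynaptic Filament / dsDNA Strand-Exchange Intermediates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses reduced-atom models of DNA bound to the RecA
    nucleoprotein filament during homology search and strand exchange. Provides a
    helical screw-transform engine (fitting, application, fragment replication),
    parameterized builders for B-form duplexes and triplet-patterned
    stretched/unwound filament DNA at strand-specific radii, kinked B-form tails,
    full three-strand synaptic assemblies, a geometric duplet-flip operator,
    screw-replicated protein anchor sets with salt-bridge bookkeeping, a
    spring-network restrained minimizer (backbone closure, radial pull), and the
    structural observables of such models: per-step axial rise and twist, strand
    radius, phosphate spacing, extension factor, base-pairing metrics D1/theta1
    with flip-state classification, junction angle, and triplet registration.
    All results are returned as tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
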