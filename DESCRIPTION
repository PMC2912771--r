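Package: merisim
Title: Spring-Based Simulation of Cell Division Rules in Isotropically
    Growing Epithelial Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex/spring model of an isotropically
    growing epithelial cell sheet such as the epidermal layer at the
    shoot apical meristem summit. Cell walls are linear springs whose
    resting lengths grow under tension; turgor-driven growth is a radial
    body force; cells divide when their area exceeds a threshold,
    according to pluggable division rules combining a division-center
    mechanism (center of mass, or uniform random point) with a
    division-direction mechanism (shortest path, random, orthogonal to
    the previous division, or perpendicular to the cell strain axis).
    Includes an adaptive fifth-order Runge-Kutta driver with division
    and boundary-removal events, an oryzalin (no-division) perturbation
    mode, and an analysis suite for cell-packing topology and geometry:
    neighbor-number distributions and their moments, deviation from a
    reference distribution, internal vertex angles against the ideal
    regular-polygon distribution, the area/perimeter-squared shape
    measure, and Lewis' law fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
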