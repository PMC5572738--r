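Package: scramblr
Title: Quantitative Analysis of Scramblase Reconstitution Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dithionite-based phospholipid
    scramblase assays on reconstituted proteoliposomes. Implements the
    Poisson/Gaussian vesicle-occupancy model relating scramblase activity
    to the protein-to-phospholipid ratio, nonlinear least-squares fitting
    of the occupancy constant and its conversion to the molar mass of the
    functional scramblase unit, single-exponential analysis of dithionite
    reduction kinetics with scrambling-rate lower bounds, Gaussian fitting
    of dynamic light scattering size distributions, and pyranine
    fluorescence-to-pH conversion for light-driven proton-pumping assays.
    Includes seeded generators for synthetic vesicle populations and
    fluorescence traces with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
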