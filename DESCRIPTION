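Package: radkin
Title: Radical-Scavenging Kinetics and Chelation Equilibria from Quantum-Chemical Thermochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline that turns quantum-chemistry-derived free
    energies into antioxidant kinetics: per-channel rate constants by
    conventional transition-state theory with Eckart tunneling (formal hydrogen
    transfer and radical adduct formation) and by Marcus theory (single electron
    transfer), corrected to the diffusion limit with the Collins-Kimball
    interpolation and Smoluchowski/Stokes-Einstein diffusion rates. Channel
    rates are weighted by acid-base mole fractions at a given pH, assembled
    into branching ratios and overall rate constants per medium, and
    complemented by metal-chelation equilibrium constants and pro-oxidant
    electron-transfer kinetics of the resulting complexes. Ships a structured
    profile format (JSON/YAML/CSV), a synthetic profile generator, bundled
    reference profiles for the alkylresorcinols olivetol and olivetolic acid,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
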