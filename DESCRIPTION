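Package: salivapk
Title: Saliva-Blood Partitioning and Salivary Pharmacokinetics of
    Ionizable Xenobiotics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts salivary uptake and clearance of ionizable
    xenobiotics for non-invasive biomonitoring. Implements an adapted
    Schmitt saliva:blood partition-coefficient algorithm combining
    Henderson-Hasselbalch ion trapping, plasma protein binding scaled by
    fluid composition, and permeation-weighted transport of ionized
    species; a coupled blood/saliva one-compartment parent-metabolite
    pharmacokinetic simulator with dynamic (pilocarpine-stimulated)
    salivary flow and an optional Michaelis-Menten carrier-transport
    mode; local normalized sensitivity analysis by forward finite
    differences; and scenario configuration, species/compound libraries
    and result writers supporting rat-to-human extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
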