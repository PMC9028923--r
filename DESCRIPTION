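Package: alphacell
Title: Glucose- and Amino-Acid-Dependent Glucagon Secretion from Pancreatic Alpha Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of glucagon secretion from pancreatic
    alpha cells. Couples three components: a metabolic component mapping plasma
    glucose and fatty-acid oxidation to lactate and CO2 fluxes, relative ATP and
    K(ATP)-channel conductance; a cAMP signaling component combining a
    bicarbonate-sensitive soluble adenylyl cyclase (sAC) source with an autocrine
    glucagon-receptor/transmembrane adenylyl cyclase (tmAC) Hill response; and a
    Hodgkin-Huxley-type membrane/secretion component in which ionotropic
    glutamate-receptor activation by amino acids scales the cation currents.
    Produces relative glucagon secretion (RGS) dose-response curves over glucose
    and amino-acid grids, membrane-potential traces with oscillation metrics, and
    stacked cAMP decompositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    rlang,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
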