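Package: quenchbind
Title: Fluorescence Quenching, Binding and FRET Analysis of
    Ligand-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of steady-state fluorescence titrations of a protein
    with a small-molecule ligand: Stern-Volmer quenching with
    static/dynamic mechanism classification across temperatures,
    double-logarithmic binding isotherms yielding association constants,
    stoichiometries and Gibbs free energies, site-marker competitive
    displacement, synchronous-fluorescence and excitation-emission-matrix
    conformational probes, UV-Vis band-shift analysis, and Forster
    resonance energy transfer distance estimation.  Includes a
    synthetic-spectra generator with known ground truth so the whole
    pipeline can be validated without instrument data, plus a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
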