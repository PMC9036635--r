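Package: cdsom
Title: Protein Secondary Structure from Circular Dichroism Spectra via
    Self-Organising Maps and Random-Coil Derandomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates protein secondary-structure content (alpha-helix,
    beta-sheet, other) from far-UV circular dichroism (CD) spectra by
    fitting against a self-organising map trained on structure-annotated
    reference spectra. For proteins with unfolded domains or populations
    the package systematically subtracts fractions of a random-coil
    spectrum ("derandomization"), selects the best-fitting core protein by
    normalised root-mean-square deviation (NRMSD), and regenerates the
    structure fractions of the original protein. Best-matching-unit
    inspection flags reference proteins of the beta-II class, whose CD
    spectra are indistinguishable from random coil. Includes reference-set
    and melting-series file IO, a synthetic spectrum generator with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
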