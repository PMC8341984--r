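Package: dpafret
Title: FRET-Based Topography of Ion-Channel Intracellular Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring the axial topography and acid-evoked motions
    of ion-channel intracellular domains from fluorescence data. Implements
    the two-plane dark-acceptor (dipicrylamine) FRET quenching model and its
    inversion to axial distances, Forster-radius calculation from spectra,
    fluorescence-voltage Boltzmann analysis for patch clamp fluorometry,
    TCSPC lifetime fitting with FRET-efficiency and dilution-series analysis,
    pH-jump apparent-FRET and gating-kinetics fits, resampling statistics
    (permutation tests, Holm-Bonferroni, exact Wilcoxon signed-rank), and
    seed-deterministic synthetic-data generators emulating each recording
    modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
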