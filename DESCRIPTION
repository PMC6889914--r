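Package: anomsite
Title: Detection of Partially Occupied Anomalous Scatterer Sites in Protein Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis tools for locating weak, partially occupied
    anomalous scatterers (such as iodine labels on disordered peptides) in
    macromolecular crystals.  Implements phased anomalous difference Fourier
    synthesis with sigma-normalized peak search, multi-energy absorption-edge
    contrast classification of anomalous sites, cross-orientation peak
    consensus, dose-dependent signal-decay checks, multi-start occupancy/ADP
    estimation with 2D-histogram readout, and ensemble selection of disordered
    conformers against observed anomalous site positions, together with a
    synthetic diffraction-data generator that emulates tetragonal protein
    crystals carrying iodine probe sites at low occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
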