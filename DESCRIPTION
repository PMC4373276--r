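Package: brainlattice
Title: Reverse-Inference Brain Maps, Behavioral Brain Lattices, and
    Collaboration Networks from Coordinate-Based Neuroimaging Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-label reverse-inference brain maps from a
    coordinate-based neuroimaging corpus (per-voxel 2x2 chi-square tests
    of the dependence between reported activation and the presence of a
    behavioral term or author, FDR-thresholded and z-scored), trains a
    self-organizing map ("brain lattice") on behavioral term maps,
    projects author maps onto the lattice by cosine similarity, ranks
    and clusters authors by the similarity of their published activation
    coordinates, and assembles a co-authorship network of principal
    investigators annotated with those similarity groups.  Includes a
    synthetic-corpus generator with planted spatial foci and planted
    collaboration pairs so the whole pipeline is testable without any
    external database, and a subcommand CLI wiring the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
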