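Package: avpdyn
Title: Kinetics of the Alkaline Synaptic-Vesicle Population from pH-Cycling
    Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of pHluorin fluorescence recordings
    acquired under fast extracellular pH-cycling, for studying the population
    of endocytosed but not-yet-reacidified ("alkaline") synaptic vesicles.
    Implements a first-order two-pool kinetic model of vesicle recycling
    under ideal and pH-cycling ("realistic") conditions, a ground-truthed
    synthetic trace and image-stack generator, derivative-based separation of
    pH 7.5 and pH 5.5 frames, Laplacian-of-Gaussian bouton detection with
    Manders/Pearson colocalization, exponential estimation of reacidification
    and endocytosis time constants, and FFT deconvolution of the endocytosis
    time course from the alkaline-population kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
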