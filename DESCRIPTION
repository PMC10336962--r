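Package: idpbench
Title: Benchmarking Coarse-Grained Models of Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for benchmarking coarse-grained predictions of the radius
    of gyration (Rg) of intrinsically disordered proteins against
    small-angle-scattering experiments. Ships a curated 24-protein benchmark
    table with predictions from four models (an N-only scaling law, the
    SOP-IDP model, a one-bead-per-residue bead-necklace model, and a modified
    Martini 2 model), and implements the evaluation statistics (signed
    percentage deviation, modified Pearson chi-square, leave-one-out
    chi-square, property-bias trendlines), sequence descriptors (fixed
    Henderson-Hasselbalch charges, FCR, NCPR, Kyte-Doolittle hydropathy,
    proline content), power-law scaling fits, and a canonical-ensemble
    Metropolis Monte Carlo simulator of the bead-necklace model with explicit
    counterions and extended Debye-Hueckel electrostatics. Synthetic-data
    generators (composition-controlled random sequences, phantom chains,
    noisy power-law datasets) support fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    seqinr,
    graphics,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
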