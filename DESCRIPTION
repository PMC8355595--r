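Package: shapesieve
Title: SHAPE Reactivity Prediction from RNA 3D Structures and Ensemble Sieving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-nucleotide SHAPE (selective 2'-hydroxyl acylation
    analyzed by primer extension) reactivity profiles from RNA 3D structures in
    PDB format. Base pairs and stacking contacts are detected geometrically,
    the 2'-hydroxyl ligand-accessible surface area is computed with a
    deterministic Shrake-Rupley algorithm, and ribose pucker is classified by
    the pseudorotation phase angle. Per-nucleotide features are combined by an
    energy-like scoring model into a predicted reactivity profile. Predicted
    profiles can be compared to experimental SHAPE data through regular and
    noise-adjusted Pearson correlations, and conformational ensembles can be
    ranked ("sieved") by SHAPE compatibility, with heavy-atom RMSD to a
    reference structure. Includes a generator for ideal A-form RNA fixtures,
    decoys, and model-consistent synthetic SHAPE profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
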