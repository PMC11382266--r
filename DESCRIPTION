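Package: surfclass
Title: Surface-Chemistry Descriptors and Interpretable Random-Forest
    Classification of Secreted and Cytosolic Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pipeline for classifying proteins as secreted or cytosolic
    from the chemistry of their solvent-exposed surface. From a 3D
    structure (PDB or mmCIF, e.g. an AlphaFold model) it computes
    Shrake-Rupley solvent-accessible surface areas, extracts surface
    residues by tripeptide-normalised relative SASA, builds compositional
    surface descriptors (amino-acid, residue-class, functional-group and
    secondary-structure percentages), trains balanced random forests over
    repeated train/test splits, prunes correlated and unimportant
    descriptors, and interprets the fitted forests by decision-path
    contribution decomposition to extract quantitative class-boundary
    thresholds for the top features.  Includes generators for synthetic
    polypeptide structures and planted-rule feature tables so the whole
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    class,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    pROC,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
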