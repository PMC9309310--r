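Package: salmopsin
Title: Spectral Inference for Salmonid Visual Photopigments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the spectral peak of absorbance (lambda-max)
    of salmonid visual photopigments. Maps opsin protein sequences onto bovine
    rod-opsin numbering and interrogates known spectral tuning sites (the
    five-sites rule for LWS, the F86 ultraviolet rule for SWS1, the E122Q
    classifier for RH2); computes chromophore geometry and fluctuation
    descriptors (named retinal torsion and bond angles, area under the
    per-atom RMSF curve of the retinal-plus-lysine moiety) from molecular
    dynamics trajectories; evaluates published descriptor-based regression
    models for RH2 and SWS2 pigments; generates Govardovskii A1 dark-spectrum
    templates; screens coding sequences for ORF-disrupting lesions
    (pseudogene calling); and depth-normalizes developmental opsin expression
    count tables. A synthetic-data module generates trajectories, coding
    sequences, and count tables with recorded ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
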