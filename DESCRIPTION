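Package: methModNet
Title: DNA Methylation Module Networks for Cancer Prognosis and Molecular Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Builds gene co-methylation networks from DNA methylation
    beta-value matrices using a rank-based (top-k nearest neighbour)
    correlation scheme, detects dense gene modules with a reimplementation
    of the MCODE algorithm, links modules into a module-level network by a
    permutation test on cross-module edges, extracts core modules by
    K-shell decomposition, and uses the core modules for survival risk
    scoring (GGI-style sum of signed module statistics) and K-means
    molecular typing with silhouette-based model selection. Includes probe
    filtering and beta-to-M preprocessing for Illumina 450K-style data, a
    resampling-based comparison of prognostic stability between data
    types, and a synthetic-cohort generator with planted modules,
    cross-talk and proportional-hazards survival for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core.R'
    'io.R'
    'mcode.R'
    'methods.R'
    'moduleNetwork.R'
    'network.R'
    'preprocess.R'
    'prognosis.R'
    'stability.R'
    'synthetic.R'
    'typing.R'
    'utils.R'
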