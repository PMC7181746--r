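Package: metroutes
Title: Clonal Evolution and Metastatic Route Inference from Multi-Lesion
    Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal evolutionary history and metastatic
    spreading routes of colorectal cancers sequenced across the primary
    tumor, lymph node metastases, and liver metastases. Provides
    depth-weighted merging of cancer cell fractions (CCFs) over multi-region
    samples, clonality calling per mutation cluster and lesion, clone-tree
    reconstruction from CCF constraints via the pigeonhole principle,
    parsimonious inference of per-metastasis seeding routes with
    monoclonal/multiclonal classification, and a three-mode taxonomy of
    spread (sequential, skip, intra-layer) over the T-P-I-C-LM network.
    Includes a synthetic patient generator with known clone trees and
    seeding histories for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
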