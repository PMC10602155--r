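Package: srev
Title: Self-Returning Excluded-Volume Chromatin Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generation and analysis of single-chromosome chromatin
    configurations under the self-returning excluded-volume (SR-EV) model.
    A self-returning random walk with a folding parameter alpha produces a
    tree-like trajectory that is expanded into a linear chain of nucleosome
    beads and relaxed with a soft repulsive potential until all bead
    overlaps are resolved. The package computes the observables used to
    characterise chromatin packing: end-to-end distance and contact
    probability versus genomic separation, chromatin volume concentration
    in probing cubes, the cumulative pair correlation G(r) and its packing
    exponent D, local volume fractions, and packing-domain segmentation of
    voxelised density stacks with mass-scaling radius criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, jsonlite, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
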