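Package: cascadeHOR
Title: Detection and Cascading Alignment of Alpha Satellite Higher-Order Repeats
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandemly organized alpha satellite monomers in genomic
    sequence by semi-global edit-distance scanning against a ~171 bp consensus,
    clusters the monomers into families (types) at a 5% divergence threshold,
    computes global repeat map (GRM) period histograms and monomer distance
    (MD) diagrams, and reconstructs higher-order repeat (HOR) arrays as
    cascading aligned schemes that classify canonical and variant copies,
    including cascading HORs in which monomer types repeat within the
    canonical copy. Ships a synthetic tandem-array simulator with
    machine-readable ground truth and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
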