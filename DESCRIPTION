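Package: netcost
Title: Cost-Efficiency Analysis of FDR-Thresholded Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-specific weighted functional connectivity networks
    from ROI time series (Pearson correlation with Benjamini-Hochberg edge
    retention), computes distance-weighted network cost metrics alongside
    standard graph measures (clustering, shortest paths, global efficiency),
    traces the cost-efficiency trade-off by random edge deletion on a
    group-averaged inverse network, screens brain subsystems for hyper- and
    hypoconnectivity with an effect-size gate, and summarises connection
    length-by-strength structure as 2-D histograms with iso-cost contours.
    Ships a synthetic multi-subject, multi-timepoint cohort generator with
    block-structured correlation ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
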