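Package: netexposure
Title: Network Exposure Analysis of Annotated Recommendation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how users of a video-sharing platform are
    exposed to vaccine misinformation through recommendation networks.
    Simulates annotated snowball-crawl recommendation networks, computes the
    network exposure model (the fraction of a node's ties leading to nodes
    carrying an attribute), descriptive network statistics (average degree,
    diameter, average clustering), and case-control odds ratios of exposure
    by video type with Woolf, Cornfield-approximate and exact conditional
    confidence intervals. Includes annotation-stage utilities (Krippendorff's
    alpha, systematic sampling, half-up percentage rounding) and report
    generation, plus readers and writers for GraphML, GEXF and CSV edge
    lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
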