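Package: keynodes
Title: Spectral Identification of Nodes Important to Network Community Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the nodes of an undirected (optionally weighted) network by
    their importance to the network's community structure using only the
    spectrum of the graph: importance is the relative perturbation of the c
    largest adjacency eigenvalues upon node removal, available both as a
    closed-form first-order approximation from the leading eigenvectors and as
    an exact removal computation. A companion score built from the bottom
    eigenvectors of the graph Laplacian (the vertex-vector magnitude arising in
    the RatioCut relaxation) separates the important nodes into community
    cores and bridges, without requiring an explicit partition. Includes
    eigengap estimation of the number of communities, planted-partition and
    fixture network generators, readers and writers for common graph formats,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
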