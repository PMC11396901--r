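Package: portraitSOM
Title: Self-Organizing Map Portrayal of Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a metagene self-organizing map (SOM) on a gene-level
    log-expression matrix and portrays each sample as an image on the neuron
    lattice. Connected regions of over-expressed metagenes are segmented into
    spot modules with gene lists, per-sample profiles and co-activation
    networks; sample-level structure is characterized through the pairwise
    portrait correlation map, independent component coordinates and a
    second-level sample SOM; spot gene lists are tested for gene-set
    overrepresentation against user-supplied GMT collections. A factorial
    time-course simulator with planted co-regulation modules supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    cluster,
    limma,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
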