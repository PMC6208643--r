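Package: phylosym
Title: Simulation-Based Evaluation of Phylosymbiosis Detection Under Ecological Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates host and microbe phylogenies, continuous trait evolution
    with tunable phylogenetic signal (Pagel's delta rescaling followed by
    Brownian motion), and individual-based assembly of host-associated
    microbial communities under environmental filtering, neutral drift and
    competition. Couples the simulator to the two standard phylosymbiosis
    detection procedures (the Mantel test on host phylogenetic distance versus
    microbiota beta diversity, and the UPGMA-dendrogram / normalized
    Robinson-Foulds congruence test with permutation nulls), computes Jaccard,
    Bray-Curtis and weighted/unweighted UniFrac dissimilarities, and provides
    an experiment runner that estimates type-I error, power and effect sizes
    across grids of phylogenetic signal, binned by realized Blomberg's K.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
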