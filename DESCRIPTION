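Package: leptokit
Title: Organellar Phylogenomics Toolkit: Topology Tests, Compositional
    Bias, and Organelle MAG Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of organellar
    (plastid and mitochondrial) genomes recovered from marine
    metagenomes. Implements constrained-topology likelihood testing
    with degrees of freedom derived from the strict consensus tree and
    a Bonferroni correction over consensus-compatible resolutions, the
    approximately unbiased (AU) test via RELL multiscale bootstrap, a
    desk-scale fixed-topology likelihood engine (empirical amino-acid
    models with discrete-gamma rates), amino-acid compositional-bias
    classification (chi-squared residuals, UPGMA taxon split, binomial
    scoring), alignment treatments (SR4 recoding, gap trimming,
    stationarity trimming by Stuart's test of marginal homogeneity),
    marker-based completeness/redundancy and ANI dereplication of
    organelle metagenome-assembled genomes, coverage-correlation
    linking of plastid and mitochondrial genomes, Dollo parsimony on
    gene presence/absence, and seeded synthetic-data generators for
    all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    MASS,
    stats,
    utils
Suggests:
    phangorn,
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
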