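Package: driftkit
Title: F-Statistics, Admixture Models and Demographic Inference for
    Pseudo-Haploid Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of the
    population-genetic inference stack used for SNP-capture ancient DNA:
    adaptive pseudo-haploid genotype calling from pileups with empirical
    stratified error rates, f2/f3/f4 statistics and Hudson Fst with a
    weighted block jackknife, qpWave rank tests and qpAdm admixture-weight
    estimation with model rotation, admixture-graph fitting and randomized
    topology search, outgroup-f3 distance matrices with MDS and
    neighbor-joining, pairwise-mismatch-rate kinship detection, and
    effective-population-size inference from runs-of-homozygosity length
    distributions. Every stage is paired with a synthetic-data generator
    (Balding-Nichols drift with admixture edges, stratified sequencing
    error, constant-Ne ROH renewal process, related-pair genotypes) so the
    whole pipeline is verifiable without access to restricted genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
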