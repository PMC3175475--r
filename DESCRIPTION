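Package: clinezone
Title: Maximum-Likelihood Cline and Disequilibrium Analysis of Hybrid Zones
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of narrow hybrid zones sampled as georeferenced
    individuals genotyped at diagnostic markers.  Projects two-dimensional
    sampling coordinates onto a one-dimensional transect whose heading is
    itself estimated by maximum likelihood using monotone (pool-adjacent-
    violators) clines; fits parametric tanh allele-frequency clines per
    locus and jointly, with profile-likelihood two-unit support limits and
    likelihood-ratio tests of cline coincidence and concordance; fits
    Barton's individual-by-locus hybrid-index concordance model (alpha,
    beta); estimates within-locus heterozygote deficit, between-locus
    gametic disequilibrium (EM over unphased diploid genotypes) and
    cytonuclear disequilibrium in a spatial sliding window; classifies
    hybrids from admixture proportions and closed-form genotype-frequency-
    class posteriors at diagnostic loci; and compares habitat-and-cline
    against cline-only models.  Includes a synthetic hybrid-zone generator
    with known cline, disequilibrium, asymmetry and habitat structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
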