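Package: iglight
Title: Germline Allele, Deletion, Haplotype and Splice-Variant Inference
    for Immunoglobulin Light-Chain Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers germline polymorphisms of human immunoglobulin
    light-chain (IGK/IGL) V and J genes from naive B-cell-receptor
    repertoire data. Prepares a germline reference by collapsing
    duplicated genes that share identical alleles and consensus-extending
    truncated reference alleles; detects novel allele candidates from
    per-individual mismatch frequencies at polymorphic positions and
    filters sequencing artefacts by their cohort-wide frequency pattern;
    tests for double chromosome deletions with a binomial test and
    Benjamini-Hochberg correction; infers gene-anchored haplotypes and
    single-chromosome deletions with binomial-likelihood Bayes factors;
    and clusters upstream (5'UTR, L-PART1, L-PART2) sequences to detect
    intron-retaining splice variants with premature termination codons.
    Includes a seeded synthetic-repertoire generator that emulates the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
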