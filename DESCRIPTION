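Package: cnaphase
Title: Clonal Origin of Synchronous Tumors via Copy-Number Phasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether multiple synchronous tumors from one patient are
    independent primaries (multi-centric disease) or clonally related
    (intrahepatic metastases). Implements matched-normal somatic variant
    filtering with read-depth and frequency exclusion rules, pairwise
    mutation recall matrices across tumor regions, copy-number segment
    matching with breakpoint-concordance comparison, and a chromosome
    phasing test that groups heterozygous sites by the direction of their
    allele-frequency shift inside a shared copy-number alteration and
    applies a Welch two-sample t-test to decide whether two tumors altered
    the same homologous chromosome. A synthetic-data generator produces
    multi-region observations (germline heterozygous sites with phase,
    homolog-labelled gains and losses, purity mixing, Poisson depth and
    binomial allele-count sampling) with full ground truth so every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
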