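Package: recpipe
Title: Pedigree-Based Sex-Specific Recombination Mapping and GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers in three-generation livestock families
    from SNP-array genotypes, builds sex-specific recombination maps with an
    EM localization algorithm, calls recombination hotspots and computes
    per-animal hotspot usage, and runs genome-wide association scans of
    recombination phenotypes with a linear mixed model whose residual
    variances are inversely proportional to the number of repeated
    measurements. Includes a pedigree and meiosis simulator with known
    crossover locations so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
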