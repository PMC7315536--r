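Package: methclock
Title: Targeted Epigenetic Age Prediction from Methylation Levels and
    Single Bisulfite Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolbox for targeted epigenetic age analysis: screening of
    age-associated CpG sites across multiple methylation studies,
    multivariable linear age predictors with the logarithmic adult-age
    transformation, Poisson quantification of methylation fractions from
    duplex droplet digital PCR counts, and a maximum-likelihood age
    predictor for the binary methylation pattern of individual bisulfite
    amplicon sequencing reads, together with seeded simulators for read
    patterns and multi-study beta-value matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
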