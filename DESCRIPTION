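Package: actisig
Title: Hormone-Receptor Activity Gene Signatures from Perturbation Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a hormone-receptor activity gene signature from panels of
    treatment-versus-vehicle perturbation transcriptomes and deploys it on
    tumor cohorts. Provides moderated-t differential expression, consensus
    occurrence filtering with elbow analysis, anchor-gene correlation
    filtering, per-sample z-mean activity scoring with random-gene-set null
    benchmarking, polynomial activity-versus-anchor trend fitting, ssGSEA-style
    pathway scoring and family-level correlation, hypergeometric
    overrepresentation analysis, panel-gene PCA and k-means derived
    classifiers, Kaplan-Meier / log-rank survival stratification with
    permutation-based prognostic-power assessment, recovery-curve single-cell
    scoring, and ChIP-peak proximity enrichment around transcription start
    sites. A synthetic-data module generates every input with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
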