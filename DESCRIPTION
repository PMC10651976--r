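Package: imgtx
Title: Imaging Transcriptomics of Spontaneous Brain Activity
Version: 0.1.0
Authors@R:
    person("Imgtx", "Developers", email = "imgtx@example.org",
           role = c("aut", "cre"))
Description: An end-to-end imaging-transcriptomics pipeline for case-control
    studies of spontaneous brain activity. Computes the amplitude of
    low-frequency fluctuations (ALFF) from BOLD time series, tests voxel-wise
    group differences with covariate-adjusted Freedman-Lane permutation and
    max-statistic family-wise error control, generates variogram-matched
    spatially autocorrelated surrogate maps for spatial nulls, preprocesses
    donor-level microarray expression (intensity filtering, RNA-seq guided
    probe selection, scaled robust sigmoid normalization, differential
    stability), correlates gene expression with sphere-sampled t-maps under a
    max-|r| permutation null, partitions genes by cross-dataset replication,
    and runs a gene-set enrichment suite (Fisher/hypergeometric, ensemble-null
    category scores, specificity-index temporal enrichment, cell-type
    enrichment, cross-disorder overlap). A synthetic-data module generates all
    pipeline inputs with planted ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
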