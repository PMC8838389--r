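Package: russetomics
Title: Multi-Omics Statistics for Apple Skin Russeting Candidate Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for comparing a russeted and a waxy apple
    variety across fruit development with metabolomic (LC-HRMS feature areas),
    proteomic (spectral counts) and transcriptomic (read counts) layers.
    Provides molecular-formula arithmetic for adduct m/z, ppm error,
    neutral-loss fragments and triterpene-hydroxycinnamate candidate series;
    per-timepoint Welch tests with a Venn-style meta-analysis and PCA
    top-loading selection for metabolite features; RPKM quantification,
    Baggerley's weighted proportion test with Benjamini-Hochberg correction,
    Pearson/complete-linkage expression clustering and hypergeometric
    enrichment; NSAF normalization with peptide-evidence filtering;
    cross-omics Pearson-correlation candidate nomination; UPGMA phenograms
    with locus-level bootstrap from SSR allele calls and Jukes-Cantor
    protein-distance trees; and a synthetic tri-omics generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
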