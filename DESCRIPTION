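Package: namqtl
Title: Joint-Linkage and Resampling GWAS Dissection of Quantitative Traits
    in Nested Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simultaneous genetic dissection of correlated
    quantitative traits in multi-family nested association mapping (NAM)
    panels of recombinant inbred lines. Provides a synthetic NAM data
    generator (Haldane meioses, selfing to fixation, augmented
    incomplete-block field designs with separable AR1xAR1 spatial plot
    error); mixed-model estimation of per-line BLUEs with BIC-guided
    random/residual structure selection, DFFITS outlier screening, Box-Cox
    transformation and delta-method line-mean heritabilities; joint
    stepwise linkage mapping with permutation-derived entry thresholds,
    family-nested allelic effects, multicollinearity pruning, peak
    re-scanning, support intervals and segregation-distortion-aware
    variance explained; resampling-based GWAS on projected dense variants
    scored by resample model inclusion probability (RMIP); pleiotropy
    quantification by correlation of family-nested allelic effects with
    Benjamini-Hochberg control; LD-windowed merging of QTL intervals and
    candidate-gene resolution; and linear versus random-forest prediction
    of a target trait from component traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    yaml,
    ranger,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
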