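Package: spikeAE
Title: Autoencoder Feature Extraction and Evaluation for Spike Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature extraction for extracellular spike sorting using ten
    autoencoder variants (shallow, deep, tied-weight, PCA-hybrid, greedily
    pretrained, LSTM, Fourier-domain, windowed-Fourier, orthogonal and
    contractive), together with the surrounding pipeline: a ground-truth
    spike simulator, peak alignment and unit-interval scaling, band-pass
    threshold spike detection, classical 2-D embeddings (PCA, ICA, Isomap)
    with grid search, K-Means clustering, six clustering validity indices
    (ARI, AMI, V-Measure, Davies-Bouldin, Calinski-Harabasz, Silhouette)
    implemented from their defining formulas, Borda rank aggregation and
    Bonferroni-corrected paired comparisons, and benchmark orchestration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
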