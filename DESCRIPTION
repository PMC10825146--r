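Package: latentbridge
Title: Cross-System Omics Translation Through a Shared Latent Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains paired autoencoders that map omics profiles from two
    biological systems (cell lines or species) into a shared global latent
    space without requiring one-to-one feature homology, enabling
    cross-system translation of perturbation signatures. The latent space is
    shaped by Euclidean and cosine alignment of same-condition embeddings, a
    Jensen-Shannon mutual-information discriminator, an adversarial prior
    discriminator, and optional covariate composition with an adversarial
    system classifier. Includes a negative-binomial reconstruction mode for
    counts, evaluation metrics (micro-F1, global Pearson, per-sample
    Spearman, sign accuracy, per-gene R2, cosine-distance effect sizes, a
    GSEA-based rank distance), interpretation machinery (integrated
    gradients, k-means latent selection, likelihood-ratio tests, feature
    networks), reference baselines (shared-encoder autoencoders,
    principal-component projection, per-gene slope-one regression, direct
    translation), and a synthetic two-system data generator for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    nnet
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
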