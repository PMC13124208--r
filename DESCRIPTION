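Package: mndpipe
Title: Multimodal Imaging Pipeline for Motor Neuron Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for five-class motor neuron
    disease classification (normal, ALS, PLS, PBP, PMA) from multimodal 2-D
    brain images (MRI, CT, PET, DTI). Provides adaptive dynamic histogram
    equalization for contrast enhancement, a total-variation bilateral filter
    for multiplicative speckle denoising in the log domain, a four-block
    residual network with convolutional block attention (channel and spatial)
    for feature extraction, a dove swarm optimizer for wrapper feature
    selection, and a deep belief network (stacked restricted Boltzmann
    machines with contrastive-divergence pretraining and supervised
    fine-tuning) for classification. Because clinical data of this kind are
    rarely shareable, the package ships a parametric phantom generator that
    emulates the intensity, texture and noise structure each stage assumes, so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
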