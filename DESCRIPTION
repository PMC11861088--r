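Package: noduleSSL
Title: Hybrid Generative-Contrastive Self-Supervised Pretraining for CT
    Pulmonary Nodule Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a hybrid self-supervised learning pipeline for
    benign/malignant classification of solitary pulmonary nodules on CT.
    Lesion-centred axial and coronal slice stacks are tiled into 5x5
    montages; a masked-autoencoder objective reconstructs hidden montage
    patches while a momentum-contrast InfoNCE objective, backed by a FIFO
    queue dictionary of momentum-encoded coronal keys, aligns the two
    anatomical views of the same lesion. Includes a synthetic lung-phantom
    generator with class-conditional nodule morphology (lobulation and
    spiculation), Hounsfield-unit preprocessing (isotropic resampling,
    window normalisation, ROI montage assembly, augmentation), a pure-R
    vision-transformer encoder/decoder with momentum encoder and queue,
    AdamW training loops with cross-validated fine-tuning, and evaluation
    utilities (bootstrap AUC confidence intervals, sensitivity/specificity,
    and image-fidelity metrics including SSIM and PSNR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
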