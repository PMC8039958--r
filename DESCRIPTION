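Package: habitatmap
Title: Hypoxic Habitat Mapping from Multiparametric MRI with Co-Registered Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify hypoxic habitats in tumors from multiparametric
    MRI (mpMRI) using pimonidazole (PIMO) stained histology as ground truth.
    Computes semi-quantitative DCE-MRI parametric maps (AUC, slope, time to
    maximum), builds binary PIMO-positive masks by per-slice Otsu thresholding,
    rasterizes vendor polygon masks (Bresenham boundary plus scanline fill with
    hole semantics), co-registers histology to MRI with a landmark-based 2D
    affine fit gated by Dice similarity, trains a compact ResNet-18 patch
    classifier of per-pixel hypoxia probability from five MR channels, and
    evaluates predictions by per-slice Pearson correlation, AUROC and the
    Youden-index cutoff for responder stratification. Includes a synthetic
    phantom generator that emulates paired mpMRI and histology slices with a
    known MR-to-hypoxia link so that every stage of the pipeline can be tested
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    EBImage,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
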