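Package: fibrestain
Title: Virtual Staining of Fibrin Networks from Label-Free Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts fluorescently labeled confocal optical sections of
    fibrin fiber networks from label-free inputs: three reflection confocal
    (RCM) channels at 405/488/561 nm plus one laser-transmission channel.
    Implements sliding-window Z-score normalization, a fully convolutional
    3D encoder-decoder with per-channel attention trained under a hybrid
    L1/L3/SSIM loss, channel-ablation and transmission-blur experiments,
    bootstrap image-quality metrics (MSE, SSIM, PSNR, Spearman), and
    skeleton-based fiber vectorization with length/width/depth statistics.
    A synthetic multimodal phantom generator emulates paired label-free and
    fluorescence stacks, including orientation-dependent RCM response,
    thick-focal-volume transmission with a spatially varying focal offset,
    and central-spot and interference-ring artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
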