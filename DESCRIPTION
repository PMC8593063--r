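Package: arterydmri
Title: Gaussian and Non-Gaussian Diffusion MRI Modelling of Arterial Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise arterial-wall microstructure from
    multi-shell diffusion-weighted MRI. Provides multi-shell acquisition
    scheme builders (high multi b-value and high angular resolution
    protocols), a synthetic arterial-ring phantom with two-compartment
    anisotropic Gaussian signal and Rician noise, Marchenko-Pastur PCA
    noise estimation with Rician bias correction, voxel-wise diffusion
    tensor fitting, directional stretched-exponential, kurtosis and
    bi-exponential decay fitting along the tensor eigenframe, derived
    microstructure indices (FA, MD, Westin shapes, mean/axial/radial
    kurtosis, kurtosis anisotropy, compartment diffusivities and
    displacement scales), and one-way ANOVA group comparison with
    Tukey post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
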