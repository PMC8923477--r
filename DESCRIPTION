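Package: dualelastica
Title: Dual Projection Methods for Euler's Elastica Image Restoration
    and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grayscale image denoising, mask-based inpainting, and two-phase
    Chan-Vese segmentation with an Euler's elastica boundary regularizer,
    solved by a primal-dual saddle-point scheme in which a single dual vector
    field is projected onto a pointwise, curvature-dependent bound
    g = a + b*kappa(u)^2. Includes the dual total-variation baseline the
    scheme generalizes (the b = 0 limit), discrete gradient/divergence/
    curvature operators with reflecting boundaries, deterministic synthetic
    phantom and damage-mask generators, PSNR and Dice evaluation metrics,
    convergence-trace bookkeeping, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
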