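Package: fbmedm
Title: Distance-Matrix Completion for Fractional Brownian Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesis of Euclidean distance matrices (EDMs) of fractional
    Brownian motion trajectories with prescribed Hurst exponent, uniqueness
    certification of partial-EDM completion via a greedy graph-rigidity test,
    classical completion baselines (nuclear-norm FISTA, trajectory
    optimization, nearest-neighbour fill, database search, ensemble mean),
    a trainable denoising-diffusion prior over EDM images with four
    conditional inpainting schemes (DDPM, RePaint, DDRM, DDNM), evaluation
    metrics (missing-entry RMSE, Frechet distance with pluggable embeddings,
    displacement scaling, Maxwell collapse, rank fraction), and an
    application to imputation of chromatin-tracing (FISH) pairwise distance
    matrices.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
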