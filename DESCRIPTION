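Package: fpmtools
Title: Fourier Ptychographic Microscopy Simulation, Reconstruction and
    Digital Refocusing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Fourier ptychographic microscopy (FPM) of thin
    blood films: a forward simulator of angle-varied LED illumination
    image stacks with a blood-film phantom generator, iterative
    sequential Gauss-Newton reconstruction with embedded pupil function
    recovery (EPRY), digital refocusing by angular-spectrum or
    linear-weighting propagation (post-reconstruction refocusing, PRR)
    or by initial pupil modification (IPM), an extended depth of field
    (EDoF) compositing pipeline with red-blood-cell segmentation and
    candidate-parasite focal-plane selection, chromatic focus-shift
    correction for RGB imaging, and image-quality metrics (SSIM
    including a luminance-omitted variant, NRMSE modulo global phase).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
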