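Package: hilomfm
Title: Multi-Focus Microscopy Phase-Mask Design and HiLo Optical Sectioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stack for spatial-light-modulator based multi-focus
    fluorescence microscopy (MFM). Designs a single phase mask that images
    several specimen depths onto disjoint tiles of one camera frame using a
    weighted global Gerchberg-Saxton algorithm over sampled Fresnel/Fourier
    wave-optics propagation; reconstructs optically sectioned images from
    uniform/speckle illumination frame pairs with the two-frame HiLo
    algorithm; assembles axially scanned multiplexed frame pairs into a
    z-ordered volume; and ships a seeded synthetic optical simulator (3-D
    phantoms, speckle illumination, defocus imaging, multiplexed frame
    rendering) so that every stage can be tested without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
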