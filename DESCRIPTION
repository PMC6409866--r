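Package: nucleocarta
Title: Automated Cartography of FISH Signals in Asymmetric Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Maps fluorescence in-situ hybridisation (FISH) signals in
    falciform (hooked) sperm nuclei. Nuclei are segmented from the
    counterstain channel, structural landmarks (apical hook tip, tail
    attachment site) are discovered from a windowed interior-angle profile
    of the outline, and a structurally equivalent triangular mesh is built
    on each nucleus and on the population consensus shape. Binarised
    signal images are warped face-by-face onto the consensus by affine
    transforms, aggregated into composite frequency maps, and compared
    with a multi-scale structural similarity index (MS-SSIM*) and
    centre-of-mass distance statistics. Includes a synthetic falciform
    nucleus generator with planted signals and ground truth, and a
    command-line workflow for simulate/detect/warp/compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
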