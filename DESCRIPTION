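Package: LAFMkit
Title: Localization Atomic Force Microscopy with Conformational Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for applying localization atomic force microscopy (LAFM)
    to flexible membrane proteins.  Simulates AFM topograph stacks from
    atomic coordinates by dilating van der Waals spheres with a
    cone-with-spherical-apex tip, reconstructs enhanced-lateral-resolution
    LAFM images from registered stacks, scores reconstructions with masked
    structural similarity (SSIM), and clusters image stacks by protein
    conformation using a convolutional autoencoder, locally scaled
    affinities and spectral clustering, including hierarchical peeling of
    stable conformations and iterative registration-and-clustering with
    automatic cluster-count selection for unaligned stacks.  A synthetic
    pseudo-protein generator with ground-truth labels supports validation
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cae.R'
    'dsc.R'
    'hdsc.R'
    'io.R'
    'irec.R'
    'lafm.R'
    'register.R'
    'simafm.R'
    'ssim.R'
    'synth.R'
    'utils-image.R'
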