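Package: leafgen
Title: Structure-Aware Synthetic Training Data for Leaf Instance Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic plant images paired with per-leaf instance
    masks for training and evaluating leaf instance segmentation models.
    Plants are modelled procedurally with hierarchical stochastic parametric
    L-systems: a leaf grammar is embedded into a plant grammar so that every
    derived string decomposes into individual leaf organs. Strings are
    interpreted by a 3D turtle-graphics engine into labelled triangle meshes,
    which a software z-buffer rasterizer turns into occlusion-aware (visible)
    and amodal instance masks. Mask patches are textured by a deterministic
    procedural leaf-texture generator (or any plug-in generator) and composed
    over procedural or user-supplied backgrounds by cut-and-paste blending.
    Datasets are exported as COCO instance-segmentation annotations, and the
    package includes the evaluation metrics used for such data: average
    precision at an IoU threshold (AP@50, AP@75) and foreground mean absolute
    error, plus the conditional-GAN and L1 objective values used when
    training learned texture generators and refiners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
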