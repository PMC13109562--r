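Package: DenseLeaf
Title: Dense Leaf Detection Components: Progressive Pyramid Fusion,
    Crowded Query Refinement and COCO-Style Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational building blocks for set-based (DETR-family) dense
    leaf detection in plant canopies: a progressive top-down feature pyramid
    with an adaptive spatial/channel attention aggregation operator, crowded
    query refinement with class-agnostic non-maximum suppression and Top-K
    Hungarian one-to-many matching, a jointly trained auxiliary-head positive
    sample pipeline with randomized-confidence suppression, COCO-style
    AP/AR detection metrics, a sliding-window dataset tiling pipeline with
    density statistics, and a seeded synthetic generator of dense mutually
    occluding leaf scenes with pixel-accurate visibility. A miniature
    end-to-end detector, running on a built-in reverse-mode autodiff engine,
    wires the components together for CPU-scale training experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    clue,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
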