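Package: vortexcount
Title: Label-Free In-Flow Enumeration of Large Circulating Cells from
    High-Speed Brightfield Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects, measures and enumerates large circulating cells
    (candidate circulating tumor cells) in high-speed brightfield video of
    microfluidically released cells. Implements background subtraction,
    interpolated upscaling, binarization and morphological closing, connected
    component morphometrics (equivalent diameter, solidity, axial ratio,
    interior intensity range), morphometric gating, cross-frame appearance
    deduplication by nearest-neighbour tracking, per-mL rates and cohort-level
    mean + 2SD positivity calls. Also provides rule-based classifiers for
    immunofluorescence (CK/CD45/DAPI) cell calls and ALK break-apart FISH
    signal patterns, and a seeded synthetic-video generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
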