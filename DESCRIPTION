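Package: histoscar
Title: Color-Based Detection, Isolation and Quantification of Myocardial
    Infarct in Stained Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects, isolates and quantifies myocardial infarct regions in
    scanned histological sections stained with Masson's trichrome (MTS),
    hematoxylin and eosin (H&E), 2,3,5-triphenyltetrazolium chloride (TTC)
    or picrosirius red (PSR), using per-pixel RGB color rules specific to
    each stain.  Includes slide splitting into single-section images,
    binary-mask post-processing (cropping, dilation, artifact removal),
    relative infarct size and physical area quantification, serial-section
    volume estimation, diffuse-fibrosis quantification on MTS sections, a
    synthetic stained-section generator with exact ground truth for
    validation, and a command-line interface with reproducible run records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
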