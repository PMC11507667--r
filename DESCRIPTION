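Package: restable
Title: Reconstruction and Evaluation of Key Resource Tables in Scientific PDFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pages of born-digital PDFs that carry key resource tables
    (reagents, antibodies, organisms, software and their identifiers such as
    RRIDs), aligns image-level table-structure detections back to per-character
    PDF bounding boxes to materialize table grids, and repairs row
    over-segmentation caused by overflowing cells with a character-level
    autoregressive table language model fine-tuned into a cell-pair merge
    classifier.  Includes a simulator that derives labeled merge training pairs
    by wrapping intact table cells to constrained column widths, a stacked
    page classifier (recurrent line model feeding a linear SVM), an OCR cell
    pipeline behind an engine contract, grid table similarity (GriTS) metrics
    with content and topology variants, and a seeded fixture generator that
    renders ground-truthed resource tables to PDF for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
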