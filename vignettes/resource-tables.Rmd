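---
title: "Reconstructing key resource tables from PDFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing key resource tables from PDFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restable)
```

## The problem

Key resource tables — the three-column REAGENT or RESOURCE / SOURCE /
IDENTIFIER convention popularized by STAR*Methods — list the antibodies,
organisms, oligonucleotides, software and chemicals a study used, together
with identifiers such as RRIDs and catalog numbers.  In preprints these
tables usually exist only as typeset PDF content: recovering them as
structured grids requires (a) finding the pages that carry them, (b)
locating the table and its columns/rows on the page image, (c) aligning
that geometry back to the PDF's per-character bounding boxes, and (d)
repairing *row over-segmentation*: a cell whose content wraps onto several
text lines surfaces as several spurious rows.

`restable` implements this stack as four pipelines sharing a front end:

* **A** — image-detected column ranges + text-line rows from the PDF +
  heuristic row merging.  Robust columns, over-segmented rows.
* **B** — image-detected column *and* row ranges.
* **C** — pipeline B's topology with cell contents read by OCR from the
  page raster.
* **D** — pipeline A's grid repaired by a learned cell-pair merge
  classifier built on a character-level table language model.

Reconstructions are scored with grid table similarity (GriTS): tables as
matrices, aligned by their most similar two-dimensional substructure.

## Geometry conventions

All page coordinates are PDF points with the origin at the **top left** and
y increasing downward; grid indices are 0-based half-open; coordinate
intervals are closed.  Directed interval overlap
(`interval_overlap_ratio(a, b)`) is normalized by the *first* argument —
in every merging rule the first argument is the row being tested for
absorption, which makes the rule monotone in how much of that row is
covered.  `iou()` is the usual symmetric intersection-over-union and is
also used on grid-coordinate span rectangles for topology scoring.

## PDF reading and writing

No R-level PDF parser with character geometry exists in this stack, so the
package carries a deliberately small pair of its own: a writer that emits
uncompressed PDF 1.4 with Courier text (every glyph advances 0.6 em, so
exact gold character boxes are computable) and a reader that interprets the
matching operator subset (`Tf`, `Tm`, `Td`/`TD`, `Tj`/`TJ`, `m`/`l`/`re`/`S`).
The reader covers the born-digital subset the fixture renderer emits;
compressed streams and embedded fonts are out of scope and raise a
structured error.  Space glyphs advance the pen but carry no box — word
spacing is reconstructed from horizontal gaps during line grouping.

`group_text_lines()` buckets characters by top-y (`y_tol = 1` pt), splits
raw lines at gaps wider than 3 average character widths, and inserts a
space at gaps over 0.25 average widths.  These defaults reproduce the
visually obvious line and word structure of the rendered fixtures and are
exposed as arguments.  Raised superscripts have a different top-y than
their baseline and deliberately surface as spurious one-glyph lines here;
canonicalization repairs them downstream.

## Page detection

A stacked generalizer decides which pages are candidates:

1. a line-level LSTM reads the tokens of the current line and one previous
   line (window = 1; the context width is configurable) plus indicator
   features — horizontal/vertical primitive graphics overlapping the line,
   for the current and previous line, and the raw page number — through a
   logistic output.  Positive-class errors are weighted 50:1 to counter
   the heavy line-level imbalance.
2. a linear SVM (`e1071::svm`, `class.weights = c("0" = 1, "1" = 5)`) over
   the page's TF-IDF bag of words plus the count of lines the level-1
   model scores above 0.5.

Token embeddings are trainable and randomly initialized by default; a
word2vec-format text file of pretrained vectors can be supplied.  Without a
deep-learning runtime in this stack, the LSTM (and the transformer below)
is implemented in base R with hand-derived backpropagation over BLAS matrix
products; finite-difference gradient checks in the test suite pin the
implementation down.

## The table language model and row merging

The merge model is a character-level autoregressive transformer (GPT-style
decoder with causal multi-head attention) over table cell contents; one
training sequence is one cell plus an end-of-cell token.  The full-scale
configuration (6 layers, 6 heads, 384-dim embeddings, 256-character
context, batch 256, 250k steps) is expressible in `TableLM` config but is
never run here; tests and the acceptance script use the reduced model: 2
layers, 4 heads, 128 dimensions, 128-character context.  Positional
encodings are learned; dropout defaults to 0.1; unknown characters map to
a reserved id instead of erroring; cells are one sequence each,
right-ragged (no packing).

For merging, the LM head is replaced by a single sigmoid neuron reading
the final position of `upper <EOS> lower`, and the trunk starts from the
pre-trained weights (fine-tuned 2 epochs, Adam, learning rate 2e-4).  When
a pair exceeds the context, the *upper* string is truncated from its left
end: the junction carries the merge signal.  Row-level decisions average
the per-column probabilities and merge on a strictly-greater-than 0.5 row
score; empty-empty pairs vote like any other pair (a switch excludes
them).  After a merge the combined row is immediately re-tested against
the next row, so three-way overflow splits collapse by cascading — the
voting rule itself is pairwise, but multi-line overflows require the
cascade.  The header row never merges upward by default.

## Simulated overflow training data

Labeled merge pairs are simulated from intact tables: resource tables are
selected by the case-sensitive `RRID:` filter; tables whose widest row
(sum of its cell lengths) exceeds 90 characters qualify, with an
80-character budget when that width is under 100 and 90 otherwise.  The
budget is divided across columns in proportion to mean column width plus
the *population* standard deviation (the paperless choice between sample
and population conventions is documented here: population, so single-row
columns contribute their mean).  Integer widths are floored shares with
leftover characters handed out in decreasing weight order.  Cells are
wrapped greedily at spaces, hard-splitting tokens longer than the width
(sequences, URLs); the splitter records each break's kind so rejoining
reconstructs the original exactly — a property the acceptance suite checks
on 1000 random cases.  Consecutive lines of a wrapped cell are positives;
vertically adjacent intact cells are negatives; the 90/10 train/test split
is at table level so no table leaks across sides.

## Canonicalization rules

Two heuristics repair text-line rows before any learning is involved:

* **Rule 1** (needs TSR row rectangles): when consecutive text rows map to
  the same closest row rectangle and the tested row's text range lies at
  least 70% inside it, merge — this absorbs superscript/subscript lines.
* **Rule 2**: when a row has empty cells, the row above has none
  ("without empty cells" is read strictly: *all* cells non-empty), and the
  tested row's text range overlaps the closest row's text range by at
  least 50% (that closest row must be the one above), merge.

"Closest" is nearest by range-center distance, ties to the row above.
Because adjacent baselines at normal leading have disjoint y-ranges,
rule 2 fires only for tight or overlapping leading; this matches the
observation that the column-only pipeline A remains over-segmented on
overflowing tables, which is exactly the gap pipeline D closes.

## OCR pipeline

Cell crops are rasterized at 300 dpi with a 2 pt margin, converted to a
single channel and contrast-stretched between the 2nd and 98th intensity
percentiles (the enhancement method is a documented implementation choice,
exposed as arguments).  The OCR engine is a contract —
`function(image, mode = "single_block") -> text` — with a Tesseract
binding used when the executable is present (invoked in single-block
segmentation mode).  For fully self-contained testing the package draws a
*synthetic* monospaced raster font (glyph patterns derived from code
points — a marker bar plus a bit column — not real typography) and ships a
mock engine that reads it back; a seeded noise option emulates the
corruption real OCR shows on long uninterrupted tokens.  This exercises
every stage of the image pipeline, but says nothing about real Tesseract
accuracy on real scans.

## GriTS

`grits()` aligns ground truth `A` and prediction `B` by choosing row and
column subsequences maximizing the summed per-cell similarity `f`, then
reports

\[ F = \frac{2\sum f}{|A| + |B|}, \qquad
   P = \frac{\sum f}{|B|}, \qquad
   R = \frac{\sum f}{|A|}, \]

so `F` is algebraically the harmonic mean of `P` and `R` under the shared
alignment (asserted to 1e-9 in tests; the measure is sometimes loosely
described as a geometric mean, but the definitions above give the
harmonic form, which is what is implemented).  For content, `f` is the
symmetric normalized longest common *subsequence* `2·LCS/(|a|+|b|)`
(two empty cells score 1); the gt-normalized diagnostic ratio the OCR
example uses is available separately as `cell_content_similarity()`,
including a stricter substring mode for sensitivity analysis.  For
topology, `f` is the IoU of span rectangles expressed relative to each
cell's anchor, which keeps pair scores independent of alignment position.

Exact 2-D substructure alignment is combinatorial, so the optimizer is a
factored heuristic: dynamic-programming alignment over rows whose row-pair
scores come from a dynamic-programming alignment over columns, alternated
to a fixed point (at most 3 passes) from several deterministic starting
points (row-first, column-first, and one restart per single column pair).
`grits_exact()` enumerates all row/column subsequence alignments for grids
up to 5×5; on 200 random grids up to 4×4 per run the heuristic matches the
enumeration exactly, which bounds its error at the scale where the bound
is checkable.

## The fixture generator and what it does not show

`generate_resource_table()` draws seeded three-column resource tables
(antibodies with catalog numbers and RRIDs, mouse and fly genotypes with
bracketed alleles, oligo sequences, software, chemicals) and
`render_to_pdf()` typesets them in Courier while recording gold
table/column/row/cell boxes — the geometry the `mock_detector()` serves,
optionally jittered, in simulated image coordinates so the rescaling path
is exercised.  Overflow and superscript rates are controllable;
multi-page tables draw the header once and continue.  The page-detection
corpus generator emulates prose pages, reference-list distractor pages
that mention vendors and RRIDs in running text, and ruled table pages —
including oligo tables with no RRID token, so vocabulary alone does not
separate the classes.

Passing tests on these fixtures demonstrate the pipelines' internal
consistency: geometry alignment, over-segmentation and its repair, the
merge classifier's ability to recover simulated wraps, and the metric
implementations.  They do not demonstrate performance on real preprints:
real PDFs have proportional fonts, compressed streams, imperfect
detectors, richer glyph inventories and messier layouts.  The published
full-corpus numbers are not reproducible at desk scale and are not
asserted anywhere; the tests assert directions and properties (for
example, LM-based merging beats the column-only pipeline on overflow
fixtures, and over-segmentation depresses precision more than recall).

## Problem sizes and numerical choices

The test and acceptance runs use: a ~2,000-cell fixture corpus and 300
pretraining steps for the reduced LM; ~6,000 simulated pairs (240 tables)
for fine-tuning, with the table-level 90/10 split; a 2,500-pair
label-shuffled control; 20 rendered overflow tables for the pipeline
ordering comparison; 30-document corpora and 5 seeds for the page
detection comparison.  These sizes were chosen as the smallest at which
the compared quantities stabilize across seeds.  Other numerical choices:
Adam with gradient-norm clipping at 1.0; layer-norm epsilon 1e-5;
alignment DP ties broken toward the diagonal (maximal matched pairs);
column-boundary character ties go to the left column; detection column
ranges are padded by 1 pt, the last column widened by two average
character widths, and overlapping padded ranges split at their midpoint;
even-length medians of row cell counts take the lower middle value
(preferring fewer columns, since spurious extra cell detections are the
common failure).

## Known limitations

Rotated and right-to-left text, vector-graphic borders beyond axis-aligned
rules, de-hyphenation, spanning-cell recovery, and principled multi-page
stitching are out of scope (consecutive candidate pages with equal column
counts are naively concatenated and flagged).  The PDF reader supports the
uncompressed operator subset described above.  The Tesseract binding is
untested in environments without the executable, where the mock engine is
the test vehicle.
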