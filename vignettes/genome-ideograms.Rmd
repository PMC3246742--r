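---
title: "Drawing whole-genome ideograms: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing whole-genome ideograms: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoglyph)
```

## The rendering model

`genoglyph` treats a genome figure as a pure function of three inputs — GFF3
records, a configuration, and nothing else. There is no hidden state and no
randomness anywhere in the drawing path, which is what makes the
byte-determinism guarantee (identical inputs ⇒ identical PNGs and
coordinate files) testable rather than aspirational.

The geometric core is a single affine map. Backbones (chromosomes, linkage
groups, pseudomolecules — any record whose type matches the configured
backbone type) are laid out as parallel vertical bars, left to right in
input order, top-aligned. One scale `s` in pixels per unit is shared by all
backbones:

* fitted mode (default): `s = drawable_height / max(end − start)`, so the
  longest backbone exactly fills the drawable region;
* fixed mode: `pixels_per_unit` from the config; a fixed scale that would
  overflow the image is refused, and the error reports the minimal
  `image_height` that would fit, since silently rescaling would defeat the
  point of fixing the scale.

A position `p` on backbone `b` maps to `y = y_top + (p − start_b) · s`. The
continuous axis starts at the backbone's own start coordinate, so 1-based
GFF3 spans and 0-based genetic maps both work; coordinates are stored as
doubles throughout because centimorgan and cytological positions are not
integers. Top alignment (rather than bottom or center) matches how
whole-genome figures are conventionally read, with the ruler's zero at the
top.

Features dispatch to one of six glyph kinds. The default rule is: type
`centromere` → centromere overlay; span ≤ 1 unit → position glyph; anything
else → range bar. The one-unit threshold is deliberately unit-agnostic — a
1 bp SNP and a point marker at 37.4 cM are both "points", while anything
with measurable extent gets a bar. `[rule]` config sections can remap any
(source, type, class) selection to any glyph, which is how gene models
become a density histogram.

## Stacking, labels, and ties

Overlapping range bars on the same side of a backbone stack outward into
columns by greedy first-fit over the start-sorted intervals: a bar takes the
innermost column whose previous occupant ends strictly above it. This keeps
disjoint bars in one column (compact) and guarantees no two bars in a
column overlap — an invariant the tests check by brute-force pairwise
intersection. Position glyphs use the same algorithm on their pixel boxes.
Ties (identical starts) resolve by input order, which keeps the layout
deterministic.

Text labels get a single greedy downward sweep per (backbone, side) group,
ordered by anchor y then input order: each label is pushed down just enough
to clear the previous one plus a configurable gap, clamped inside the
image, and dropped (with a warning naming it) only when the bottom edge
leaves no room. A downward-only sweep is less clever than simulated
annealing or leader lines, but it is O(n log n), deterministic, and adequate
at whole-genome label densities; packages that need denser labelling should
thin their inputs instead.

## Histogram semantics

A histogram series counts each feature once, in the half-open bin
`[start + (k−1)·b, start + k·b)` containing its midpoint `(start+end)/2`;
the last bin is truncated at the backbone end and closed there. Midpoint
assignment, rather than counting a feature into every bin it overlaps,
keeps `Σ counts = n` exactly — the conservation property the suite verifies
on 200 random fixtures against an independent per-interval counter. Bin
size defaults to 400,000 units, the "genes per 400 kbp" display unit that
makes pericentromeric gene deserts visible at maize/soybean chromosome
scales; it is a plain config key for other unit systems.

Bar lengths are normalized by the maximum bin count **across the whole
image**, not per chromosome. Per-chromosome normalization would make every
chromosome's densest bin look identical and destroy exactly the
cross-chromosome comparison a whole-genome view exists to support. The
trade-off — one extremely dense region flattens everything else — is
documented rather than worked around.

## HSP clustering

"Adjacent HSPs within a window" is formalized as gap-threshold chaining:
within each (seqid, query Name) group, sort by start and merge any run in
which every gap (next start − running max end) is ≤ `w`. This is the
single-linkage transitive closure of the pairwise "gap ≤ w" relation, which
makes it order-independent and gives it two properties worth testing:
idempotence (re-clustering output is a no-op) and monotonicity (output
count never grows with `w`). The suite checks equivalence against a literal
pairwise closure merger on 1,000 random instances (n ≤ 200). The window
measures the *gap* (end-to-start), not start-to-start distance: a gap
formulation makes `w = 0` mean "merge only touching/overlapping segments",
which is the natural zero. Merged features keep the best (minimum) e-value
— 0.0 is the best possible — because downstream displays color hits by
significance, and gain `hsp_count` so the collapse is auditable. Groups
never merge across seqid or query: the displayed unit is "where does this
query hit", per query.

## Configuration resolution

Three layers, strict precedence: built-in defaults < INI file < command
line `--set` overrides. Within a feature's style: glyph-kind defaults, then
the class palette, then the first matching `[rule]` section in file order,
then a per-feature `color` GFF attribute. "First rule wins" (rather than
last) follows firewall-style matching: specific rules are written first and
general fallbacks last. The palette is a fixed list of ten high-contrast
colors assigned by first appearance of each class; from the eleventh class
colors repeat (index mod 10) and the legend remains the disambiguator.
Resolution is total by construction — every path ends in a concrete value —
and the suite asserts no style field is ever missing, including for
malformed inputs: an unparsable `color` attribute warns and falls back
rather than failing a whole render.

## Rasterization and text

Rendering records draw operations and rasterizes them in one pass over
function-local channel matrices (R's copy-on-write makes naive per-glyph
buffer updates quadratic in practice; the one-pass design keeps a
5,000-feature image under a second to rasterize). Compositing is plain
src-over alpha; there is **no anti-aliasing**, so the same inputs produce
the same bytes on every platform — the package treats reproducibility as a
contract and sharp 1-px edges as an acceptable price at ideogram scales.

Text uses a 5×7 bitmap face embedded in the source, scaled by integer
factors, with lowercase mapped to uppercase. A vector font engine would
look better but would tie output bytes to the host's font stack and
hinting; the bitmap face keeps the text path dependency-free and
deterministic, and ideogram labels (chromosome names, tick labels, legend
entries) fit comfortably in a terminal-style face. This is a deliberate
design choice, and the main known cosmetic limitation.

Rounding happens once, at rasterization and coordinate-file writing: pixel
boxes are `round()`ed to integers and clamped into the image, so the
coordinate file round-trips exactly and the containment invariant is exact
rather than "within ε".

## The ruler

Ticks follow the standard 1–2–5 decade rule: the step is the largest value
`{1,2,5}×10^k` giving between 4 and 10 major ticks over the longest span,
with minors at fifths. Ticks are computed on the relative axis (0 at each
backbone's top), because backbones from different unit systems or with
nonzero starts share one ruler; labels abbreviate thousands/millions
(`20M`). The ruler is optional (`ruler = off`).

## What the synthetic generator does and does not emulate

`generate_genome()` emulates the *shapes* of real whole-genome data: 10
chromosomes of 150–300 Mbp by default, a centromere of 2–5% of the span
near the middle, gene midpoints either uniform or depleted within ±10% of
the span around the centromere (acceptance probability 0.15 inside the
window — enough depletion to make density plots visibly non-trivial),
synteny blocks of 5–15% of a span paired with random partner chromosomes,
and per-query HSP chains with known lengths and gaps. Every quantity is
recorded in a truth structure (gene midpoints, centromere bounds, chain
gaps), so tests assert against construction rather than re-derivation.

It does **not** simulate sequence content, realistic gene length
distributions, clustered tandem arrays, or chromosome-specific density
profiles. Passing tests therefore demonstrate that the geometry, binning,
clustering and serialization are correct on data of realistic scale and
shape — not that any biological conclusion drawn from a real genome's
figure is right. Generation is seeded and restores the caller's RNG state;
the seed is part of the truth record.

## Problem sizes used by the test and acceptance suites

The suites run at the scales the tool targets while staying desk-sized:
1,000 random geometry triples for the affine oracle (tolerance 1e−9 px —
double precision, far below the 1-px rasterization grain); 200 random
histogram fixtures (half at the 400-kbp display bin); 1,000 random
clustering instances with n ≤ 200 HSPs against the O(n³) closure oracle;
one 5,000-feature, 10-chromosome end-to-end render; and byte-identity
checks over full reruns. These sizes were chosen as the package's own
statement of its operating envelope — several thousand features in a
single static image; far beyond that, a figure stops being readable before
the renderer stops being fast.

## Known limitations

* Raster output only (PNG); no SVG/PDF scene graph.
* Flat GFF3: `Parent`/`ID` hierarchies are not resolved, `##FASTA`
  sections are skipped, and sequence-ontology terms are not validated.
* Vertical layout only; no circular or horizontal mode, and no
  inter-chromosome connector arcs (a circular layout is the right tool for
  relationship-heavy figures).
* No anti-aliasing and a bitmap-only text face, as discussed above.
* Duplicate backbone seqids are an error rather than last-wins; the
  ambiguity is inherent in the input, and failing loudly was judged safer
  than guessing.
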