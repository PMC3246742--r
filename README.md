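# genoglyph

Whole-genome linear ideogram rendering from GFF3, in R.

Single-chromosome browsers are good at close-up inspection; they are poor at
the questions that need *all* chromosomes in one picture — where are the
gene-poor pericentromeres, how do duplicated blocks pair up across the
genome, where do a query's BLAST hits land. `genoglyph` answers those by
drawing every chromosome of a genome side by side as a vertical bar and
placing features on or beside the bars as configurable glyphs, then writing
three files per run:

1. a **genome PNG** (the ideogram),
2. a **legend PNG** (one swatch per glyph kind / feature class drawn),
3. a **coordinate file** (`name  x1  y1  x2  y2`, one row per drawn
   feature) from which clickable HTML image maps can be built.

Input is plain GFF3. Records whose type is a configured *backbone* type
(default `chromosome`; linkage groups and pseudomolecules work the same way)
define the bars; every other record is a feature tied to its backbone by the
`seqid` column, named by the `Name` attribute and grouped/colored by the
`class` attribute. Coordinates are unit-agnostic doubles, so base pairs,
centimorgans, and cytological units all render through the same affine map

```
y(pos) = y_top + (pos − backbone_start) × scale,
```

with one shared `scale` (px/unit) chosen so the longest backbone fills the
drawable height — drawn lengths stay proportional to real spans across the
whole figure.

Six glyph kinds cover the usual whole-genome displays: `centromere`
(overlay rectangle wider than the bar), `position` (dot/rect at a point),
`range` (bar beside the backbone; overlapping ranges stack outward in
columns), `border` (translucent band across the bar), `marker` (tick), and
`histogram` (feature density per fixed-width bin, e.g. genes per 400 kbp,
bar length `count / max_count × max_bar_length` normalized globally so
chromosomes are comparable).

Two converter utilities prepare display GFF from BLAST results:

- `blast_to_gff()` lifts 12-column tabular hits (`-outfmt 6`) — or a plain
  two-column query→peptide id map — onto genomic coordinates via a
  peptide-location GFF, carrying the e-value in the score column;
- `cluster_hsps()` collapses runs of same-query HSPs whose gaps are at most
  a window `w` into single intervals (single-linkage chaining; idempotent
  and monotone in `w`), tagging merged features with `hsp_count`.

A seeded synthetic-genome generator (`genome_spec()` / `generate_genome()`)
produces maize-scale fixtures with known ground truth — centromere
positions, gene midpoints, HSP chain gaps — so every claim above is tested
without downloading a genome.

## Worked example

```r
library(genoglyph)

gen <- generate_genome(genome_spec(n_chrom = 4, genes_per_chrom = 120,
                                   seed = 42))
records <- parse_gff(c(gen$backbone_gff, gen$feature_gff))

# draw gene models as a 400-kbp density histogram instead of range bars
cfg <- load_config(overrides = c("rule genes.match_class=gene",
                                 "rule genes.glyph=histogram",
                                 "rule genes.bin_size=400000"))
coll <- partition_features(records, cfg)
coll
#> <feature_collection> 4 backbone(s), 496 feature(s), 6 group(s)
validate_collection(coll)
#> <validation_report> 0 error(s), 0 warning(s)

r <- render_genome(coll, cfg)
r
#> <genome_render> 416x700 px, 450 drawn feature(s), 7 legend row(s)
write_outputs(r, "soy")
#> "soy.png"  "soy.legend.png"  "soy.coords.tsv"

head(r$drawn, 4)
#>    name    glyph  x1 y1  x2  y2        locator
#> 1 chr01 backbone 123 51 139 653 backbone chr01
#> 2 chr02 backbone 193 51 209 660 backbone chr02
#> 3 chr03 backbone 263 51 279 455 backbone chr03
#> 4 chr04 backbone 333 51 349 626 backbone chr04
```

The 496 input features produce 450 drawn rows because the 480 gene models
are aggregated into histogram bars (one row per non-empty bin) while the
centromeres and synteny blocks stay one row each; the 7 legend rows are the
backbone entry plus one per distinct glyph/class. Pixel boxes use the PNG's
own convention (origin top-left, y down), so `r$drawn` (and the coordinate
file) drop straight into an HTML image map via `write_imagemap()`.

From a shell, the same pipeline is:

```sh
Rscript inst/cli/genoglyph.R draw -o out \
    --set "rule genes.match_class=gene" --set "rule genes.glyph=histogram" \
    backbones.gff features.gff
Rscript inst/cli/genoglyph.R blast2gff -b hits.tsv -p peptides.gff -o lifted.gff
Rscript inst/cli/genoglyph.R clusterhsp -w 50000 -o merged.gff lifted.gff
```

Exit codes: 0 success, 1 I/O failure, 2 data validation failure.

## Configuration

An INI file (and/or repeatable `--set section.key=value` overrides, which
take precedence over the file, which takes precedence over built-in
defaults) controls image size, margins, spacing, background, title, ruler,
fixed or fitted scale, per-glyph colors/sizes/offsets/transparency, and
`[rule NAME]` sections that match features by `match_source` /
`match_type` / `match_class` and restyle them (including remapping the
glyph kind). Colors are any R color name or `#RRGGBB(AA)` hex; classes
without explicit colors draw from a fixed 10-color palette in
first-appearance order. See `?load_config` for the full key list and
`vignette` sources under `vignettes/` for the reasoning behind defaults.

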