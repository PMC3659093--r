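# tmakit

Metadata-aware tissue microarray (TMA) core tracking, scoring and exchange
for R.

A TMA packs hundreds of cylindrical tissue cores, punched from donor blocks,
into one arrayed recipient block; sections of that block are stained by
immunohistochemistry (IHC) and each core must then be located, scored and
linked back to the tissue it came from. Multi-centre studies add two further
problems: the scores from different laboratories must mean the same thing,
and the data must travel in a standard format. `tmakit` addresses the full
chain for researchers running such studies:

- a **Common Data Element (CDE) registry**: every scored field is governed by
  a registered metadata definition (name, definition, value domain, units,
  alternative names) and validated against it; the built-in set of 16 TMA
  CDEs records the corresponding TMA Data Exchange Specification (TMA DES)
  tag names as alternative names;
- **slidemaps**: XML layouts binding grid coordinates `(x, y)` (column, row,
  1-based from the top left) to donor-block identifiers, built from the
  layout spreadsheets laboratories actually keep (CSV), with gap and
  orientation-marker cells;
- **imaging**: a synthetic stained-core generator for fixtures, scanner-style
  JPEG export (`{slide}_{x}_{y}_{version}.JPEG`, 70 % resolution by default)
  and a batch **Deep Zoom (DZI)** pyramid tiler for smooth zoom/pan viewing
  — levels run from full resolution down to 1×1 by ceiling halving, so a
  `w×h` image has `ceil(log2(max(w, h))) + 1` levels, each tiled into
  `ceil(w/254)×ceil(h/254)` tiles with 1 px overlap;
- **scoring systems** with CDE-bound fields, including the **Allred score**
  for oestrogen-receptor (ER) status: `total = intensity + proportion` with
  intensity ∈ 0–3, proportion ∈ 0–5, the two components jointly zero or
  jointly positive (so totals span {0} ∪ [2, 8] and 1 is impossible), and
  `total ≥ 3` classified ER positive;
- **heatmaps** of a slide's scores (0 = pale yellow, 1 = intense yellow,
  2 = pale blue, 3 = intense blue; grey orientation cores, pink no-tumour,
  black cursor), virtual-slide montages, and scorer-vs-scorer discrepancy
  reports;
- a **hierarchical document store** (study → marker → scorer → slide XML
  documents) with advisory access grants, versioned immutable score records,
  tabular export carrying the donor linkage, and donor-block queries across
  markers;
- **TMA DES XML** import/export, using the standard's tag names wherever one
  exists and a `cg:` extension namespace elsewhere.

## Worked example

```r
library(tmakit)

reg <- load_default_cdes()
length(reg)
#> [1] 16
cde_lookup(reg, "block_identifier")$name   # lookup by TMA DES alternative name
#> [1] "Tissue Microarray Recipient Block Identifier"

allred_total(3, 5)
#> [1] 8
classify_er_status(c(2, 3))                # the borderline totals
#> [1] "negative" "positive"

blk <- recipient_block("B1", n_cols = 3, n_rows = 3)
cells <- matrix(c("DB7", "DB2", "DB3",
                  "",    "MARKER", "DB4",
                  "DB5", "DB6", "DB7"), nrow = 3, byrow = TRUE)
map <- parse_layout_table(cells, blk, "S1", "ER")
map
#> <tma_slidemap 'S1' (ER): 3x3 grid, 9 positions (8 used)>

img  <- generate_synthetic_core(synthetic_core_spec(size_px = 1000, seed = 7),
                                "S1", x = 2, y = 3)
path <- export_core_image(img, tempdir())  # 70% resolution JPEG
basename(path); dim(jpeg::readJPEG(path))[1:2]
#> [1] "S1_2_3_1.JPEG"
#> [1] 700 700

build_pyramid(img, tempdir())
#> <tma_pyramid 1000x1000, 11 levels, tiles 254+1 overlap, jpeg>

rec <- score_record("S1", 2, 3, "path1", "ER",
                    values = list(intensity = 2, proportion = 4, total = 6),
                    timestamp = "2013-05-01T09:00:00Z")
validate_score(builtin_systems(reg)[["allred"]], reg, rec)
#> valid
```

The slidemap holds 9 positions of which 8 are used (one gap), the exported
core file name encodes slide, coordinates and version, a 1000×1000 image
yields an 11-level pyramid, and the Allred record passes because
2 + 4 = 6 lies in the legal range with both components positive.

## Command line

A thin dispatcher over the same functions ships in `inst/cli/tmakit.R`:

```sh
Rscript inst/cli/tmakit.R simulate --root demo-store --study ST --markers ER,PR --seed 42
Rscript inst/cli/tmakit.R build-pyramids --in-dir demo-store/_images --out-dir demo-pyr
Rscript inst/cli/tmakit.R heatmap --root demo-store --study ST --marker ER \
        --scorer path1 --slide-id ST-ER-S1 --out-png hm.png
Rscript inst/cli/tmakit.R export --root demo-store --study ST --marker ER \
        --out scores.csv --format csv
```

Subcommands: `convert-layout`, `simulate`, `build-pyramids`,
`import-scores`, `heatmap`, `compare`, `export`, `query-donor`. Logs go to
stderr, data to files or stdout; errors exit nonzero.

## See also

The methods vignette (`vignettes/tma-scoring-pipeline.Rmd`) documents the
models, parameter choices, numerical conventions and limitations.
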