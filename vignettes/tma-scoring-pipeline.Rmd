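---
title: "The tmakit TMA scoring pipeline: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tmakit TMA scoring pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmakit)
```

`tmakit` manages the data side of tissue microarray (TMA) studies: which
donor tissue sits at which grid position of which slide, what each observer
scored there under which scoring system, and how all of it travels between
laboratories. This vignette is the package's own account of the models and
conventions it implements, the parameters that matter, and the choices made
where the design was genuinely open.

## The metadata model

Every scored field is governed by a Common Data Element (CDE): a named
metadata definition comprising an informal definition, a value domain,
units, and alternative names. Four value-domain kinds exist — enumerated
code lists, closed integer and real ranges (optionally stepped), and
pattern-constrained free text — and `validate_value()` is a pure membership
check against them. Treating an out-of-domain value as a *result* rather
than an error keeps validation usable both for form feedback and for batch
screening.

The built-in registry holds sixteen TMA elements: the layout vocabulary
(donor block, recipient block and its core diameter/spacing in mm, slice
number, x/y coordinates, slide and core identifiers, the position-used flag
that records deliberate gaps) and the scoring vocabulary (the three Allred
elements, percentage staining, HER2 IHC, binary staining). Where the TMA
Data Exchange Specification (TMA DES) defines a tag for the same concept,
that tag is stored as an alternative name, so `cde_lookup()` resolves either
vocabulary. Name lookups are case-sensitive exact matches: determinism
matters more here than forgiveness, since these names key machine-to-machine
exchange.

The scoring CDEs are published by name only in the exchange vocabulary, so
the package fixes their domains from the standard scoring conventions:
Allred intensity 0–3, proportion 0–5, total 0–8, percentage staining 0–100,
HER2 IHC {0, 1+, 2+, 3+}, binary {positive, negative}.

## Slidemaps and coordinates

A slidemap binds a slide and stain to a recipient-block layout. Coordinates
are `x` = column, `y` = row, both 1-based with the origin at the top left
and `y` increasing downward — the order in which a scorer works through an
array, starting at the first (top-left) core. Layout tables use three cell
conventions: an empty cell is a gap (`used = FALSE`), the case-insensitive
sentinel `MARKER` is an orientation core, and anything else is a donor-block
identifier. Donor identifiers may repeat (replicate cores); `(x, y)` pairs
may not. The sentinel is a package convention: orientation cores are a fact
of arrays but spreadsheet practice for flagging them varies, so one explicit
token beats guessing.

The slidemap XML dialect is defined by this package (the scanner vendors'
schemas are proprietary); its element names reuse the DES tag vocabulary
(`slide_identifier`, `block_identifier`, `block_core_size`, …) so the files
are self-describing to anyone who knows the standard. A missing
`sliceNumber` defaults to 1 with a warning rather than an error, because
single-slice studies commonly omit it.

## Synthetic core images

`generate_synthetic_core()` exists so that every image-touching operation
can be tested from code alone. It emulates the gross appearance of one
scanned IHC core: a circular tissue disc (pale eosin-pink tone, RGB
230/205/210) centred on a flat background grey, with `stained_fraction` of
the disc covered by randomly placed circular clusters whose colour
interpolates from the tissue tone at intensity 0 to a dark DAB brown
(94/61/34) at intensity 3. Cluster count scales with the target fraction
(about 12 at full coverage) and the cluster radius is solved so the expected
union area matches the fraction. The image is a deterministic function of
its spec, including the seed; the generator restores the caller's RNG state.

What it does **not** emulate: real tissue texture and nuclei, staining
heterogeneity and edge artefacts, out-of-focus regions, JPEG acquisition
noise, or torn/folded cores. Passing tests therefore demonstrate that the
geometry, bookkeeping and codecs of the pipeline are exact — not that any
staining quantification would work on real histology, which the package
deliberately does not attempt (manual scoring is the use case).

## Export scaling and file naming

Scanner-style export names each file `{slide_id}_{x}_{y}_{version}.JPEG`
and scales to 70 % resolution by default. Two conventions needed fixing:

- *"70 % resolution"* is interpreted as linear scaling of width and height
  (round-half-up, minimum 1 px), not as JPEG compression quality; quality is
  a separate knob (default 85). Both are exposed, so a deployment that reads
  the phrase the other way can configure it.
- Filename parsing is **right-anchored**: the last three underscore-separated
  tokens before the extension are read right-to-left as version, y, x, and
  everything left of them is the slide identifier. This makes identifiers
  containing underscores (`TRIAL_A`) round-trip, where a left-anchored parse
  would be ambiguous.

Resizing uses nearest-neighbour sampling: it is deterministic, exactly
reproducible across platforms, and adequate for scoring thumbnails; no
claim of resampling quality is made.

## Deep Zoom pyramids

A Deep Zoom image is a descriptor plus a tile tree. Levels run from index 0
(1×1) to `max_level` (full resolution), with
`max_level = ceil(log2(max(w, h)))`; each level is the ceiling-halving of
the one above. The package computes the level count by integer halving
rather than `log2` to avoid floating-point edge cases at exact powers of
two. Defaults follow the published Deep Zoom conventions: tile size 254,
overlap 1, JPEG tiles; a level of width `w` has `ceil(w/254)` tile columns
and each tile extends 1 px past its nominal edge wherever a neighbour
exists, which is what lets viewers blend seams.

Downsampling is a 2×2 box mean with ceiling dimensions (odd edges average
the available one or two pixels), rounded half-up to 8 bits *at every
level*, because tiles are 8-bit images on disk. This makes each level a
pure function of the one above, preserves flat fields exactly, and is
trivially checkable against a brute-force oracle. The test suite builds
pyramids with PNG tiles so that reassembling a level from its
overlap-cropped tiles can be compared pixel-for-pixel; JPEG remains the
deployment default for size. All internal pixel work is on lossless integer
arrays; lossy encoding happens only at file boundaries.

## Scoring systems and the Allred score

A scoring system is an ordered set of fields, each bound to a CDE, plus
optional derived-field rules. Five ship built in: `allred`,
`intensity-0-3`, `percentage`, `her2-ihc`, `binary`.

The Allred composite is `total = intensity + proportion` with intensity in
0–3 and proportion in 0–5. The package enforces the standard coupling rule:
the components are either both zero (no staining anywhere) or both positive
(any staining has some intensity and some extent), so a total of 1 cannot
occur and legal totals span {0} ∪ [2, 8] — 16 of the 24 component pairs.
ER classification places the boundary between the borderline totals:
`total ≤ 2` is ER negative, `total ≥ 3` ER positive. Both the coupling rule
and the threshold follow the standard published Allred system; the exchange
vocabulary itself names the elements without restating the arithmetic.

Score records are immutable and versioned: "updating" a score appends a
record with the next `record_version` for that core/scorer/marker, and all
views read the latest version. This preserves a complete audit trail, which
multi-observer QA work needs. Timestamps are ISO-8601 and supplied by the
caller (or an injected fixed clock), never read implicitly from the wall
clock inside the pipeline commands — the price of byte-reproducible runs.
Records carry an optional free-text note, stored opaquely.

## Heatmaps and comparison

The heatmap draws one uniformly coloured square per grid position. The 0–3
legend uses fixed RGB values — pale yellow (255,255,204), intense yellow
(255,215,0), pale blue (173,216,230), intense blue (0,0,205) — with grey
(128,128,128) orientation cores, pink (255,192,203) no-tumour cores, white
unscored cells and a black outline on the current position. The published
description of the interface names the colours without hues, so these
concrete values are package choices, overridable in `heatmap_spec()`.
Systems beyond the 0–3 legend (Allred totals, percentages) interpolate
linearly between the pale-yellow and intense-blue endpoints over the
system's range. "No tumour" is a record *status*, not a numeric value: it
is an observation about the core, not a point on the scale.

`compare_scorers()` compares the latest values of two observers on the
cells both scored; the discrepancy report renders as a third heatmap
(green agree / red differ). Only counting is implemented — inter-rater
statistics such as kappa are out of scope.

## The document store

The store is a plain directory tree of XML documents mirroring the
collection hierarchy study → marker → scorer → slide, with the slidemap
stored once per marker collection and referenced from each scorer's
document by relative path plus SHA-1 checksum. A directory tree rather
than an embedded XML database keeps every document diffable, versionable
and greppable while preserving the same collection semantics; there is no
hidden state, so closing and reopening a store is a no-op by construction.
Names beginning with an underscore are reserved at the store root (the
simulator keeps its image tree in `_images`).

Permissions are advisory grants enforced by the library API: a scorer may
open or write documents only under granted (study, marker) pairs.
Authentication, transport security and concurrent multi-user semantics are
deployment concerns, not methods, and are out of scope. Patient identities
are never stored — the donor-block identifier is the only link outward,
and joining it to clinical data happens in systems with the appropriate
governance.

## TMA DES exchange

Export writes each internal field under its DES tag where the supported
vocabulary has one (`block_identifier`, `block_core_size`,
`block_core_spacing`, `slide_identifier`,
`core_histo-repository_donor-block`,
`core_results_percent-tissue-staining`, and
`core_results_tissue-intensity` for the generic 0–3 intensity system) and
everything else as elements in the `cg:` extension namespace
(`urn:tmakit:tmades-extension`): coordinates, slice number, position-used
flags, and the system-specific fields — Allred components, HER2, binary —
which have no direct DES equivalent. Two routing choices deserve note:

- Coordinates are exported as per-core `cg:x`/`cg:y` elements rather than
  reconstructing the DES `block_array-hash` structure, whose internal
  layout is not part of the supported vocabulary.
- The *generic* intensity score maps to `core_results_tissue-intensity`
  (the standard's general staining-intensity value), but the *Allred*
  intensity component stays an extension element: it is a component of a
  specific composite system, and flattening it into the general tag would
  lose that meaning.

Besides the tag vocabulary, the writer emits only the DES structural
elements `tma`, `header`, `block`, `slide`, `core`;
`tmades_conformant()` verifies that every element of an export is
structural, a known DES tag, or `cg:`-namespaced. The import side is
tolerant: unrecognised vendor elements are retained as opaque annotations
and logged, and a core without coordinates imports as an unplaced core with
a warning rather than failing the document. A slide without an identifier
is an error — nothing downstream can be keyed without it. The header is
minimal (origin, date, generator with package version); validation against
the official DES DTD is not attempted.

## Determinism and numerical conventions

- One master seed drives every simulated quantity; per-core seeds are
  derived arithmetically from it, and seeding is scoped so the caller's RNG
  state is untouched.
- Rounding is half-up throughout (`floor(x + 0.5)`), not banker's rounding.
- Doubles are serialised to XML with 17 significant digits, so
  parse ∘ serialize is exact.
- Pixel equality tests always go through PNG; JPEG is never asserted on.
- CSV/score values that look numeric are read back as numbers so domain
  validation behaves identically after a round trip.

## Scales used by the test suite

The suite verifies the Deep Zoom geometry against an independent halving
oracle over all of [1, 300]² and tile reassembly on 50 random images (sides
up to 48 px; up to 6 px when exercising 1-px tiles); XML dialect and
filename round trips run on 200 randomized instances each; the end-to-end
determinism check uses a 3×3, two-marker, two-scorer study at 48 px image
size, small enough to run comfortably while touching every pipeline stage.
These sizes are the package's chosen test conditions; the operations
themselves are size-agnostic.

## Known limitations

- No whole-slide de-arraying: the pipeline starts at individual core
  images, as produced by scanner vendors' splitting software.
- No automated staining quantification and no inter-rater statistics
  beyond discrepancy counts.
- The store is single-process; advisory grants are API-level, not
  authentication.
- The synthetic generator is a geometric fixture, not a histology
  simulator (see above).
- TMA DES conformance is structural (tag vocabulary + namespaces), not DTD
  validation.
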