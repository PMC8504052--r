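---
title: "Composing genome track figures and Hi-C analytics with trackkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing genome track figures and Hi-C analytics with trackkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackkit)
```

`trackkit` is a toolkit for genome track figures in which the figure and
the data behind it are one object graph: every panel is a *track* with a
two-method contract — fetch the data for a genomic range, draw that
fetched payload — and a figure is a `+`-composition of tracks. This
vignette is the package's account of the conventions, statistics and
design choices underneath that surface.

## Coordinates

All in-memory coordinates are **1-based, fully inclusive**, the
convention of the region strings users type into a genome browser
(`chr9:4,000,000-6,000,000`). On-disk half-open 0-based formats (BED,
bedGraph, BEDPE) are converted once, at the reader boundary; GTF and
4DN pairs positions are already 1-based and pass through. A consequence
worth spelling out: the bedGraph record `[100, 200)` becomes bases
101..200, so the 1-based query `chr1:100-101` overlaps both it and its
predecessor `[0, 100)` — the boundary case the readers' tests pin down.

Region queries use **any-overlap** semantics, never containment: a gene
half outside the window is still returned (whole, so its span can be
drawn running off the panel edge). Readers never clip records; clipping
for display is the renderer's job.

Binning (`range_to_bins()`) anchors at the *query* start, not at
absolute position 0, so a panel shows exactly the requested window; the
last partial bin is kept. The one exception is the contact-matrix
reader, whose bins are fixed by the file's genome-wide grid: requested
ranges are expanded outward to that grid so that matrix cells are always
whole file bins.

Navigation rounds half away from zero and enforces a minimum window of
2 bp; zooming preserves the window center to ±1 bp, and sliding at a
chromosome edge slides the window flush against the boundary rather
than truncating it. These rules are conventions we fixed, not values
with a scientific ground truth; they are frozen in the test suite.

## Indexed access

Text readers answer a region query through a tabix index when the file
is bgzipped with a `.tbi` sibling (via Rsamtools), and otherwise by a
filtered linear scan. The two paths must be *bit-identical*; the test
suite runs them against each other. Two deliberate exceptions:

* **BEDPE/pairs** always linear-scan. A standard tabix index covers only
  the first anchor, and the arcs track's "either anchor overlaps" rule
  would silently miss records whose second anchor alone is in view.
* **bigWig** is delegated wholly to `rtracklayer`; it is a binary format
  with its own index and is excluded from the bit-exact oracle suite
  (bedGraph is the reference signal format for tests).

Cooler/HDF5 containers are out of scope for this build (no HDF5 reader
in the dependency set); the supported contact-matrix container is the
HiC-Pro sparse text pair — a bins BED (`chrom start end id [weight]`)
plus upper-triangle `bin1 bin2 count` triplets. Absent triplets are 0,
on-diagonal windows are symmetrized exactly, and `balanced = TRUE`
multiplies cell `(i, j)` by `weight_i * weight_j`, turning non-finite
weights into `NaN` cells. Balancing weights are only ever *read*;
computing them is a normalization problem outside this package's scope.

## The Hi-C statistics

The analytic tracks name widely used statistics whose exact formulas
vary across the literature; the package adopts the canonical published
definitions and parameterizes the rest.

**Directionality index** (window `w` bins, default 5): the signed
chi-square-like contrast of upstream versus downstream contact sums
defined in the TAD literature. `DI` is *not* invariant to scaling the
matrix by `c > 0` — it scales by `c` — which the tests assert as a
property rather than a bug. Bins within `w` of a matrix edge are `NaN`.

**Insulation score** (diamond half-width `w` bins, default 5): the mean
of the `w × w` diamond of contacts crossing each bin, reported as a
log2 ratio to the mean diamond over the window. The log-ratio form makes
it scale-invariant (also asserted as a property). `normalize = "none"`
exposes the raw diamond means.

The defaults of 5 bins are chosen for the package's working scale of
tens-of-kilobase bins over sub-megabase windows; at 40 kb bins
genome-wide, the literature's windows correspond to ~50 and ~12 bins
respectively, and both are plain `window =` properties on the track.

**Virtual 4C** averages the anchor bins' rows; a single-bin anchor is an
exact row extraction. `NaN` propagates — an all-`NaN` anchor row yields
an all-`NaN` profile. Analytic code never converts `NaN` to a number;
what to do with missing bins is a display decision.

**Differential matrices** compare two conditions as
`z(A) − z(B)`. Whether the z-scoring should be per-distance or global
is genuinely open; per-distance is the default because contact
frequency decays steeply with genomic distance, and z-scoring each
diagonal separately removes that shared decay so the difference
highlights *local* structure rather than reproducing the decay curve.
`method = "global"` selects the single-distribution variant. Population
(not sample) SD is used; a diagonal with fewer than two finite entries
or zero SD becomes 0 rather than `NaN`-flooding the difference.

## Composition semantics

`+` follows a small closed rule set: track + track opens a frame;
frame + track appends; frame + frame concatenates (one shared x-axis
per figure — nesting is deliberately not supported); anything + feature
patches style properties; anything + coverage attaches an overlay
painter. Two decisions were genuinely open and are fixed as follows:

* A `feature()` binds to the **preceding** track by default (the last
  track composed), with `scope = "all"` for frame-wide patches. Binding
  forward instead would make `x_axis + feature(...) + track` ambiguous
  while a chain is being built.
* Composition is **immutable**: operands are never modified, so one
  track object can appear in two frames with independent styling, and
  the CLI can replay a chain through the same functions with no hidden
  state. This is also what makes navigation stateless — rendering a
  browser state is defined to equal a fresh render of its frame at its
  current range, byte for byte.

Style properties are validated at set time (the offending key is
named); unknown keys are preserved untouched, because custom tracks need
a place for their own options.

## Rendering

One grid-based drawing path serves all four output formats (SVG, PNG,
JPEG, PDF). Determinism is a contract, not an accident: SVG output is
canonicalized — comments/metadata stripped, embedded-image ids
renumbered in order of appearance — so identical input gives
byte-identical files, which is what the CLI/API parity and navigation
tests compare. Panel layout is exposed as data (`layout_frame()`):
panels tile vertically in composition order, with heights proportional
to each track's `height` property (inches). Tests assert on layout
plans, fetch payloads and geometry specs (`arc_geometry()`,
`layout_gene_rows()`, `matrix_panel_transform()`), never on decoded
pixels; images are checked only for existence and byte determinism.

Numerical display choices: matrix color scales default to `log1p` with
an automatic clamp at the 2nd/98th percentile of finite values
(symmetric about zero for differential matrices); colorbars are labeled
in pre-transform data units; `NaN` cells render as background. The
triangular matrix style rotates the upper triangle 45°, with depth
defaulting to half the view span (`depth` property). Gene rows pack by
greedy first-fit; arcs are half-ellipses with apex height proportional
to genomic span, normalized to the tallest arc in view, and line width
proportional to score when scores exist. A failing track renders as an
error placeholder panel so one broken path does not kill a ten-track
figure; `strict = TRUE` inverts that choice and produces no file.

The joint 2D view places a (possibly off-diagonal) heatmap of contacts
between a vertical and a horizontal range at the center, with 1D frames
along the matching axes (left/right rotated 90°). Its center is defined
as `read_contact_matrix(source, range_v, range_h)` and its side panels
as `frame_fetch_all()` of each side frame — the same functions users
call — so "what the figure shows" is testable as data equality. The
side-frame extent relative to the 3.6-inch center square is a knob
(`side_size`, default 0.6× the frames' natural heights).

## The CLI

The grammar is frozen: verbs (`add`, `feature`, `coverage`, `goto`,
`joint`, `plot`, `fetch`, `gen-fixtures`) separated by a literal `-`
token, `key=value` keyword arguments, global flags (`--strict`,
`--dpi`, `--width`, `--config`) first. `run_cli()` replays the verbs
through `make_track()`/`compose()`/`render_frame()` — there is no second
composition implementation — which is why a CLI chain and its paired API
composition produce byte-identical SVGs. A YAML `--config` file (one
track per entry, same key=value schema) covers reproducible figure
recipes. `parse_cli_chain()` / `format_cli_chain()` round-trip, so
programs are data.

## The synthetic dataset

`generate_dataset()` writes every supported format from one seed, with
the planted ground truth in `manifest.json`. The contact matrices come
from `planted_matrix()`: an exponential distance-decay base
`round(100 · exp(−d/5))` (counts ~100 at the diagonal, decay length 5
bins), +50 inside planted TAD blocks, planted loop strengths of 60-80
at chosen cells, and optional seeded Poisson resampling. These constants
keep every statistic far from degeneracy: block bonuses step the
insulation diamond by ~half the local signal, and loop strengths stand
several diagonal SDs above their distance's background. The default
genome is two chromosomes of 500 kb and 300 kb at 10 kb resolution
(50 + 30 bins) — large enough for two boundaries and two cross-boundary
loops, small enough that the full property suite (hundreds of region
queries per format, fifty 40×40 reference-implementation comparisons,
and a few dozen rendered figures) runs in about a minute.

What the generator emulates — and what it does not: deterministic
piecewise signal with known per-interval values, gene models with known
exon structure, loops whose BEDPE anchors are exactly the planted bins.
It does not emulate read-level noise, mappability artifacts, copy-number
effects, trans contacts, or unbalanced coverage. Passing tests therefore
demonstrate that the *computations and contracts* are correct on records
of realistic shape; they do not certify biological robustness on noisy
real matrices, where window choices and balancing quality dominate.

## Known limitations

* One chromosome per axis: no split-axis/multi-chromosome frames, no
  liftover awareness.
* Analytic tracks compute on the fetched window, so their edge bins are
  `NaN` inside the view; fetch a wider range (or plot one) when scores
  at the window edge matter.
* `.cool`/`.mcool`/`.hic` binary containers and BAM tracks are not
  read; convert to HiC-Pro text or bedGraph/bigWig upstream.
* Matrix ranges are snapped outward to the file's bin grid; a window
  not aligned to the grid shows the enclosing whole bins.
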