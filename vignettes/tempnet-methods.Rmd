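---
title: "Models and methods behind tempnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tempnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempnet)
library(dplyr)
```

tempnet analyses dynamic perturbations — dose series, time series, or
dose-over-time designs — on biological networks. This vignette explains the
data model, each analytic component and its assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## The temporal network model

A network is a set of nodes (genes, CpG islands, proteins — any entity) and
directed or undirected edges. tempnet adds one dimension: a **frame**, one
condition of an ordered experimental series. A frame can be a time point
(`T8`), a dose (`D1000`), or a dose-over-time combination (`T8_D1000`). The
container is a node set, an ordered frame vector, and a long-format edge
table with one row per (source, target, frame). A static network is the
degenerate single-frame case, which keeps every analytic uniform: there is
no separate static code path.

Conventions, fixed once:

* **Directedness** is a single per-network flag, default directed, because
  the regulatory interpretation ("A regulates B") is directional.
* **Duplicate edges** within a frame collapse to one; **self-loops** are
  kept.
* **Node ids** are case-sensitive, whitespace-trimmed strings. No
  identifier normalization happens in the container; symbol-based
  annotation lives in the annotation store.
* For undirected input we treat each listed row as one interaction and do
  not merge `A B` with `B A`; undirected files should list each interaction
  once.

## File formats and automatic detection

Four text dialects are read: two-column edge lists, labelled 0/1 adjacency
matrices, Cytoscape SIF (`source relation target`), and long-format dynamic
edge tables (`source target frame`). The delimiter is sniffed in a fixed
order — tab, comma, semicolon, any whitespace — and the first candidate
producing consistent column counts wins.

Format detection is deterministic and total. The discriminating rules, in
order: a square grid of 0/1 cells with row and column labels is an
adjacency matrix; two columns throughout is an edge list; three columns is
SIF when the extension is `.sif` or when the middle column repeats over a
small token set that never appears as an endpoint, and a dynamic edge list
when the third column repeats over a small label set (or matches declared
frame labels). Anything else is `unknown` and is reported, never guessed.

One genuine ambiguity deserves a note: a 2×2 labelled 0/1 grid and a
two-column edge list whose ids happen to be "0"/"1" cannot be told apart on
content grounds alone. We commit to the all-cells-in-{0,1} square-grid rule
and require adjacency matrices to carry row *and* column labels; unlabelled
numeric grids are rejected rather than misread.

## Degree analytics

Degree centrality is split into three components: **inner degree** (edges
pointing into a node — the node is regulated by many neighbours), **outer
degree** (edges pointing out — the node regulates many others), and their
sum, the **total degree**. High-degree HUB nodes are the pivotal points
whose disruption tends to break the system, which is why the table is
computed per frame: a node's importance can be transient.

Numerical conventions: a self-loop contributes 1 to inner and 1 to outer
(total +2) in a directed network; in an undirected network the split is
meaningless and inner = outer = total = incident edge count, a self-loop
counting once. These choices are arbitrary but frozen and tested.

Threshold filtering retains nodes whose chosen degree is at least the
cut-off, then keeps edges with both endpoints surviving — so the filter is
monotone: raising the threshold never adds a node. First-degree
neighbourhoods take the union of in- and out-neighbours, because a gene's
local story includes both its regulators and its targets.

**Persistent edges** between two frames are the intersection of their edge
sets. Edge identity is the ordered (source, target) pair; the relation
label is ignored, since dialects that carry relations (SIF) and those that
do not must compare equal. Companion counts (sizes of both frames, the
intersection, both differences) come along via `edge_turnover()`.

## Force-directed layout

Node positions come from a Fruchterman–Reingold-style spring model:
attraction $d^2/k$ along every edge, repulsion $k^2/d$ between every node
pair, displacement capped by a temperature cooled linearly from its start
value to zero over the iterations. For an isolated connected pair the two
forces balance exactly at $d = k$, so the `natural_length` parameter (default
0.3, dimensionless pre-normalization units) is literally the equilibrium
edge length — a property the tests exploit. Defaults: 300 iterations,
initial temperature equal to `natural_length`.

Determinism is part of the contract, not an accident: initial positions are
drawn from the seed in canonical (sorted) node order, so the same inputs and
seed give bitwise-identical output and permuting the node list changes
nothing. Self-loops exert no force. Final coordinates are min–max
normalized to $[0,1]$ per axis; a degenerate axis (single node, or all
collinear) maps to 0.5.

The third dimension is a closed-form fold of the 2D sheet:

$$z = 0.8\,y\,\sin(\pi y) + 0.8\,x\,\sin(\pi x)$$

with $x, y \in [0,1]$ the normalized layout coordinates. The surface is a
smooth dome: $z = 0$ whenever both coordinates are 0 or 1, the maximum
$z = 0.8$ sits at the centre $(0.5, 0.5)$, and $|z| \le 0.8(x+y) \le 1.6$
everywhere. Feeding the formula normalized coordinates is a documented
precondition (the source formulation does not pin the input range; we fix
it at $[0,1]$ so the dome shape is scale-independent). Non-normalized input
is an error rather than a silent clamp.

Positions are held fixed across animation frames by default — the eye
should track colour and wiring changes, not node movement — with
`relayout_per_frame` available when per-frame geometry is wanted.

## Expression colour mapping

The colour scale domain is $[-M, +M]$ where $M$ is the maximum absolute
value over **all** nodes and frames jointly. Using the global maximum
guarantees two things: a strong downregulation is exactly as saturated as
an equally strong upregulation, and the same value has the same colour in
every frame of an animation, so frames are comparable.

Mapping is linear per RGB channel: $-M$ is full red (255, 0, 0), $+M$ full
green (0, 255, 0) or full blue for the red/blue palette, and 0 a near-black
neutral (30, 30, 30) — a dark-to-bright ramp in both directions. Values
outside the domain clamp (this cannot happen when the scale was built from
the same series, but can when a scale is reused on new data); missing
values render neutral grey `#808080`, deliberately distinct from the
0-value colour so "no data" never masquerades as "no change". The mapping
is total: it never errors on a value. Units are the user's own — intensity,
log fold change, anything — since only the ratio to $M$ matters.

Node size maps linearly from $[0, \max \text{degree}]$ to a configurable
radius range (default 4–16 display pixels), with the maximum taken over all
frames so radii are comparable across an animation.

## Annotation store and pathway ranking

Biological context comes from three flat per-species tables (Homo sapiens,
Rattus norvegicus, Mus musculus): gene info (symbol, Entrez id,
`|`-separated synonyms, gene type), gene→pathway and gene→disease
associations — the local emulation of pathway, toxicogenomics and gene
databases. Lookups are total: an unknown gene yields an empty record
flagged unannotated, never an error, because networks routinely contain
ids outside any vocabulary.

Pathway ranking counts **distinct genes** per pathway among the queried
nodes (not association rows — duplicated query ids cannot inflate a
pathway), sorts by count descending with alphabetical tie-break, and
reports the top 10; the full ranking is exportable and the top-10 table is
always a prefix of it.

## Animation assembly and export

An animation holds one frame per series condition. Three modes fall out of
the inputs: static network + multi-frame expression (colour animation),
dynamic edges + no expression (wiring animation), and both (the combined
view that shows whether expression changes travel with interaction
changes). Frame labels of a multi-frame network and expression series must
be reconcilable — identical, or explicitly mapped — and a mismatch is an
error that prints both label sets.

Rendering decisions: edge changes are hard cuts (an edge is present or
absent per frame; no tweening — the data are discrete conditions, and
interpolated intermediate states would be fiction); nodes with no incident
edge in a frame stay drawn in grey so the geometry stays comparable, with
`drop_absent` to remove them; default GIF frame duration is 1000 ms,
configurable. The stepper clamps at both ends rather than wrapping.

Exports: animated GIF, numbered PNG sequence (`frame_001.png`, ...), a
self-contained HTML page embedding the frame data with forward/backward
controls (a static artefact, not a server), and a single-frame SVG written
directly as text. The GIF encoder is built into the package: frames are
quantized to a fixed 5×5×5 colour cube and encoded with byte-aligned LZW
literal codes (7-bit minimum code size, clear codes emitted before the
dictionary would widen past 8 bits) — modest compression, maximal
portability, and the block structure is verifiable by the bundled frame
counter.

The 2D line graph is the static companion for a node selection (typically
a first-degree neighbourhood): one line per node over the ordered frames,
with the underlying tidy table written next to the figure so the numbers
behind every plot are inspectable.

## The synthetic study generator

`fixture_spec()` / `simulate_fixture()` generate complete studies in the
exact dialects the readers consume, with every planted quantity recorded in
a ground-truth JSON. The generator emulates the structure of a repeat-dose
exposure experiment with recovery:

* four frames — three exposure days and a washout;
* a focal hub connected to 10 neighbours on day 1 (7 regulators, 3
  targets), growing to 71 interactions by day 3 (49 in, 22 out), keeping
  exactly 50 (35 in, 15 out) after washout and gaining none;
* day 2 sits at 40 interactions — the reference schedule only constrains
  day 2 to lie between day 1 and day 3 (interactions grow during
  exposure), so a monotone midpoint was chosen once;
* a background of 120 genes whose random edges evolve by a birth/death
  process (initial density 0.02, birth 0.01, death 0.2 per frame),
  excluded from the hub so hub persistence counts are exact;
* planted expression trajectories — a strong downregulation at the second
  frame (0.1, −1.2, −0.4, −0.1) and a strong upregulation peaking at 1.8 —
  on a noise background clamped to $[-1, 1]$, so the planted extreme is
  provably the series maximum and therefore the colour-scale boundary;
* miniature annotation tables over 12 pathways and 5 diseases.

New hub partners are drawn from a shuffled pool and never recycled, which
makes the per-transition persistence counts exactly the configured retain
counts. One seed governs everything; the same spec is byte-identical across
runs.

What the generator does **not** emulate: scale-free degree distributions,
correlated expression between interacting genes, biological edge semantics,
or measurement noise models. Passing the recovery suite therefore shows the
*pipeline* is faithful (what was planted is recovered through file I/O,
analytics and export), not that the method would make biological
discoveries on real data.

```{r fixture-demo}
sim <- simulate_temporal_network(fixture_spec(seed = 1))
degree_over_time(sim$net) |> filter(node == "HUB1")
```

## Problem sizes and runtime choices

The test and acceptance workloads run at desk scale: random graphs up to
n = 50 for the degree oracles (100 seeds), 20×20 adjacency equivalence,
a 101×101 grid for the z-formula bound, the 121-node reference study for
end-to-end recovery, and small raster sizes for export checks. These sizes
were chosen so each property suite completes in seconds while still
exercising every code path; all scale parameters are arguments, not
constants.

## Known limitations

* The force model is $O(n^2)$ per iteration — fine into the low thousands
  of nodes, not for genome-scale graphs.
* GIF output uses a fixed 125-colour cube; smooth colour ramps show mild
  banding.
* SIF relations are carried through parsing and writing but ignored by all
  analytics (including edge persistence).
* The HTML export targets any modern browser but embeds all frame data
  inline; very large animations produce large files.
* Enrichment statistics (e.g. hypergeometric tests) are out of scope:
  pathway ranking is by raw membership count.
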