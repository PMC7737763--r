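---
title: "Methods: per-residue validation metrics and the radial report"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue validation metrics and the radial report}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainview)
```

# Scope and model of the data

`chainview` evaluates a protein coordinate model residue by residue and
presents the results radially. The package assumes crystallographic-style
inputs: a PDB coordinate file (optionally two iterations of the same model),
and, for density-fit scoring, either structure factors as amplitude/phase
pairs or a precomputed map. All analyses are local (per residue); no global
indicators such as R-factors are computed.

A coordinate file is parsed into a chain → residue → atom hierarchy. Rules
applied at this stage, chosen where the underlying formats leave room:

* **Altlocs.** One conformer per atom is kept: highest occupancy wins, ties
  resolve to file order. Single-valued per-residue metrics need a single
  conformer; averaging over conformers would blur exactly the signal the
  report is meant to expose.
* **Amino-acid gate.** A residue enters the cascade iff its name is one of
  the 20 canonical codes (extensible via an allow-list, e.g. `MSE`) *and*
  the backbone atoms N, CA, C are present. Reference libraries cover the
  canonical types, so non-standard monomers would only ever classify
  "unknown".
* **Hydrogens** are parsed but excluded from B-factor and fit aggregation by
  default: at typical resolutions they are riding constructs, not
  experimentally resolved scatterers. A flag includes them.
* **Multi-MODEL files:** only the first MODEL block is read. The report is
  per-iteration, not per-NMR-model.
* **Resolution** comes from the `REMARK 2` record when present; its absence
  is legal and routes percentile queries to the all-data entry.

# Backbone conformation

φ(i) is the C(i−1)–N(i)–CA(i)–C(i) torsion and ψ(i) the
N(i)–CA(i)–C(i)–N(i+1) torsion, IUPAC sign convention, in `[-180, 180)`.
A peptide bond longer than **2.5 Å** is treated as a chain break and the
torsions that would span it are reported absent rather than computed across
the gap; 2.5 Å is far beyond any plausible C–N bond and well short of the
next-residue distance in any physical arrangement, so the rule is
insensitive to its exact value.

The (φ, ψ) pair is scored against a category-specific probability table
(categories: general, GLY, PRO, pre-PRO, ILE/VAL — assignment by residue
name, with pre-PRO taking precedence over ILE/VAL only when the successor is
proline; GLY and PRO take precedence over pre-PRO). Tables are regular
periodic grids; lookup is bilinear interpolation with wrap-around, clamped
to `[0, 1]`. Classification applies two thresholds, **favored ≥ 0.02** and
**allowed ≥ 0.002** by default. Published tools differ in their exact
threshold choices and per-category variations; both values are plain
arguments (`rama_classify`, or `rama_thresholds` in the report config) so a
site can match whatever companion software it uses without code changes.

# Side-chain conformation

Two routes, reflecting the two shapes in which rotamer reference data is
published.

**Continuous score.** Each recognized rotamer of a residue type carries the
mean and SD of every χ torsion ("central values"). Each χ dimension is
modelled as an independent Gaussian; the score of a side chain against one
rotamer is the quadratic mean (RMS) of its per-dimension z-scores, and the
reported score is the minimum over all recognized rotamers. Zero therefore
means "exactly on some rotamer"; 1 roughly means "one SD away in every
dimension from the nearest rotamer". All recognized rotamers are evaluated —
no pruning — since the entry count per type is tiny. Angle differences wrap
to the shortest arc; the terminal χ of two-fold symmetric side chains (ASP,
GLU, PHE, TYR) wraps with period 180° instead of 360°.

**Discrete class.** A contour grid over χ space stores, at every lattice
point, one of four states: unknown (0), outlier (1), allowed (2), favored
(3). States derive from raw rotamericity percentages thresholded at
**≤ 0.3% → outlier** and **≥ 2.0% → favored**, with unlisted lattice points
becoming unknown. The grid is flattened row-major (last χ fastest), so a χ
coordinate's position is computable and no keys are stored:
`index = Σ_n nint((χ_n − X_n0)/spacing_n) · Π_{m>n} dim(X_m)`. Lookup
rounds to the nearest node — `nint` rounds halves away from zero, a
convention that matters only for queries landing exactly between nodes and
is documented here because implementations differ. Out-of-range χ wraps
periodically, so every query yields a valid index.

The flattened state array packs four 2-bit states per byte: point *j*
occupies bits `2·(j mod 4)` to `2·(j mod 4)+1` of byte `⌊j/4⌋`
(little-end-first within the byte), and the concatenated payload is
gzipped. The file header (JSON after magic bytes `RTLB\x01`) records axis
metadata, byte offsets, the bit order, and the thresholds, so the format is
self-describing and versioned. Decompression is the exact inverse;
round-trip identity is enforced by tests over randomized libraries.

Residues whose χ set cannot be fully measured (missing side-chain atoms) are
flagged `incomplete` and given no score — a partial z-score over the
measurable dimensions would silently understate the problem. Types with no
χ (GLY, ALA) are flagged `no_chi`. The unknown state is reported as its own
class but *rendered* with the outlier color in the chain-view: an
unclassifiable side chain deserves a look, not a green light.

# Density fit

A map is synthesized from the reflection list by inverse FFT,
`ρ(x) = (1/V) Σ_h F_h e^{−2πi h·x}`, with Friedel mates completed so the
synthesis is real. The grid spacing is at most `d_min/(2·s)` with
oversampling `s = 1.5` by default, i.e. spacing `d_min/3` — the standard
"third of the resolution" sampling; finer grids only cost memory since the
density is band-limited. Amplitude/phase pairs are consumed as given (e.g.
2mFo−DFc coefficients prepared upstream); no weighting is computed here.
When both a map file and reflections are supplied the map file wins,
avoiding silent resynthesis differences.

Each atom is scored `−ln Φ((ρ/Z − μ_map)/σ_map)`: the density at the atom
position (trilinear interpolation, periodic wrap), normalized by proton
number so heavy and light atoms are comparable, standardized against the
global map distribution, and turned into a positive "surprise" score —
larger is poorer, strictly decreasing and continuous in ρ. Two numerical
choices are deliberate and documented: the logarithm is natural (any base
is only a scale factor), and **μ_map/σ_map are computed from the raw,
unnormalized map** while only ρ is divided by Z — the literal reading of
the score's definition; the alternative (statistics of a Z-normalized
density field) is not well defined without an atom assignment for every
grid point. Φ is clamped above machine-tiny before the log so extreme
negative z stays finite. Residue scores are plain means over all atoms,
over the backbone set {N, CA, C, O, OXT}, and over the rest; an empty
subset yields an absent value rather than zero.

# Percentiles

Raw metrics live in incomparable units, so the report displays percentiles.
A percentile library stores, per metric, empirical thresholds at every
integer percentile 1–99, computed separately within **10 resolution bins**
(default edges 1.0, 1.3, 1.5, 1.8, 2.0, 2.3, 2.5, 3.0, 4.0 Å — denser where
the PDB is denser; fully configurable, and shipped as data so regeneration
is reproducible) plus an all-data entry used for unknown resolutions and
empty bins. Quantiles are type-7 (linear interpolation between order
statistics), the most common default, recorded in the library metadata. A
query returns the largest percentile whose threshold does not exceed the
value (0 below the first threshold), which makes the query monotone and
self-consistent with training ranks to within one percentile. Display-side,
percentiles are uniformly flipped to "higher = better" for metrics whose
raw polarity is higher-is-worse (B-factors, fit scores); the flip lives in
one function so it cannot drift between report elements. The bundled
records generator draws from plausible distributions for demonstration; a
real deployment regenerates the library from its own corpus via
`build_percentile_library` (also exposed as a CLI subcommand), with any
corpus filters (deposition date, redundancy) recorded in the `provenance`
metadata rather than enforced at build time.

# Comparing two iterations

Chains are paired by identical id first; leftovers are paired greedily by
best alignment score; chains present in only one version are reported
unpaired. Sequences (one-letter; non-standard residues as `X`, which scores
0 against anything) are aligned by Needleman–Wunsch with match +1,
mismatch −1, gap −2 — the scheme is a package choice, declared and
configurable, since nothing about the task demands a particular one — and a
deterministic tie-break (diagonal, then up), so reports are reproducible to
the byte. Metrics from both versions are collated column-by-column along
the alignment; a gap on either side becomes a missing marker, drawn as a
black spot at the chain-view rim. No coordinate-based superposition is
attempted: sequence alignment alone is what lets the same graphic absorb
renamed chains and edited sequences.

# The report

Continuous rings are min–max scaled (per chain by default; per model on
request), flipped where higher is worse so poor values always point inward,
and skewed by `r ↦ r^γ` with **γ = 2** so troughs are exaggerated — the
inward side of each axis is the side worth staring at. An all-constant axis
renders at full radius (no trough) by definition. Discrete rings use
traffic-light colors. The first residue sits at 12 o'clock, positions run
clockwise, and a small angular gap hosts the selector arm. Both versions'
geometries are embedded (previous-version radii and classes as data
attributes and a JSON payload), and the toggle animates a linear
interpolation of radii over a configurable duration, falling back to an
instant swap under reduced-motion preferences.

The whole report is one XML-well-formed HTML file with inline SVG, CSS, and
script; it contains no timestamps and no randomness, so identical inputs
give byte-identical output. The full mode appends per-chain summary tables;
the minimized mode is just the graphical panel, intended for iframe
insertion into host GUIs. Interaction goes through three named hooks —
`selectResidue(chain, position)`, `toggleVersion()`, `selectChain(i)` — so
embedding software can drive the panel, and every residue gets an anchor id
for linking out to 3D viewers. The legacy compatibility mode emits script
restricted to archaic keywords (`var`/`function`, no arrow functions,
template literals, or block-scoped declarations) and keeps all styles under
namespaced `cv-`/`rv-` classes, for embedded browsers that predate modern
JavaScript.

# Synthetic data: what it emulates and what it does not

The fixtures module builds everything the tests consume:

* **Models** from specified (φ, ψ) and χ torsions with ideal bond lengths
  and angles (ω fixed trans), a configurable B-factor profile (base,
  gradient, hotspots), optional residue displacement, written as standard
  PDB with a REMARK 2 record. Nine residue types (GLY, ALA, SER, VAL, LEU,
  ASP, MET, LYS, PHE) cover 0–4 χ dimensions. Side chains use a small
  embedded ideal-geometry table; only torsions vary.
* **Maps** as sums of per-atom Gaussians (amplitude ∝ Z, width tied to
  resolution) on a periodic orthogonal cell enclosing the model, with
  optional white noise, plus forward transforms to matching reflection
  sets.
* **Reference libraries** with planted ground truth: rotamer central values
  and contour grids whose favored/allowed/outlier regions are constructed,
  and Ramachandran tables with Gaussian basins at the helix (−57, −47) and
  sheet (−120, 130) positions.

All generators are pure functions of their spec and seed. What passing
tests show: the geometry engines recover what was built (to 10⁻³ degrees on
full-precision fixtures; PDB's three-decimal coordinates limit file-based
recovery to ~0.05°), the compression pipeline is lossless, classification
respects its thresholds exactly, fit scores discriminate displaced
residues, and rendering is structurally correct at 3–1200 residues. What
they do not show: agreement with real Top8000-derived tables (the planted
references have the right *shape*, not the right contents), behavior on
real crystallographic noise, maps with symmetry beyond P1, or percentile
scales comparable to a real corpus. Production use should load real
reference tables through the file readers and regenerate the percentile
library from a real record stream.

# Problem sizes and numerical tolerances used in the test suite

Property suites run at sizes chosen to be exhaustive where cheap: the flat
index is checked as a bijection against brute-force enumeration on 200+
random grids (≤ 4 dimensions, ≤ 6 nodes each); compression round-trips on
100 randomized libraries; alignment scores against an exhaustive
enumeration oracle for sequences up to length 8 and against an independent
dynamic-programming implementation for longer ones; fit-score
discrimination over 20 seeded model/map pairs (6 residues, 3 Å
displacement); rendering up to 1200 residues. Torsion identities are
asserted at 10⁻⁶–10⁻³ degrees depending on whether the path crosses PDB
coordinate rounding; FFT round-trips at 10⁻⁶ relative.

# Known limitations

* Reflection input is the plain-text `h k l F phi` dialect and CCP4 maps;
  binary MTZ is not parsed.
* Map synthesis assumes the supplied reflection list is complete for the
  asymmetric unit of interest (P1 synthesis with Friedel completion); no
  space-group symmetry expansion is performed.
* The density-fit score is intentionally simple — a pointwise
  normal-CDF surprise, not RSR/RSCC — and shares the known biases of
  pointwise scores.
* Percentile quality is entirely inherited from the record stream the
  library was built from.
* Bond-length/angle/planarity/chirality outliers, clash detection, and
  CaBLAM-style Cα metrics are out of scope; external validators' flags can
  be ingested as rim markers instead.
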