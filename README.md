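# chainview

Per-residue validation of protein models, rendered as a compact interactive
radial **chain-view** (one angular segment per residue, one concentric ring
per metric) next to a detailed **residue-view**, in a single self-contained
HTML file. The package targets crystallographic model building and
refinement: areas of a model that need attention tend to ripple across
several metrics at once, and a multi-metric ring chart makes those areas
visible at a glance. When two iterations of the same model are supplied
(e.g. consecutive snapshots from an automated building pipeline) the package
aligns their chains and sequences and lets the report animate between the
two versions, highlighting what changed.

## Metrics

For every amino-acid residue the metrics cascade computes:

- **B-factor statistics** — minimum, maximum, mean, and population SD of the
  atomic Debye–Waller factors (Å²) over the residue's atoms.
- **Backbone conformation** — φ and ψ torsions (IUPAC convention), the
  probability of the (φ, ψ) pair under a category-specific Ramachandran
  table (general / GLY / PRO / pre-PRO / ILE-VAL), bilinearly interpolated
  on the periodic grid, and a discrete favored / allowed / outlier class
  from thresholds on that probability (defaults 0.02 and 0.002,
  configurable).
- **Side-chain conformation** — two complementary scores over the measured
  χ torsions:
  a *continuous* score from per-rotamer central values,

      score = min_i sqrt( (1/N) Σ_n ((χ_n − μ_in) / σ_in)² )

  the minimum over recognized rotamers *i* of the quadratic-mean z-score
  across the N χ dimensions (angle differences wrapped to the shortest
  arc); and a *discrete* class looked up in a flattened contour grid over
  χ space. Grid values are thresholded at the conventional rotamericity
  cut-offs — ≤ 0.3% outlier, ≥ 2.0% favored — packed at 2 bits per lattice
  point (four points per byte), and gzip-compressed; the flat index of a χ
  coordinate is

      index = Σ_n nint((χ_n − X_n0) / (X_n1 − X_n0)) · Π_{m>n} dim(X_m)

  so no coordinate keys need to be stored.
- **Density fit** — a map is synthesized from structure factors by FFT
  (or read from a CCP4 map file), and each atom is scored

      score_atom = −ln Φ((ρ/Z − μ_map) / σ_map)

  where ρ is the trilinearly interpolated density at the atom position, Z
  its proton number, and Φ the standard normal CDF; larger is poorer.
  Residue scores are the means over all atoms, backbone atoms, and
  side-chain atoms.
- **Percentiles** — continuous metrics are placed on a common 0–100 scale
  by a library of empirical thresholds at every integer percentile,
  computed in 10 non-uniform resolution bins plus an all-data entry for
  models of unknown resolution.

## Worked example

```r
library(chainview)

seqv <- c("ALA","SER","LEU","LYS","MET","VAL","ASP","PHE","GLY","ALA")
spec <- fixture_spec(seed = 7, n_residues = 10, sequence = seqv,
                     chis = list(`2` = 62, `3` = c(-65, 175),
                                 `5` = c(-65, -65, -70)))
latest   <- synthetic_model(spec, path = "latest.pdb")
previous <- synthetic_model(fixture_spec(seed = 7, n_residues = 7,
                                         sequence = seqv[1:7]),
                            path = "previous.pdb")
map <- synthetic_map(latest$model, resolution = 2)
write_reflections_txt(synthetic_reflections(map, dmin = 2.5), "latest.hkl")

res <- generate_report("latest.pdb", "previous.pdb",
                       latest_reflections_path = "latest.hkl",
                       output_dir = "report_out")
str(res$summary$chains)
#> List of 1
#>  $ A:List of 5
#>   ..$ positions       : int 10
#>   ..$ missing_latest  : int 0
#>   ..$ missing_previous: int 3
#>   ..$ rama_outliers   : int 0
#>   ..$ rotamer_outliers: int 9
```

The previous iteration is three residues shorter; sequence alignment places
the gaps at the chain tail, and the chain-view marks those three positions
with black rim spots. The per-residue table behind the report:

```r
df <- chain_metrics(latest$model$chains[[1]], default_reference_data(),
                    map = map,
                    percentile_lib = build_percentile_library(
                      synthetic_percentile_records()),
                    resolution = 2)
df[2:5, c("seq_num","name","phi","psi","rama_class",
          "rot_score","rot_class","b_mean","fit_all")]
#>   seq_num name phi psi rama_class rot_score rot_class b_mean fit_all
#> 2       2  SER -57 -47    favored  0.000114   favored     20   0.158
#> 3       3  LEU -57 -47    favored  0.001660   favored     20   0.174
#> 4       4  LYS -57 -47    favored        NA   unknown     20   0.168
#> 5       5  MET -57 -47    favored  0.003540   favored     20   0.175
```

Helical residues sit in the favored Ramachandran basin; SER, LEU, and MET
were built at their reference rotamers, so their continuous scores are near
zero and their grid classes favored; LYS has no entry in the (deliberately
small) demonstration rotamer library, so its class is reported as unknown.
`report_out/report.html` opens in any browser: clicking a segment updates
the residue-view, and the toggle animates between the two model versions.

A command-line front end with the same capabilities plus library-building
and fixture subcommands is installed at `inst/cli/chainview`
(`chainview report -l latest.pdb -p previous.pdb -o out ...`).

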