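# condock

Ligand binding-site prediction for GPCR-like receptors by rescoring
blind-docking poses with evolutionary surface conservation.

## The problem

Blind (global) docking scatters candidate ligand poses across an entire
receptor surface, and on G-protein coupled receptors — above all on
homology models — the pose with the best docking energy is often at the
wrong site: physics-based scoring functions are highly sensitive to
small structural errors. Evolutionary conservation is an orthogonal
signal (real binding sites tend to be retained across species), but on
its own it cannot localize a site either, since structural cores are
conserved too. `condock` combines the two.

## The scoring function

For each docked pose *p* with docking energy score *E_p* (e.g.
SwissDock FullFitness; more negative = more favorable):

1. The pose's **binding site** is the set of receptor residues with any
   heavy atom within 3.5 Å (inclusive) of any ligand heavy atom.
2. The **Conservation Score** is the arithmetic mean of the
   per-residue conservation values over the *n* site residues:
   *C_p = (1/n) Σ c_k*, with *c_k* ∈ [0, 1].
3. The **combined score** is the exact product *S_p = C_p × E_p*.

Poses are ranked by ascending *S_p* (most negative first; ties break by
energy, then pose id), and the rank-1 pose's site is the predicted
binding site. Conservation comes either from a ConSurf-style 0–9 grades
table (normalized as grade/9) or from a multiple sequence alignment via
a Jensen–Shannon divergence column scorer. Predictions are benchmarked
by the center-of-mass distance between predicted and reference ligand
positions — a site-level metric that, unlike RMSD, needs no atom
matching.

## Worked example

The package ships a small synthetic scenario
(`inst/extdata/scenario1/`): a 60-residue pseudo-receptor with a
conserved pocket, a grades table, and 9 docked poses — one true pose in
the pocket, eight decoys elsewhere.

```r
library(condock)
fixture  <- system.file("extdata", "scenario1", package = "condock")

receptor <- read_receptor(file.path(fixture, "receptor.pdb"))
poses    <- read_poses(file.path(fixture, "poses_swissdock.pdb"), "swissdock")
grades   <- read_consurf_grades(file.path(fixture, "grades.txt"))
profile  <- map_profile_to_structure(grades, receptor)

ranking <- rank_poses(receptor, poses, profile)
ranking
#> condock ranking: 9 ranked pose(s), 0 unranked (cutoff 3.5 A)
#>   pose_id energy_score conservation_score condock_score rank n_site
#> 1   c8.e0    -1492.157          0.8888889    -1326.3619    1      7
#> 2   c0.e0    -1561.376          0.2222222     -346.9725    2      7
#> 3   c7.e0    -1553.127          0.2222222     -345.1394    3      3
#> 4   c1.e0    -1549.282          0.2222222     -344.2849    4      4
#> ...
```

Read the table like this: pose `c0.e0` has the best docking energy
(−1561.4), so docking alone would pick it — but its site residues have
mean conservation only 0.22 (grade 2 of 9). Pose `c8.e0` is merely 6th
by energy, yet it sits on a 7-residue site of mean conservation 0.89
(grade 8 of 9), so its combined score −1326.4 wins by a wide margin.
Conservation has rescued the ranking. Evaluating against the bundled
reference ligand position confirms the rescue found the right place:

```r
reference  <- read_pose_pdb(file.path(fixture, "reference.pdb"))
evaluate_prediction(ranking, reference, receptor, profile)
#> site evaluation (threshold 4 A, mass-weighted COM)
#>   rank-1 pose 'c8.e0': COM distance 0.00 A, jaccard 1.00, SUCCESS
```

The same pipeline runs from a shell via the bundled script
(`inst/exec/condock`): subcommands `predict`, `evaluate`, `profile`
(conservation export, including a B-factor-colored PDB) and `simulate`
(write a fresh seeded scenario).

```sh
Rscript inst/exec/condock predict \
  --receptor receptor.pdb --poses poses_swissdock.pdb \
  --grades grades.txt --out-dir out/
```

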