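---
title: "Binding-site prediction from docking and surface conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site prediction from docking and surface conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condock)
```

## The problem and the model

Blind (global) docking places candidate ligand poses over the whole
surface of a receptor and scores each with a physics-based energy
function. On G-protein coupled receptors — and especially on homology
models of them — the energy-best pose is often in the wrong place:
scoring functions are sensitive to small structural errors, and loops or
side chains modeled slightly wrong can make a spurious surface patch
look favorable. Evolutionary surface conservation carries orthogonal
information: residues that actually bind physiological ligands tend to
be retained across species, while arbitrary surface patches are not.
Conservation alone, however, cannot localize a site either, because
large parts of a receptor (e.g. the helix-packing core) are conserved
for structural reasons.

This package combines the two signals with a deliberately simple scoring
function. For a docked pose $p$ with docking energy score $E_p$ (for
SwissDock output, the FullFitness value; more negative = more
favorable):

1. **Binding-site extraction.** The candidate site of pose $p$ is the
   set of receptor residues with at least one heavy atom within 3.5 Å
   (inclusive) of any ligand heavy atom.
2. **Conservation Score.** $C_p = \frac{1}{n}\sum_{k=1}^{n} c_k$, the
   arithmetic mean of the per-residue conservation values $c_k \in
   [0,1]$ over the $n$ site residues.
3. **Combined score.** $S_p = C_p \times E_p$, the exact product with no
   clamping or rescaling. Because $E_p$ is a modified free energy, the
   most negative $S_p$ marks the most probable binding site.

Poses are ranked by ascending $S_p$; exact ties break by ascending
energy, then pose id. The rank-1 pose's site is the predicted binding
site. The key qualitative behavior is *rescue*: a correct pose whose
energy rank is, say, third can still win the combined ranking when its
site is distinctly more conserved than the decoys' — and with a
constant conservation surface the combined ranking provably collapses
to the pure energy ranking, so conservation only adds information where
it varies.

## Conservation sources

Two per-residue conservation sources feed the same profile container:

* **Imported grade tables.** ConSurf-style tables assign each sequence
  position an integer grade 0–9 (9 = retained in all aligned
  organisms). Grades are divided by 9, giving values in $[0,1]$; the
  normalization is exact in floating point (value × 9 recovers the
  integer grade bit-for-bit, which the tests assert). The phylogenetic
  machinery that produces such grades is out of scope here — grades are
  an input format.
* **Jensen–Shannon divergence from an MSA.** For an alignment column
  with residue distribution $P$ and background $B$,
  $\mathrm{JSD} = \tfrac12 KL(P\|M) + \tfrac12 KL(B\|M)$,
  $M = \tfrac12(P+B)$, logs base 2, so the score lies in $[0,1]$ (1 bit
  maximum). Gaps are excluded from $P$. A pseudo-count of
  $1/(20\,n_\mathrm{seq})$ is added to the column frequencies so no KL
  term has zero support; $n_\mathrm{seq}$ is the column depth including
  gaps, which makes the score depend only on the relative residue
  frequencies at fixed depth (and makes the documented gap-penalty
  identity exact). With the gap penalty enabled (default) the score is
  multiplied by the column's non-gap fraction, down-weighting gappy
  columns. `X` symbols are treated as non-informative: excluded from
  $P$ but not counted as gaps.

  The default background is uniform over the 20 residues; the
  Robinson–Robinson empirical amino-acid frequencies are selectable for
  users who prefer a database background. Because of the pseudo-count, a
  fully conserved column scores below the 1-bit ceiling at small
  alignment depth (≈0.57 at 6 sequences, approaching 1 as depth grows),
  and duplicating every sequence moves a score only through the
  $O(1/n)$ pseudo-count, never through the frequencies. No windowed
  smoothing over neighboring columns is applied; scores are per-column.

Profiles are carried onto a structure by a global pairwise alignment of
the score table's sequence against the structure's one-letter sequence
(BLOSUM62, gap open/extend 10/0.5). The mapping requires ≥ 80% identity
over aligned positions; individual letter mismatches warn but still
assign, and structure residues with no aligned score simply carry no
profile entry. Site residues without a profile value are, by default,
omitted from the site mean (and reported); a strict mode errors instead.

## Evaluation metric

Predictions are benchmarked by the Euclidean distance between the
centers of mass of the predicted and reference ligand positions. Unlike
RMSD this requires no atom matching, so predicted and reference ligands
may differ in atom count or identity — appropriate when the question is
*where* the ligand binds, not its exact pose. Mass weighting (standard
atomic masses) is the default; an unweighted centroid is available, and
the two agree exactly for homo-elemental ligands. A companion Jaccard
overlap compares the predicted site with the reference ligand's own
3.5 Å site, derived with the same contact rule so the two sets are
commensurable. A prediction is flagged successful when the COM distance
is at or below a configurable threshold, default 4 Å — in this
literature, predictions within a few Å identify the correct pocket
while >10 Å misses are unambiguous failures; the threshold is
reporting convenience, not part of the score.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `cutoff` | 3.5 | Å | inclusive heavy-atom contact distance defining a site |
| `gap_penalty` | on | — | multiply JSD by the column's non-gap fraction |
| `background` | uniform | — | JSD background distribution (`robinson` selectable) |
| `min_identity` | 0.8 | — | required sequence identity for profile→structure mapping |
| `weighting` | mass | — | COM weighting (`geometric` selectable) |
| `success_threshold` | 4.0 | Å | COM distance below which a prediction counts as a success |

Hydrogens are excluded on both sides of the contact computation by
default (toggleable): docked poses and crystal structures are
inconsistent about hydrogen presence, and excluding them makes sites
deterministic across input sources. Alternate locations resolve to the
highest-occupancy conformer (ties: file order). Energy scores are used
exactly as the docking program reports them — never rescaled or
z-normalized across poses; a positive energy triggers a warning because
the product ordering assumes negative energies.

## The synthetic scenario generator

Real inputs for this method are receptor structures, SwissDock pose
sets, and ConSurf runs — none of which can be bundled or regenerated
offline. The `scenario_spec()`/`make_scenario()` generator therefore
builds fully self-contained test scenarios in which the truth is
planted and every artifact is a pure function of the spec (including
its mandatory seed):

* **Receptor**: a poly-alanine pseudo-receptor of `n_residues` rigid
  5-heavy-atom units on a staggered cylinder (radius 8.5 Å, 12 residues
  per 3 Å ring) around a central cavity, echoing the extracellular
  cavity geometry in which most GPCR ligands bind. Cβ atoms point
  inward, so the cavity wall is the contact surface.
* **Conservation**: a planted pocket (the `pocket_fraction` of residues
  nearest an anchor just inside the wall) gets conservation level
  `pocket_conservation` (default 0.9); all other columns get
  `background_conservation` (default 0.2). Grades are
  `round(9 × level)`; the MSA keeps the consensus residue in each
  column with probability equal to the planted level (scaled by
  `mutation_rate`), so JSD recovery of the planted profile is itself
  testable (Spearman ρ ≈ 0.96 at 50 sequences).
* **Poses**: one true pose of a rigid 8-heavy-atom toy ligand (a cube of
  carbons; contact and COM arithmetic need no chemistry) centered in the
  pocket, plus `n_decoys` decoys at random non-pocket wall positions.
  Decoy energies are drawn from N(−1500, 100²), the magnitude regime of
  SwissDock FullFitness values; the true pose's energy is placed at
  `true_energy_percentile` of the decoy energies. Percentile 0 makes
  docking alone sufficient; percentiles above ~0.5 reproduce the rescue
  regime where only the combined score finds the truth. Generation-time
  validation enforces that the true site lies inside the pocket and
  every decoy site overlaps it by < 20%.

The defaults (60 residues, pocket fraction 0.2, conservation 0.9 vs
0.2, 10 decoys, percentile 0.7, 50 sequences) are the package's study
conditions: a clearly but not perfectly conserved pocket, a background
at the low end of surface conservation, and a true pose that docking
alone ranks mid-field. What passing tests on these scenarios shows is
that the scoring arithmetic, ranking, and rescue logic are correct and
that the JSD scorer recovers planted signal; what they cannot show is
performance on real receptors, where conservation and energy errors are
correlated with structure quality, sites are not cleanly two-level, and
decoys are not geometrically segregated from the pocket.

Coordinates and energies are rounded at generation time to the precision
of their text formats (3 decimals for PDB, 4 for energies) so that
write→read round-trips are exact identities rather than approximate
ones.

## Numerical and design choices

* *Inclusive cutoff.* "Within 3.5 Å" is implemented as ≤; at PDB
  coordinate precision the boundary case has measure zero, but
  inclusiveness makes the hand-constructed boundary fixtures
  deterministic.
* *Tie-breaking.* Exact product ties break by energy, then pose id —
  arbitrary but total, so rankings are reproducible.
* *Cluster files.* SwissDock-style cluster files assign the
  cluster-level FullFitness to every member pose; a flag restricts
  reading to cluster representatives (element 0), since which of the
  two conventions an upstream pipeline used cannot be inferred from the
  file.
* *Degenerate inputs.* An empty site is a valid, flagged result (the
  pose touches nothing); such poses are appended to the output unranked
  with a reason code rather than silently dropped, and a run in which
  *no* pose is scoreable is an error. An all-gap alignment column warns
  and scores 0.
* *Problem sizes.* The bundled test suite and the acceptance script use
  60-residue receptors, 8–10 decoys per scenario, 200 rescue scenarios,
  100 random contact fixtures, and 50-sequence alignments — sizes chosen
  so the planted effects are unambiguous while the whole suite runs in
  about a minute on one core.

## Known limitations

* The generator's receptor is a geometric toy: no secondary structure,
  no side-chain chemistry, no realistic packing. It exercises the
  scoring pipeline, not structural biology.
* The JSD scorer is a per-column substitute for phylogeny-aware
  conservation estimation; it ignores tree structure and sequence
  redundancy (beyond the frequency-proportional behavior documented
  above).
* Cross-docking accuracy claims on real receptors depend on external
  docking runs and curated alignments and are outside what this package
  can verify; the package verifies the method's internal contracts and
  its planted-truth behavior.
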