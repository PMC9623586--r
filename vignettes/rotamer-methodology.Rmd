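---
title: "Sequence-dependent rotamer libraries and rotamer-move basin-hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-dependent rotamer libraries and rotamer-move basin-hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotbh)
```

## The problem

Amino-acid side chains occupy a small set of recurrent conformations —
rotamers — characterized by their chi dihedral angles.  A rotamer library
records, per residue type, the chi means, a spread for each chi, and an
occurrence probability.  `rotbh` implements a *sequence-dependent,
backbone-independent* variant: rotamers are keyed by the tripeptide
context (previous, central, next residue), because the adjacent residues
exert strong steric control over which side-chain conformations are
accessible.  The same library then drives *rotamer moves* inside
basin-hopping global optimization: instead of rotating random side-chain
dihedrals, a move sets all chi of a chosen residue to a library rotamer
drawn with its occupation probability.

The intended inputs are conformational ensembles of capped tripeptides
(ACE--XXX--YYY--ZZZ--NME) produced by an exhaustive sampling method that
records, for every distinct local minimum, its potential energy and an
estimate of its local free energy.  The package does not ship a protein
force field; ensembles arrive as multi-model PDB plus a sidecar energy
table, or as TSV torsion tables, and desk-scale benchmarking uses the
built-in toy systems described below.

## Library construction

For one sequence context with conformations $i = 1..m$:

1. **Populations.** Each conformation receives its Boltzmann equilibrium
   population at $T = 298\,$K from its free energy,
   $p_i \propto e^{-F_i / k_B T}$.  Free energies enter in kcal/mol;
   only differences matter.
2. **Torsional metric.** Side chains are compared as vectors of chi
   angles with the periodic Euclidean metric
   $d(\mathbf p, \mathbf q) = \sqrt{\sum_j \mathrm{min}(|p_j - q_j|,
   360 - |p_j - q_j|)^2}$ (degrees), so $-179°$ and $180°$ are $1°$
   apart.  Clustering in torsional rather than Cartesian space keeps
   distal chi differences from being down-weighted.
3. **Clustering.** Unweighted average-linkage (UPGMA) agglomerative
   clustering of the pairwise distance table, with flat clusters cut at
   $40°$.  The cut is *strict*: conformations merging at exactly the
   cutoff stay separate.  Because every component of the metric is
   bounded by the total, members of one flat cluster are automatically
   within $40°$ in every individual chi — the aggregate criterion is
   stricter than a per-chi one.
4. **Rotamer statistics.** Per cluster, the chi means are circular means
   and the spreads circular *population* standard deviations (root mean
   square of wrapped deviations about the circular mean).  Within a
   $40°$ cluster the wrap only matters near $\pm 180°$, where an
   arithmetic mean would be badly wrong, which is why circular
   statistics are used throughout.  Single-member clusters get a spread
   of $1.0°$ per chi, a nominal width for thermal displacements about an
   isolated minimum.  The cluster probability is the sum of its
   members' populations.
5. **Pruning.** Rotamers with probability strictly below $0.005$ are
   removed.  Retained probabilities are *not* renormalized — the library
   records the population each rotamer actually carries; rotamer-move
   selection renormalizes over a context's entries at draw time, so the
   two conventions cannot drift apart.

`rotamer_library()` is the fitting entry point and returns a classed
object with `print`, `summary` and `predict` methods; `write_library()`
/ `read_library()` serialize it as diffable tab-separated text whose
write--read--write round trip is byte-identical.

### Matching and coverage

An observed side chain matches a rotamer when *every* chi is strictly
within $40°$ of the rotamer mean (`match_sidechain()`); among several
matches the most probable rotamer wins.  `coverage_report()` applies
this criterion to a test set and reports, per central residue type, the
percentage matched and the mean number of rotamers per context,
averaging uniformly over contexts (occurrence-weighted averaging would
require abundance data the library does not carry).
`reference_rotamer_tracking()` follows one reference rotamer — by
default the top rotamer of the glycine-flanked context, the least
constrained environment — across all contexts with the same central
residue and reports how sequence promotes or suppresses it.  The
matching criterion used for tracking is the per-chi form by default;
the aggregate Euclidean form is available behind `aggregate = TRUE`
(the two differ only for multi-chi residues, and the per-chi form is
the one used for coverage scoring, so it is the default).

Generic `HIS` queries fall back to the delta-protonated tautomer
(`HID`), which keeps libraries built from explicit protonation states
usable against data that does not record them.

## Basin-hopping

`run_basin_hopping()` explores the transformed landscape
$\tilde V(x) = \min V(x)$ in which every configuration maps to the
energy of its local minimum: perturb, minimize (L-BFGS to an RMS force
of $10^{-6}$ kcal/mol/Å), then accept or reject against the current
minimum of the Markov chain with the Metropolis rule
($\Delta \le 0$ always accepted, else probability
$e^{-\Delta/T}$, $T$ in kcal/mol).  With `use_free_energy = TRUE`
(FEBH) the acceptance uses harmonic local free energies
$F = V + k_B T \sum_j \ln \omega_j$ over the positive normal modes
(unit masses); Hessians come from the analytic callback when present,
else central finite differences of the gradient (step $10^{-4}$).
Eigenvalues within $10^{-8}$ of zero are treated as rigid-body modes
and dropped; anything more negative raises an error, because the point
is then not a minimum.

Moves:

* **Group rotation** — each rotatable dihedral is independently selected
  (probability 0.025 by default, the value used during library
  construction runs) and rotated by a uniform draw in
  $[-A, +A]$; only atoms downstream of the bond move, so bond lengths
  and angles are conserved exactly.  The default amplitude is $A = 180°$
  — the source procedure says only that the magnitude is random, and a
  full-range uniform draw is the least informative choice.
* **Scheme moves** — the benchmark schemes rotate an *exact* number of
  dihedrals: every `f_BB` steps, `n_BB` distinct backbone dihedrals;
  every `f_SC` steps either `n_SC` side-chain dihedrals (group-rotation
  schemes) or `n_SC` whole residues set to drawn rotamers (rotamer
  schemes).  When both fire on one step the backbone move is applied
  first, so imposed rotamer angles survive into minimization.
* **Cartesian displacement** — each coordinate perturbed uniformly
  within $\pm 1$ Å by default; disabled (amplitude 0) in the benchmark
  schemes.
* **Rotamer move** — residues chosen uniformly without replacement
  among chi-bearing residues; a rotamer drawn per residue with
  probability proportional to its library probability; all chi set to
  the rotamer means by downstream rotation, backbone untouched.

`scheme_presets()` returns the twelve benchmark schemes (eight rotamer,
four group rotation) at sampling temperature 1.3 kcal/mol.  A run
records every proposal (energy, move type, acceptance, minimizer
effort); `markov_diagnostics()` produces the proposal-energy series
relative to the chain minimum and the least-RMSD (after optimal
superposition) between adjacent accepted minima.

Ties ($\Delta = 0$) are accepted, and acceptance always compares
against the current chain minimum.  A single seeded RNG drives every
stochastic choice, so a (potential, scheme, seed) triple reproduces a
trajectory bit for bit.

## Synthetic data and the toy benchmark

Two generators stand in for the force-field machinery that the package
deliberately does not include:

**Planted ensembles** (`sample_planted_ensemble()`) draw conformations
around $K$ torsional centers with wrapped Gaussian noise (truncated at
$4\sigma$; a von Mises draw would change nothing at $\sigma \ll 360°$),
defaulting to $\sigma = 5°$ — the typical within-rotamer spread.
Centers must be pairwise farther than twice the clustering cutoff, else
recovery is not an identifiable target.  Draw counts per center are
multinomial in the Boltzmann weights of the planted free energies.
Each draw carries its center's free energy plus $k_B T \ln n_c$ plus a
small uniform jitter ($\pm 0.05$ kcal/mol, so basin members are
distinct minima rather than exact degenerates): the $\ln n_c$ term
splits a basin's population among its members, making the sum of member
populations equal the planted basin population — the quantity the
library is supposed to recover — independent of how many draws landed
in the basin.

**The rotamer chain** (`make_rotamer_chain()`) is a Cartesian bead
chain: `n_residues + 3` backbone beads plus a two-bead side chain per
residue, one chi dihedral each.  The energy combines harmonic bonds
(1.5 Å, 100 kcal/mol/Å²) and angles (120° backbone / 109.47° side,
50 kcal/mol/rad²), cosine torsional terms — a `k`-fold chi well
(barrier 6 kcal/mol) with one well deepened by a seeded bias of
0.8--1.6 kcal/mol, a backbone double well (barrier 6, bias 1--2
kcal/mol), and a single-well attachment dihedral pinning the side-chain
orientation — and a soft $\varepsilon(\sigma/r)^6$ repulsion between
beads three or more bonds apart ($\varepsilon = 0.2$, $\sigma = 1.2$ Å).
These magnitudes mirror the ordering in real peptides: torsional
barriers of a few kcal/mol, well-depth differences of order 1 kcal/mol
(a few $k_B T$ at room temperature), and stiff bonded terms.  The
energy and gradient are compiled (with an L-BFGS minimizer specialized
to this potential) because a benchmark performs on the order of $10^5$
local minimizations.

At build time every combination of chi and backbone wells is
enumerated, minimized and deduplicated, so the global minimum is known
by construction and "success within 1 kcal/mol of the global minimum"
is decidable without any external reference.  `toy_library()` then runs
the *actual* pipeline — finite-difference harmonic free energies at
298 K (zero-mode floor $10^{-4}$, appropriate because the chain's six
rigid-body modes are separated from its softest internal mode by many
orders of magnitude), Boltzmann populations, torsional clustering — on
the enumerated minima, so rotamer moves on the toy system consume a
library produced by the same code path as for peptides.

What the toy systems do *not* emulate: real force-field energetics,
solvent, correlated chi--backbone coupling beyond soft repulsion, and
the combinatorial breadth of 18 amino-acid types.  Tests passing on
them validate the machinery (metric, clustering, statistics, moves,
acceptance, bookkeeping), not force-field-level accuracy on proteins.

### Benchmark conditions

The scheme comparison uses the 4-residue, 3-well chain (1296 enumerated
well combinations), a 2,000-step budget, 20 seeds per arm, and the
matched pair "rotamer 2" vs "group rotation 1" — the preset pair
designed to apply a comparable number of side-chain dihedral changes
per step.  These sizes keep a full comparison within minutes on one
core while leaving the success criterion non-trivial per step.  On this
desk-scale landscape both arms typically reach the global minimum
within the budget, so success *rates* saturate and the discriminating
readouts are the number of steps to first success (reported by the
acceptance script) and the minimizer effort per move type
(`summary()` of a run).  The comparison asserts the one-sided trend —
rotamer success at least matches group rotation, which must not be
significantly better — rather than any absolute rate, which would
require the original force-field systems.

## Numerical choices

* Angles live in $(-180, 180]$, IUPAC dihedral sign convention; the
  torsional metric is used unnormalized (no $1/n$), which is what makes
  the 40° flat-cluster cut stricter than the per-chi criterion.
* Chi definitions are the standard heavy-atom quadruples (χ1--χ4),
  shipped as a plain-text table; the three histidine protonation states
  share one chi topology.  Symmetric terminal dihedrals (PHE/TYR χ2,
  ASP χ2, GLU χ3) are kept as computed — no folding into a half-range —
  since the matching criterion and clustering operate on the same
  convention on both sides.
* Cluster-count determinism: flat clusters are read off the merge tree
  by a strict-inequality union of merges below the cutoff.  Equal-height
  merge ties are resolved by the ordering of the underlying
  average-linkage implementation (`stats::hclust`); ties have measure
  zero for continuous torsions and do not affect the flat clusters in
  the regimes the library targets.
* The minimizer restarts L-BFGS from its endpoint until the RMS-force
  criterion is met (or an attempt budget is exhausted, which flags the
  record rather than failing silently).
* `local_minimize()` returns an energy never above its start; a
  non-decreasing step would be rejected and the start returned.

## Limitations

* The library quality is bounded by the ensembles fed in; the package
  evaluates and serializes, it does not sample peptides.
* Harmonic free energies ignore anharmonicity; at room temperature this
  biases populations of soft, wide wells downward.
* The mean-rotamer-count summary averages contexts uniformly; data sets
  with strong context abundance skews may prefer occurrence weighting.
* Coverage against experimental side-chain data requires the external
  structure sets; the shipped machinery is exercised end-to-end on
  synthetic ensembles only.
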