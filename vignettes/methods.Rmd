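---
title: "Annotating, modelling and sampling protease-peptide complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating, modelling and sampling protease-peptide complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsites)
```

## The problem

Endopeptidases bind their substrates across eight surface pockets,
S4–S1 and S1′–S4′, which accommodate the substrate residues P4–P1 and
P1′–P4′; the scissile bond lies between P1 and P1′.  Experimental
cleavage data summarised as a specificity matrix — the occurrence
fraction $n_{ij}$ of amino acid $i$ at substrate position $j$ — gives
an information-theoretic measure of how selective each pocket is:

$$H(j) = -\sum_{i=1}^{20} n_{ij}\,\log_{20} n_{ij}, \qquad
H_\mathrm{cleavage} = \sum_{j=1}^{8} H(j),$$

with $0\,\log 0 := 0$ by continuity.  $H(j)$ runs from 0 (one amino
acid dominates) to 1 (all twenty equally used); the total runs from 0
to 8.  `subsites` computes structural observables — burial, contacts,
interface energies — per substrate position from sampled conformations
of modelled protease–peptide complexes, so that their per-position
trends can be compared against $H(j)$ by rank correlation.

This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and
do not demonstrate.

## Annotation workflow

A structure is an atom tibble (one row per atom, author numbering,
coordinates in Å).  The annotation stages and their defaults:

* **Ligand detection.**  Candidate substrate chains have 3–12 residues
  and at least one residue from a configurable peptide-like name list
  (the 20 standard residues plus a small hetero list standing in for
  the peptide-like class of the PDB Chemical Component Dictionary;
  there is no database dependency).  Chains made only of UNK residues
  are excluded.
* **Catalytic-site occupancy.**  With a table of catalytic residues
  (chain, residue number, role), the ligand is accepted when the summed
  solvent accessibility of the catalytic residues increases by strictly
  more than 0 Å² upon ligand removal.  All-atom accessibility is used
  (side-chain-only is a constructor argument away); waters are always
  excluded from the occlusion set.  Structures without catalytic
  annotation are not analysed; missing annotations can be filled by
  homology transfer, which walks an ordered library of annotated
  sequences and transfers positions through the first global alignment
  exceeding 50 % identity.  Identity is counted as identical columns
  over all alignment columns, gaps included; `X` never matches.
  Alignment uses BLOSUM62 with gap open 10 / extend 0.5.
* **Pocket assignment.**  Every protease residue with at least one atom
  within 4.5 Å of at least one atom of a reference peptide residue
  joins that residue's pocket; a protease residue may belong to several
  pockets.  The 4.5 Å default reflects the ~5 Å ceiling on the
  distance between a bound peptide and the catalytic machinery.
* **Projection.**  Other structures of a family are annotated by
  superposing them onto the reference (protease sequences aligned,
  matched Cα atoms fitted by least squares; the fit is refused below
  30 % identity) and giving each target peptide residue the pocket of
  the reference residue that captures most of its atoms within 2 Å.
  Ties go to the N-terminal-most reference residue; residues capturing
  no atoms stay unassigned.
* **Gap closing.**  If the projected labels split into runs whose
  label-vs-position offsets disagree, the shorter run is re-labelled to
  continue the longer one (the longer run is trusted); equal-length
  runs keep the N-terminal run fixed.  Labels pushed outside S4–S4′
  become unassigned.
* **Filters.**  Acetyl/diazomethane-type capping groups are removed by
  residue name, and assignments with fewer than three pocket residues
  are discarded with a recorded reason.

## Substrate modelling

* **Non-natural residues.**  A modified residue is mapped onto the
  natural amino acid whose side-chain graph is most similar under a
  circular (Morgan-style) fingerprint: atoms start from an
  element/degree invariant and are iteratively re-hashed with their
  neighbours' invariants and bond orders out to radius 2; similarity is
  the Tanimoto coefficient on the resulting identifier sets.  The
  graphs are anchored at Cα so that attachment isomers (norleucine
  vs. isoleucine) are distinguished.  A best similarity at or below
  0.4 marks the residue unreplaceable and the complex is discarded;
  both the floor and the fingerprinter are arguments.
* **Side-chain construction.**  Mutations keep the backbone bit-for-bit
  and rebuild the side chain from an internal-coordinate template with
  ideal bond lengths and angles.  Chi angles are copied from the
  template residue wherever the four defining atoms correspond by
  name, otherwise a small most-common-rotamer table supplies them.
  The clash count (heavy-atom pairs under 2 Å, excluding covalent
  backbone neighbours) is attached to the result.
* **Relaxation.**  After each mutation a deterministic greedy scan
  rotates each chi torsion over a 30° grid, minimising the clash count
  with the residue's non-bonded energy as tie-break.  This stands in
  for a rotamer-library repack; an external engine can be substituted
  by replacing this hook.
* **Missing positions.**  Partial substrates (at least three
  consecutive pockets covered) are extended residue by residue to the
  full P4–P4′ 8-mer with ideal backbone geometry (C–N 1.329 Å, trans
  peptide), scanning φ/ψ on a 30° grid and keeping the least-clashing
  conformer, extended values preferred on ties.  If no grid point is
  clash-free for some residue the complex is unmodellable — there are
  no partial successes.
* **Libraries.**  Random libraries draw each of the eight positions
  i.i.d. uniformly from the 20 amino acids; the default library size
  is 480 peptides.  Threading substitutes positions P4→P4′ in order,
  relaxing after each substitution.

## Sampling and energy model

The sampler is Metropolis Monte Carlo over two proposal types:

* **Backrub moves** rotate the backbone segment between two pivot Cα
  atoms (2–12 consecutive residues) rigidly about the pivot axis by an
  angle uniform in ±11°, preserving all bond lengths exactly.
* **Side-chain moves** perturb one random chi torsion of one random
  flexible residue by a Gaussian step (σ = 20°); glycine, alanine and
  proline are skipped.

Only the peptide and the pocket residues are flexible; the rest of the
protease is frozen.  Acceptance follows
$\min(1, e^{-\Delta E/kT})$ with kT = 1.2 by default; energies here
are model-internal units, so kT is configurable and only comparisons
matter.  Runs default to 5000 steps with a frame recorded every 10
steps — 500 frames; the 10:1 stride is the package's choice for that
frame budget.

The energy model sums, over non-bonded atom pairs within 10 Å
(excluding pairs within a residue or between sequence-adjacent
residues):

* a 12-6 Lennard-Jones term with element-based radii and depths,
* Coulomb electrostatics with coarse, implicit-hydrogen partial
  charges under a distance-dependent dielectric $\varepsilon(r) = Dr$
  with $D = 12$.  The strong screening is deliberate: every charged
  group in these small complexes sits at the solvent-exposed surface
  with no explicit solvent, and weaker screening lets isolated
  charge–carbonyl contacts dominate the per-position energies that are
  meant to report on burial,
* a short-range hydrogen-bond bonus for donor/acceptor heavy-atom
  pairs near 2.9 Å.

Per-position interface energies sum the cross-partition pair terms of
each peptide residue, so the positions add up exactly to the total
interface energy.

## Observables

Per frame and per substrate position the package records: relative
accessible surface area, hydrogen-bond counts and non-bonded contact
counts split into main-chain/side-chain (classified on the peptide
atom), and the interface energy.

* **Accessibility** uses a Shrake–Rupley engine: each atom's
  solvent-expanded sphere (van der Waals radius + 1.4 Å probe) is
  sampled with a deterministic point set — half a Fibonacci lattice
  plus its antipodes, so the set is inversion-symmetric and
  mirror-symmetric structures get exactly equal areas.  The default of
  3840 points per atom is converged in the sense that doubling it
  changes per-residue areas by under 1 %; the per-frame observable
  stage uses a coarser 240-point set, trading ~2 % quadrature noise
  per frame for speed, which averages out over frames.  Relative
  accessibility divides by theoretical Gly-X-Gly maxima and may
  slightly exceed 1 for distorted geometries (reported uncapped).
* **Hydrogen bonds** use HBPLUS-style geometric criteria: donor–
  acceptor ≤ 3.9 Å, hydrogen–acceptor ≤ 2.5 Å, donor–hydrogen–acceptor
  ≥ 90°.  Crystal structures carry no hydrogens, so the backbone amide
  H is constructed from N, Cα and the preceding carbonyl C, while
  rotatable side-chain hydrogens (hydroxyl, thiol, amine) are taken to
  point at the candidate acceptor — for those donors the angle test is
  vacuous and the distance test effectively tightens to D–A ≤ 3.5 Å.
* **Non-bonded contacts** are cross-partition heavy-atom pairs within
  3.9 Å not already counted as hydrogen bonds.

Averages follow
$O_{ij} = \frac{1}{N_f}\sum_\alpha \sum_f o_{ij}^{\alpha f}$ where
$N_f$ counts the frames contributing to cell $(i, j)$ — within one run
the amino acid at a position is fixed, so cells accumulate across the
runs (one run per library peptide).  Position summaries average over
the amino acids observed at each position; a min–max normalisation
across the eight positions is recorded alongside (never instead of)
the raw averages.  Per-position Spearman correlations (average ranks
on ties) compare each observable's profile with $H(j)$; structures
with a constant profile have no defined rank correlation and are
dropped with a warning rather than zero-filled.

## Synthetic fixtures: what they emulate

`make_toy_complex()` builds an extended peptide flanked by two
glycine-rich β strands registered onto the peptide's own backbone
trace (constant lateral offset 4.8 Å, hydrogen-bond capable), a
catalytic Ser/His pair across the P1/P1′ junction with side chains
parity-selected to point out of the groove, and an "S1 pocket": a cage
of single glycine residues around the P1 side-chain tip (inner shell
at a 4.4 Å gap, outer shell 3.2 Å further), placed with
non-consecutive residue numbers so the sampler never treats them as a
bonded segment.  Ground-truth pocket membership is recorded at
construction time by naive distance loops, independent of the
annotation code it validates.  A `blocked_prime_side` variant fills
the prime-side region with a dense carbon grid so reconstruction is
provably impossible; an `nnaa_at` variant swaps in a norleucine.

The fixtures exercise contracts, not biophysics: they demonstrate that
the pipeline recovers constructed ground truth, that burial and
interface energy concentrate at an engineered pocket, and that the
machinery is deterministic — not that the model reproduces real
specificity profiles.  Real protease grooves are neither straight nor
glycine; transferring conclusions to real structures requires real
inputs.

With a 4-peptide random library (the fixture-pipeline setting used in
the tests) the per-position mean interface energy carries
draw-to-draw noise of the same order as the pocket contribution
(single charged residues contribute several energy units to a
4-sequence mean), so the energy ranking is asserted at the default
seed, while the accessibility ranking is robust across seeds.
Full-size 480-peptide libraries average this noise away by design.

## Problem sizes and determinism

The shipped tests run the full 5000-step/500-frame sampler contract on
a 3-residue toy complex, the fixture pipeline at 4 library peptides ×
200 steps, library-uniformity checks at n = 20 000, and Monte Carlo
calibration checks at 10⁵ draws.  All randomness flows from explicit
integer seeds: libraries, samplers and pipelines restore the caller's
RNG state, and rebuilding any fixture with the same seed is
bit-identical.

## Known limitations

* The energy model is comparative, not calibrated: no solvation term,
  coarse charges, arbitrary units.  Agreement with full molecular
  mechanics or knowledge-based scoring functions is out of scope by
  design.
* Proline side chains are built approximately (no ring closure to the
  backbone nitrogen) and are excluded from torsion moves.
* The backbone amide hydrogen construction and rotatable-donor
  convention approximate HBPLUS; exact numeric agreement with
  NACCESS/DSSP/HBPLUS outputs is a non-goal (property-level agreement
  is tested instead).
* Metalloproteases are out of scope (no metal-site handling), as are
  mmCIF input, multi-model ensembles and symmetry expansion.
* Homology transfer uses the library in the order given; with several
  entries above the identity floor, the first wins.
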