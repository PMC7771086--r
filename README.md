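# subsites

Proteases recognise their substrates through eight surface pockets —
the subsites S4–S1 and S1′–S4′ — that accommodate the substrate
residues P4–P1 and P1′–P4′ on either side of the scissile bond.  How
picky each pocket is can be quantified from experimental cleavage data:
given a specificity matrix (the per-position occurrence fractions
*n<sub>ij</sub>* of the 20 amino acids among a protease's known
substrates), the per-position cleavage entropy is the base-20 Shannon
entropy

&nbsp;&nbsp;&nbsp;&nbsp;H(j) = −Σ<sub>i=1..20</sub> n<sub>ij</sub> log<sub>20</sub> n<sub>ij</sub> ∈ [0, 1],

with H(j) = 0 for a fully specific position and 1 for a fully
promiscuous one, and the total cleavage entropy
H<sub>cleavage</sub> = Σ<sub>j</sub> H(j) ∈ [0, 8].

`subsites` provides the structural side of that comparison, for
structural bioinformaticians working on protease–peptide recognition:

* **Annotation** — detect peptide-like ligands (3–12 residues) in
  protease crystal structures, confirm catalytic-site occupancy through
  the accessibility change of the catalytic residues upon ligand
  removal (threshold 0 Å²), assign peptide residues to pockets from a
  reference complex (4.5 Å contact rule), project the annotation onto
  other structures (sequence-guided superposition, 2 Å most-atoms
  rule), close label gaps, strip capping groups, and discard substrates
  with fewer than three pocket residues.  Catalytic residues can be
  inferred by homology (>50 % identity transfer).
* **Substrate modelling** — replace non-natural amino acids by their
  most similar natural analogue (circular-fingerprint Tanimoto
  similarity), rebuild side chains with ideal geometry, reconstruct
  missing P positions up to the full P4–P4′ 8-mer, and thread random
  peptide libraries (480 8-mers, uniform per position) onto the
  template.
* **Sampling** — a Metropolis Monte Carlo sampler with backrub-style
  rigid-segment backbone rotations and Gaussian side-chain torsion
  moves under a pluggable Lennard-Jones + screened-Coulomb + H-bond
  energy model (defaults: 5000 steps, kT 1.2, 500 frames).
* **Observables** — per-frame, per-position relative accessible surface
  area (Shrake–Rupley), hydrogen bonds and non-bonded contacts split by
  main/side chain, and per-residue interface energies; averaged as
  O<sub>ij</sub> over runs and frames and compared with the entropy
  profile by per-position Spearman correlation.
* **Fixtures** — deterministic toy protease–peptide complexes (a
  β-groove with an engineered S1 pocket and catalytic Ser/His) and toy
  specificity matrices with entropies known by construction, so the
  whole pipeline runs and is testable without any downloads.

Everything is tidyverse-native: structures are tibbles of atom records,
results come back as tibbles with `tidy()`/`glance()` methods, and
result objects have `autoplot()` methods.

## Worked example

```r
library(subsites)

# a toy complex: extended peptide in a beta-groove "protease"
fx <- make_toy_complex(fixture_spec(seed = 1))

# annotate its pockets from the reference positions
asg <- assign_pockets_from_reference(fx$structure, "P", fx$ref_positions)
asg
#> Pocket assignment (peptide chain P):
#>   K:S4 A:S3 T:S2 L:S1 S:S1' V:S2' N:S3' E:S4'
#>   36 pocket residues, cleavage site present

# entropies of a toy specificity matrix: P1 and P2 one-hot, rest uniform
sm  <- make_toy_matrix(specific_positions = c("P1", "P2"),
                       promiscuous_positions = setdiff(P_LABELS, c("P1", "P2")))
ent <- cleavage_entropy(sm)
tidy(ent)
#> # A tibble: 8 x 2
#>   position     H
#>   <fct>    <dbl>
#> 1 P4           1
#> 2 P3           1
#> 3 P2           0
#> 4 P1           0
#> 5 P1'          1
#> ...
total_cleavage_entropy(ent)
#> [1] 6

# the full pipeline on the fixture: thread a 4-peptide random library,
# sample 200 Monte Carlo steps each, average the observables and
# correlate them with H(j)
run <- run_pipeline(
  pipeline_config(library_n = 4, n_steps = 200, seed = 1),
  list(structures = list(toy = fx$structure),
       catalytic  = cbind(pdb_id = "toy", fx$catalytic),
       reference  = list(id = "toy", ref_positions = fx$ref_positions),
       peptide_chains = c(toy = "P"),
       specmat = sm))
dplyr::filter(run$results$toy$observables$position, observable == "rel_asa")
#> # A tibble: 8 x 4
#>   observable position  mean normalized
#>   <chr>      <fct>    <dbl>      <dbl>
#> 1 rel_asa    P4       0.596      1
#> 2 rel_asa    P3       0.265      0.244
#> 3 rel_asa    P2       0.410      0.575
#> 4 rel_asa    P1       0.159      0
#> 5 rel_asa    P1'      0.358      0.457
#> 6 rel_asa    P2'      0.394      0.539
#> 7 rel_asa    P3'      0.427      0.615
#> 8 rel_asa    P4'      0.547      0.890

run$comparison
#> # A tibble: 6 x 3
#>   observable rho_mean n_structures
#>   <chr>         <dbl>        <int>
#> 1 energy        0.252            1
#> 2 hb_main      -0.775            1
#> 3 hb_side      -0.630            1
#> 4 nb_main       0                1
#> 5 nb_side       0                1
#> 6 rel_asa       0.378            1
```

The P1 position — sitting in the engineered S1 pocket — comes out as
the most buried position (relative ASA 0.159, the minimum) with the
strongest interface energy (−9.37 model units), the pattern expected
at the cleavage site; relative ASA and interface energy are also the
observables whose per-position profiles correlate positively with the
entropy profile of the toy matrix.  A thin
command-line wrapper (`inst/cli/subsites.R`) exposes `fixtures`,
`entropy`, `library`, `annotate` and `pipeline` subcommands for shell
use.

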