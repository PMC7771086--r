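# Pluggable pairwise energy model: 12-6 Lennard-Jones with element-based
# parameters, Coulomb electrostatics under a distance-dependent
# dielectric, and a geometric hydrogen-bond bonus.  Units are arbitrary
# (model-internal); every downstream use is comparative.  Pairs within a
# residue, and between sequence-adjacent residues of the same chain, are
# excluded as bonded.

#' Construct an energy model
#'
#' @param w_lj,w_coulomb,w_hbond dimensionless term weights.
#' @param dielectric distance-dependent dielectric coefficient D in
#'   eps(r) = D*r.  The default of 12 screens bare surface charges
#'   strongly, reflecting that every charge here sits at the
#'   solvent-exposed surface of a small complex with no explicit
#'   solvent.
#' @param cutoff non-bonded cutoff in Angstrom (no long-range
#'   correction).
#' @return object of class `subsites_energy_model`.
#' @export
energy_model <- function(w_lj = 1, w_coulomb = 1, w_hbond = 1,
                         dielectric = 12, cutoff = 10) {
  out <- list(w_lj = w_lj, w_coulomb = w_coulomb, w_hbond = w_hbond,
              dielectric = dielectric, cutoff = cutoff)
  class(out) <- "subsites_energy_model"
  out
}

# Is each atom a plausible hydrogen-bond donor or acceptor heavy atom?
# (name-based, used only for the energy bonus term)
hb_capable <- function(structure) {
  don <- logical(nrow(structure))
  don[donor_atoms(structure)] <- TRUE
  acc <- logical(nrow(structure))
  acc[acceptor_atoms(structure)] <- TRUE
  list(donor = don, acceptor = acc)
}

# Cross energy between two disjoint atom index sets.  Returns the summed
# energy; bonded pairs (same residue or sequence-adjacent in the same
# chain) are skipped.
energy_between <- function(structure, ia, ib, model, precomp = NULL) {
  if (length(ia) == 0 || length(ib) == 0) return(0)
  pc <- precomp %||% energy_precompute(structure)
  xyz <- pc$xyz
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hits <- which(d2 < model$cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(0)
  i <- ia[hits[, 1]]
  j <- ib[hits[, 2]]
  # bonded exclusions
  same_chain <- pc$chain[i] == pc$chain[j]
  near <- same_chain & abs(pc$res_seq[i] - pc$res_seq[j]) <= 1 &
    pc$ins[i] == pc$ins[j]
  same_res <- same_chain & pc$res_seq[i] == pc$res_seq[j] &
    pc$ins[i] == pc$ins[j]
  keep <- !(near | same_res)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(0)
  r2 <- d2[hits[, 1] + (hits[, 2] - 1) * length(ia)][keep]
  if (any(r2 < 1e-12)) {
    abort("overlapping identical atoms (zero distance) in energy evaluation")
  }
  r <- sqrt(r2)
  # Lennard-Jones
  rmin <- pc$lj_rmin[i] + pc$lj_rmin[j]
  eps <- sqrt(pc$lj_eps[i] * pc$lj_eps[j])
  s6 <- (rmin / r)^6
  e_lj <- sum(eps * (s6 * s6 - 2 * s6))
  # Coulomb with eps(r) = D*r  =>  332 q1 q2 / (D r^2)
  e_coul <- sum(332 * pc$charge[i] * pc$charge[j] / (model$dielectric * r2))
  # Hydrogen-bond bonus: donor/acceptor heavy-atom pairs near 2.9 A.
  hb_pair <- (pc$donor[i] & pc$acceptor[j]) | (pc$acceptor[i] & pc$donor[j])
  w <- pmax(0, 1 - abs(r - 2.9) / 0.6)
  e_hb <- -sum(w[hb_pair])
  model$w_lj * e_lj + model$w_coulomb * e_coul + model$w_hbond * e_hb
}

# Precomputed per-atom vectors reused across many pair evaluations.
energy_precompute <- function(structure) {
  lj <- lj_params(structure$element)
  hb <- hb_capable(structure)
  list(
    xyz = atom_coords(structure),
    chain = structure$chain,
    res_seq = structure$res_seq,
    ins = structure$ins,
    lj_rmin = lj$rmin,
    lj_eps = lj$eps,
    charge = atom_partial_charge(structure$res_name, structure$atom),
    donor = hb$donor,
    acceptor = hb$acceptor
  )
}

# Energy within one atom index set (sum over unordered pairs).
energy_within <- function(structure, idx, model, precomp = NULL) {
  n <- length(idx)
  if (n < 2) return(0)
  pc <- precomp %||% energy_precompute(structure)
  total <- 0
  # split in two halves recursively: within(A) + within(B) + between(A,B)
  half <- floor(n / 2)
  a <- idx[seq_len(half)]
  b <- idx[(half + 1):n]
  total <- total + energy_within(structure, a, model, pc)
  total <- total + energy_within(structure, b, model, pc)
  total + energy_between(structure, a, b, model, pc)
}

#' Total energy of a structure
#'
#' Sum of all non-bonded pair terms (Lennard-Jones, Coulomb, H-bond
#' bonus) under the model, excluding intra-residue and
#' sequence-adjacent pairs.
#'
#' @param structure atom tibble with finite coordinates.
#' @param model a [energy_model()].
#' @return scalar energy in model units.
#' @export
total_energy <- function(structure, model = energy_model()) {
  energy_within(structure, seq_len(nrow(structure)), model)
}

#' Protease-peptide interface energy decomposed by peptide position
#'
#' For each peptide residue, sums the cross-partition pair terms that
#' involve that residue.  The per-position energies sum to the total
#' interface energy exactly.
#'
#' @param structure atom tibble (complex).
#' @param peptide_chain peptide chain id.
#' @param model a [energy_model()].
#' @return tibble with chain, res_seq, ins, res_name, energy.
#' @export
interface_energy_per_position <- function(structure, peptide_chain,
                                          model = energy_model()) {
  pc <- energy_precompute(structure)
  pep <- which(structure$chain == peptide_chain)
  other <- which(structure$chain != peptide_chain &
                   !is_water(structure$res_name))
  res <- residue_table(structure[pep, ])
  res$energy <- purrr::pmap_dbl(
    res[, c("chain", "res_seq", "ins")],
    function(chain, res_seq, ins) {
      ia <- pep[structure$res_seq[pep] == res_seq &
                  structure$ins[pep] == ins]
      energy_between(structure, ia, other, model, pc)
    }
  )
  res
}
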