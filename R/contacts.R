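# Geometric hydrogen-bond and non-bonded contact detection across the
# protease/peptide partition.  Criteria follow HBPLUS-style defaults:
# donor-acceptor distance <= 3.9 A, hydrogen-acceptor distance <= 2.5 A,
# donor-hydrogen-acceptor angle >= 90 degrees.  Crystal structures carry
# no hydrogens: the backbone amide H is constructed geometrically from
# N, CA and the preceding carbonyl C; rotatable side-chain hydrogens
# (hydroxyl, thiol, amine) are taken to point at the candidate acceptor,
# which makes the angle criterion moot for them and tightens the
# effective distance criterion to D-A <= h_a_max + 1 A.

is_water <- function(res_name) toupper(res_name) %in% c("HOH", "WAT", "DOD")

donor_atoms <- function(structure) {
  bb <- structure$atom == "N" & structure$res_name %in% AA3 &
    structure$res_name != "PRO"
  sc <- purrr::map2_lgl(structure$res_name, structure$atom, function(rn, at) {
    at %in% (SIDECHAIN_DONORS[[rn]] %||% character(0))
  })
  which((bb | sc) & !is_water(structure$res_name))
}

acceptor_atoms <- function(structure) {
  bb <- structure$atom %in% c("O", "OXT") & structure$res_name %in% AA3
  sc <- purrr::map2_lgl(structure$res_name, structure$atom, function(rn, at) {
    at %in% (SIDECHAIN_ACCEPTORS[[rn]] %||% character(0))
  })
  which((bb | sc) & !is_water(structure$res_name))
}

# Geometric backbone amide hydrogen for atom row i (must be an N), or
# NULL when the preceding carbonyl C is absent (chain N-terminus).
backbone_h <- function(structure, i) {
  ch <- structure$chain[i]
  rs <- structure$res_seq[i]
  N <- c(structure$x[i], structure$y[i], structure$z[i])
  ca <- which(structure$chain == ch & structure$res_seq == rs &
                structure$atom == "CA")
  cp <- which(structure$chain == ch & structure$res_seq == rs - 1 &
                structure$atom == "C")
  if (length(ca) == 0 || length(cp) == 0) return(NULL)
  CA <- c(structure$x[ca[1]], structure$y[ca[1]], structure$z[ca[1]])
  Cp <- c(structure$x[cp[1]], structure$y[cp[1]], structure$z[cp[1]])
  N + 0.98 * unit(unit(N - CA) + unit(N - Cp))
}

#' Detect cross-partition hydrogen bonds
#'
#' Finds donor-acceptor pairs between the peptide chain and the rest of
#' the structure satisfying the geometric criteria.
#'
#' @param structure atom tibble (complex).
#' @param peptide_chain chain id of the peptide partition.
#' @param d_a_max donor-acceptor distance ceiling, Angstrom.
#' @param h_a_max hydrogen-acceptor distance ceiling, Angstrom.
#' @param angle_min minimum donor-hydrogen-acceptor angle, degrees.
#' @return tibble of contact records with one row per hydrogen bond:
#'   donor/acceptor addresses, geometry, `part` ("main"/"side" from the
#'   peptide-side atom) and `pep_res_seq` (peptide residue number).
#' @export
detect_hbonds <- function(structure, peptide_chain, d_a_max = 3.9,
                          h_a_max = 2.5, angle_min = 90) {
  don <- donor_atoms(structure)
  acc <- acceptor_atoms(structure)
  xyz <- atom_coords(structure)
  pep <- structure$chain == peptide_chain
  pairs <- rbind(
    expand.grid(d = don[pep[don]], a = acc[!pep[acc]]),
    expand.grid(d = don[!pep[don]], a = acc[pep[acc]])
  )
  if (nrow(pairs) == 0) return(empty_contacts())
  dvec <- sqrt(rowSums((xyz[pairs$d, , drop = FALSE] -
                          xyz[pairs$a, , drop = FALSE])^2))
  pairs <- pairs[dvec <= d_a_max & dvec > 0.1, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_contacts())
  rows <- purrr::pmap(pairs, function(d, a) {
    D <- xyz[d, ]; A <- xyz[a, ]
    dist_da <- vnorm(A - D)
    if (structure$atom[d] == "N") {
      H <- backbone_h(structure, d)
    } else {
      H <- NULL  # rotatable: points at the acceptor
    }
    if (is.null(H)) {
      h_a <- dist_da - 1.0
      ang <- 180
    } else {
      h_a <- vnorm(A - H)
      ang <- bond_angle(D, H, A)
    }
    if (h_a > h_a_max || ang < angle_min) return(NULL)
    pep_idx <- if (structure$chain[d] == peptide_chain) d else a
    tibble(
      donor_chain = structure$chain[d], donor_res = structure$res_seq[d],
      donor_atom = structure$atom[d],
      acceptor_chain = structure$chain[a],
      acceptor_res = structure$res_seq[a],
      acceptor_atom = structure$atom[a],
      distance = dist_da, angle = ang,
      type = "hbond",
      part = if (structure$is_backbone[pep_idx]) "main" else "side",
      pep_res_seq = structure$res_seq[pep_idx]
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty_contacts() else out
}

empty_contacts <- function() {
  tibble(
    donor_chain = character(0), donor_res = integer(0),
    donor_atom = character(0), acceptor_chain = character(0),
    acceptor_res = integer(0), acceptor_atom = character(0),
    distance = numeric(0), angle = numeric(0), type = character(0),
    part = character(0), pep_res_seq = integer(0)
  )
}

#' Detect cross-partition non-bonded contacts
#'
#' Heavy-atom pairs across the peptide/protease partition within
#' `cutoff`, excluding pairs already recorded as hydrogen bonds.
#'
#' @param structure atom tibble.
#' @param peptide_chain peptide chain id.
#' @param cutoff distance ceiling in Angstrom.
#' @param hbonds optional precomputed output of [detect_hbonds()] used
#'   for the exclusion; computed internally when `NULL`.
#' @return tibble of contact records (columns as [detect_hbonds()], with
#'   `type` "nonbonded" and donor/acceptor read as atom1/atom2).
#' @export
detect_nonbonded <- function(structure, peptide_chain, cutoff = 3.9,
                             hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(structure, peptide_chain)
  heavy <- structure$element != "H" & !is_water(structure$res_name)
  pep <- which(heavy & structure$chain == peptide_chain)
  other <- which(heavy & structure$chain != peptide_chain)
  if (length(pep) == 0 || length(other) == 0) return(empty_contacts())
  xyz <- atom_coords(structure)
  d <- cross_dist(xyz[pep, , drop = FALSE], xyz[other, , drop = FALSE])
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())
  i <- pep[hits[, 1]]
  j <- other[hits[, 2]]
  key <- function(a, b) {
    paste(structure$chain[a], structure$res_seq[a], structure$atom[a],
          structure$chain[b], structure$res_seq[b], structure$atom[b])
  }
  hb_keys <- c(
    paste(hbonds$donor_chain, hbonds$donor_res, hbonds$donor_atom,
          hbonds$acceptor_chain, hbonds$acceptor_res, hbonds$acceptor_atom),
    paste(hbonds$acceptor_chain, hbonds$acceptor_res, hbonds$acceptor_atom,
          hbonds$donor_chain, hbonds$donor_res, hbonds$donor_atom)
  )
  keep <- !(key(i, j) %in% hb_keys)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(empty_contacts())
  tibble(
    donor_chain = structure$chain[i], donor_res = structure$res_seq[i],
    donor_atom = structure$atom[i],
    acceptor_chain = structure$chain[j],
    acceptor_res = structure$res_seq[j],
    acceptor_atom = structure$atom[j],
    distance = d[hits[, 1] + (hits[, 2] - 1) * length(pep)][keep],
    angle = NA_real_,
    type = "nonbonded",
    part = ifelse(structure$is_backbone[i], "main", "side"),
    pep_res_seq = structure$res_seq[i]
  )
}
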