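# Chemistry tables: van der Waals radii, Lennard-Jones parameters, coarse
# partial charges, reference maximal accessible areas, side-chain internal
# coordinates (z-matrix rows), chi-angle definitions and side-chain
# element/bond graphs for the 20 standard amino acids plus norleucine
# (NLE), the modified residue used in the toy fixtures.

# Van der Waals radii (Angstrom) by element, used by the accessible-area
# engine and the clash detector.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

element_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  if (any(is.na(r))) {
    bad <- unique(element[is.na(r)])
    abort(paste0("no van der Waals radius configured for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(r)
}

# 12-6 Lennard-Jones parameters by element: rmin is the per-atom radius at
# the potential minimum (combined additively), eps the well depth in the
# model's arbitrary energy units (combined geometrically).
LJ_RMIN <- c(C = 1.90, N = 1.85, O = 1.70, S = 2.00, H = 1.00, P = 2.10)
LJ_EPS  <- c(C = 0.07, N = 0.17, O = 0.12, S = 0.45, H = 0.02, P = 0.20)
LJ_RMIN_DEFAULT <- 1.90
LJ_EPS_DEFAULT <- 0.10

lj_params <- function(element) {
  e <- toupper(element)
  rmin <- LJ_RMIN[e]
  eps <- LJ_EPS[e]
  rmin[is.na(rmin)] <- LJ_RMIN_DEFAULT
  eps[is.na(eps)] <- LJ_EPS_DEFAULT
  list(rmin = unname(rmin), eps = unname(eps))
}

# Coarse partial charges.  Backbone charges follow a reduced polar-group
# scheme; side-chain polar atoms carry united-atom style charges with the
# missing hydrogens folded into the heavy atom, since crystal structures
# carry no hydrogens.  Units: elementary charge.
BACKBONE_CHARGES <- c(N = -0.35, H = 0.25, CA = 0.07, C = 0.45,
                      O = -0.45, OXT = -0.50)

SIDECHAIN_CHARGES <- list(
  ARG = c(NE = -0.30, CZ = 0.50, NH1 = 0.40, NH2 = 0.40),
  LYS = c(NZ = 0.60),
  ASP = c(CG = 0.30, OD1 = -0.55, OD2 = -0.55),
  GLU = c(CD = 0.30, OE1 = -0.55, OE2 = -0.55),
  ASN = c(CG = 0.40, OD1 = -0.45, ND2 = 0.05),
  GLN = c(CD = 0.40, OE1 = -0.45, NE2 = 0.05),
  HIS = c(ND1 = -0.10, NE2 = -0.10, CE1 = 0.20),
  SER = c(OG = -0.30),
  THR = c(OG1 = -0.30),
  TYR = c(OH = -0.30),
  TRP = c(NE1 = 0.05),
  CYS = c(SG = -0.10),
  MET = c(SD = -0.10)
)

atom_partial_charge <- function(res_name, atom) {
  q <- unname(BACKBONE_CHARGES[atom])
  side <- vapply(seq_along(atom), function(i) {
    tab <- SIDECHAIN_CHARGES[[res_name[i]]]
    if (is.null(tab)) return(0)
    v <- tab[atom[i]]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  ifelse(is.na(q), side, q)
}

# Reference maximal accessible surface areas (Angstrom^2) in an extended
# Gly-X-Gly context (theoretical values, Tien et al. style), used to turn
# residue areas into relative accessibilities.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# ---------------------------------------------------------------------------
# Side-chain internal coordinates.  Each row places one atom from three
# previously placed atoms (a-b-c, parent c) with bond length, bond angle
# (b-c-new) and a dihedral (a-b-c-new).  Dihedrals are numbers or
# expressions over chi variables ("chi1", "chi2+120", ...).

zrow <- function(atom, a, b, c, bond, angle, dih) {
  list(atom = atom, a = a, b = b, c = c,
       bond = bond, angle = angle, dih = dih)
}

cb_row <- function(bond = 1.53, angle = 110.5) {
  zrow("CB", "C", "N", "CA", bond, angle, "-122.0")
}

SIDE_CHAIN_ZMAT <- list(
  ALA = list(cb_row()),
  ARG = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.52, 111.5, "chi2"),
    zrow("NE", "CB", "CG", "CD", 1.46, 112.0, "chi3"),
    zrow("CZ", "CG", "CD", "NE", 1.33, 124.0, "chi4"),
    zrow("NH1", "CD", "NE", "CZ", 1.33, 120.0, "0"),
    zrow("NH2", "CD", "NE", "CZ", 1.33, 120.0, "180")
  ),
  ASN = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 113.0, "chi1"),
    zrow("OD1", "CA", "CB", "CG", 1.23, 121.0, "chi2"),
    zrow("ND2", "CA", "CB", "CG", 1.33, 117.0, "chi2+180")
  ),
  ASP = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 113.0, "chi1"),
    zrow("OD1", "CA", "CB", "CG", 1.25, 119.0, "chi2"),
    zrow("OD2", "CA", "CB", "CG", 1.25, 119.0, "chi2+180")
  ),
  CYS = list(
    cb_row(),
    zrow("SG", "N", "CA", "CB", 1.81, 114.0, "chi1")
  ),
  GLN = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.52, 112.5, "chi2"),
    zrow("OE1", "CB", "CG", "CD", 1.23, 121.0, "chi3"),
    zrow("NE2", "CB", "CG", "CD", 1.33, 117.0, "chi3+180")
  ),
  GLU = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.52, 112.5, "chi2"),
    zrow("OE1", "CB", "CG", "CD", 1.25, 119.0, "chi3"),
    zrow("OE2", "CB", "CG", "CD", 1.25, 119.0, "chi3+180")
  ),
  GLY = list(),
  HIS = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.50, 114.0, "chi1"),
    zrow("ND1", "CA", "CB", "CG", 1.38, 122.5, "chi2"),
    zrow("CD2", "CA", "CB", "CG", 1.36, 129.5, "chi2+180"),
    zrow("CE1", "CB", "CG", "ND1", 1.32, 109.0, "180"),
    zrow("NE2", "CB", "CG", "CD2", 1.37, 107.0, "180")
  ),
  ILE = list(
    cb_row(),
    zrow("CG1", "N", "CA", "CB", 1.53, 110.5, "chi1"),
    zrow("CG2", "N", "CA", "CB", 1.53, 110.5, "chi1+120"),
    zrow("CD1", "CA", "CB", "CG1", 1.52, 113.5, "chi2")
  ),
  LEU = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.53, 116.0, "chi1"),
    zrow("CD1", "CA", "CB", "CG", 1.52, 110.5, "chi2"),
    zrow("CD2", "CA", "CB", "CG", 1.52, 110.5, "chi2+120")
  ),
  LYS = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.52, 111.5, "chi2"),
    zrow("CE", "CB", "CG", "CD", 1.52, 111.5, "chi3"),
    zrow("NZ", "CG", "CD", "CE", 1.47, 111.0, "chi4")
  ),
  MET = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("SD", "CA", "CB", "CG", 1.81, 112.5, "chi2"),
    zrow("CE", "CB", "CG", "SD", 1.79, 100.5, "chi3")
  ),
  PHE = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.50, 114.0, "chi1"),
    zrow("CD1", "CA", "CB", "CG", 1.39, 120.5, "chi2"),
    zrow("CD2", "CA", "CB", "CG", 1.39, 120.5, "chi2+180"),
    zrow("CE1", "CB", "CG", "CD1", 1.39, 120.5, "180"),
    zrow("CE2", "CB", "CG", "CD2", 1.39, 120.5, "180"),
    zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, "0")
  ),
  PRO = list(
    zrow("CB", "C", "N", "CA", 1.53, 103.0, "-120.0"),
    zrow("CG", "N", "CA", "CB", 1.49, 104.5, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.50, 105.5, "chi2")
  ),
  SER = list(
    cb_row(),
    zrow("OG", "N", "CA", "CB", 1.42, 111.0, "chi1")
  ),
  THR = list(
    cb_row(),
    zrow("OG1", "N", "CA", "CB", 1.43, 110.0, "chi1"),
    zrow("CG2", "N", "CA", "CB", 1.53, 111.0, "chi1+120")
  ),
  TRP = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.50, 114.0, "chi1"),
    zrow("CD1", "CA", "CB", "CG", 1.37, 127.0, "chi2"),
    zrow("CD2", "CA", "CB", "CG", 1.43, 126.5, "chi2+180"),
    zrow("NE1", "CB", "CG", "CD1", 1.38, 110.0, "180"),
    zrow("CE2", "CB", "CG", "CD2", 1.41, 107.0, "180"),
    zrow("CE3", "CB", "CG", "CD2", 1.40, 133.5, "0"),
    zrow("CZ2", "CG", "CD2", "CE2", 1.40, 122.0, "180"),
    zrow("CZ3", "CE2", "CD2", "CE3", 1.39, 118.5, "0"),
    zrow("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, "0")
  ),
  TYR = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.50, 114.0, "chi1"),
    zrow("CD1", "CA", "CB", "CG", 1.39, 120.5, "chi2"),
    zrow("CD2", "CA", "CB", "CG", 1.39, 120.5, "chi2+180"),
    zrow("CE1", "CB", "CG", "CD1", 1.39, 120.5, "180"),
    zrow("CE2", "CB", "CG", "CD2", 1.39, 120.5, "180"),
    zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, "0"),
    zrow("OH", "CD1", "CE1", "CZ", 1.38, 120.0, "180")
  ),
  VAL = list(
    cb_row(),
    zrow("CG1", "N", "CA", "CB", 1.53, 111.0, "chi1"),
    zrow("CG2", "N", "CA", "CB", 1.53, 111.0, "chi1+120")
  ),
  NLE = list(
    cb_row(),
    zrow("CG", "N", "CA", "CB", 1.52, 114.0, "chi1"),
    zrow("CD", "CA", "CB", "CG", 1.52, 111.5, "chi2"),
    zrow("CE", "CB", "CG", "CD", 1.52, 111.5, "chi3")
  )
)

# Most-common-rotamer defaults used when chi angles cannot be copied from
# the template residue.
DEFAULT_CHI <- list(
  generic = c(chi1 = -65, chi2 = 180, chi3 = 180, chi4 = 180),
  PHE = c(chi1 = -65, chi2 = 90),
  TYR = c(chi1 = -65, chi2 = 90),
  TRP = c(chi1 = -65, chi2 = 95),
  HIS = c(chi1 = -65, chi2 = 90),
  ASN = c(chi1 = -65, chi2 = -20),
  ASP = c(chi1 = -65, chi2 = -15),
  PRO = c(chi1 = 30, chi2 = -35)
)

default_chi <- function(res_name) {
  tab <- DEFAULT_CHI[[res_name]] %||% numeric(0)
  out <- DEFAULT_CHI$generic
  out[names(tab)] <- tab
  out
}

# Atom quadruples defining the chi torsions of each residue; used both to
# measure chi angles on an existing residue and to identify the rotatable
# bonds for side-chain Monte Carlo moves.
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  NLE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"))
)

# Hydrogen-bond chemistry: side-chain donor and acceptor heavy atoms by
# residue.  Backbone amide N (except proline) is always a donor; backbone
# carbonyl O always an acceptor.
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1"
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG"
)

# ---------------------------------------------------------------------------
# Side-chain element/bond graphs for fingerprinting.  The alpha carbon
# is prepended as atom 1 to anchor the attachment point (norleucine and
# isoleucine side chains are otherwise isomorphic C4 graphs); atom 2 is
# CB.  Bond orders: 1 single, 1.5 aromatic/resonant, 2 double.

side_graph <- function(elements, bonds = NULL) {
  if (is.null(bonds)) {
    bonds <- matrix(numeric(0), ncol = 3)
  } else {
    bonds <- matrix(bonds, ncol = 3, byrow = TRUE)
  }
  if (length(elements) > 0) {
    bonds[, 1:2] <- bonds[, 1:2] + 1
    bonds <- rbind(c(1, 2, 1), bonds)
    elements <- c("C", elements)
  } else {
    elements <- "C"
  }
  colnames(bonds) <- c("i", "j", "order")
  list(elements = elements, bonds = bonds)
}

SIDE_CHAIN_GRAPHS <- list(
  ALA = side_graph("C"),
  ARG = side_graph(c("C", "C", "C", "N", "C", "N", "N"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1.5, 5, 6, 1.5, 5, 7, 1.5)),
  ASN = side_graph(c("C", "C", "O", "N"),
                   c(1, 2, 1, 2, 3, 2, 2, 4, 1)),
  ASP = side_graph(c("C", "C", "O", "O"),
                   c(1, 2, 1, 2, 3, 1.5, 2, 4, 1.5)),
  CYS = side_graph(c("C", "S"), c(1, 2, 1)),
  GLN = side_graph(c("C", "C", "C", "O", "N"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 2, 3, 5, 1)),
  GLU = side_graph(c("C", "C", "C", "O", "O"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 1.5, 3, 5, 1.5)),
  GLY = side_graph(character(0)),
  HIS = side_graph(c("C", "C", "N", "C", "C", "N"),
                   c(1, 2, 1, 2, 3, 1.5, 2, 4, 1.5, 3, 5, 1.5, 4, 6, 1.5,
                     5, 6, 1.5)),
  ILE = side_graph(c("C", "C", "C", "C"),
                   c(1, 2, 1, 1, 3, 1, 2, 4, 1)),
  LEU = side_graph(c("C", "C", "C", "C"),
                   c(1, 2, 1, 2, 3, 1, 2, 4, 1)),
  LYS = side_graph(c("C", "C", "C", "C", "N"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1)),
  MET = side_graph(c("C", "C", "S", "C"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 1)),
  PHE = side_graph(c("C", "C", "C", "C", "C", "C", "C"),
                   c(1, 2, 1, 2, 3, 1.5, 2, 4, 1.5, 3, 5, 1.5, 4, 6, 1.5,
                     5, 7, 1.5, 6, 7, 1.5)),
  PRO = side_graph(c("C", "C", "C"), c(1, 2, 1, 2, 3, 1)),
  SER = side_graph(c("C", "O"), c(1, 2, 1)),
  THR = side_graph(c("C", "O", "C"), c(1, 2, 1, 1, 3, 1)),
  TRP = side_graph(c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
                   c(1, 2, 1, 2, 3, 1.5, 2, 4, 1.5, 3, 5, 1.5, 5, 6, 1.5,
                     4, 6, 1.5, 4, 7, 1.5, 7, 8, 1.5, 8, 9, 1.5, 9, 10, 1.5,
                     10, 6, 1.5)),
  TYR = side_graph(c("C", "C", "C", "C", "C", "C", "C", "O"),
                   c(1, 2, 1, 2, 3, 1.5, 2, 4, 1.5, 3, 5, 1.5, 4, 6, 1.5,
                     5, 7, 1.5, 6, 7, 1.5, 7, 8, 1)),
  VAL = side_graph(c("C", "C", "C"), c(1, 2, 1, 1, 3, 1)),
  NLE = side_graph(c("C", "C", "C", "C"),
                   c(1, 2, 1, 2, 3, 1, 3, 4, 1))
)

#' Side-chain chemical graph of a residue
#'
#' Returns the heavy-atom element/bond graph of a residue's side chain
#' anchored at the alpha carbon (atom 1), the input form consumed by
#' the fingerprint-based residue mapping.
#'
#' @param res_name 3-letter residue code (20 standard amino acids or NLE).
#' @return list with `elements` (character vector) and `bonds` (matrix
#'   with columns i, j, order).
#' @export
residue_graph <- function(res_name) {
  g <- SIDE_CHAIN_GRAPHS[[toupper(res_name)]]
  if (is.null(g)) {
    abort(paste0("no side-chain graph available for residue ", res_name))
  }
  g
}
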