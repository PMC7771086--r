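# Ideal-geometry construction of peptide backbones and side chains.  Used
# by the toy-complex fixtures, the mutation engine and the missing-residue
# reconstruction.  Standard backbone internal coordinates: N-CA 1.458,
# CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; angles N-CA-C 111.2,
# CA-C-N 116.2, C-N-CA 121.7, CA-C=O 120.8 degrees; trans peptide
# (omega 180) unless stated otherwise.

BB_N_CA <- 1.458
BB_CA_C <- 1.525
BB_C_N <- 1.329
BB_C_O <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

atom_element_from_name <- function(atom) {
  toupper(substr(gsub("^[0-9]+", "", atom), 1, 1))
}

# Evaluate a z-matrix dihedral expression ("chi2+120", "-122.0", ...).
eval_dihedral_expr <- function(expr, chi) {
  m <- regmatches(expr, regexec("^(chi[1-4])([+-][0-9.]+)?$", expr))[[1]]
  if (length(m) == 0) return(as.numeric(expr))
  base <- chi[[m[2]]]
  offset <- if (m[3] == "") 0 else as.numeric(m[3])
  base + offset
}

#' Build side-chain atoms onto an existing backbone
#'
#' Places the side-chain heavy atoms of `res_name` with ideal bond lengths
#' and angles, given the residue's backbone atoms N, CA and C.
#'
#' @param backbone named list (or tibble rows) with 3-vectors `N`, `CA`,
#'   `C`.
#' @param res_name 3-letter code with a configured template.
#' @param chi named numeric vector of chi angles in degrees; missing
#'   angles fall back to the residue's most common rotamer.
#' @return tibble with columns atom, element, x, y, z (side-chain atoms
#'   only, possibly empty for glycine).
#' @export
build_side_chain <- function(backbone, res_name, chi = NULL) {
  zmat <- SIDE_CHAIN_ZMAT[[toupper(res_name)]]
  if (is.null(zmat)) {
    abort(paste0("no side-chain template for residue ", res_name))
  }
  chi_full <- default_chi(toupper(res_name))
  if (!is.null(chi) && length(chi) > 0) chi_full[names(chi)] <- chi
  pos <- list(N = backbone$N, CA = backbone$CA, C = backbone$C)
  rows <- purrr::map(zmat, function(zr) {
    for (ref in c(zr$a, zr$b, zr$c)) {
      if (is.null(pos[[ref]])) {
        abort(paste0("missing reference atom ", ref, " while building ",
                     res_name))
      }
    }
    xyz <- place_atom(pos[[zr$a]], pos[[zr$b]], pos[[zr$c]],
                      zr$bond, zr$angle,
                      eval_dihedral_expr(zr$dih, as.list(chi_full)))
    pos[[zr$atom]] <<- xyz
    tibble(atom = zr$atom, element = atom_element_from_name(zr$atom),
           x = xyz[1], y = xyz[2], z = xyz[3])
  })
  bind_rows(rows)
}

# Coordinates of one named atom in a residue slice of a structure tibble.
atom_xyz <- function(res_tbl, name) {
  i <- which(res_tbl$atom == name)
  if (length(i) == 0) return(NULL)
  c(res_tbl$x[i[1]], res_tbl$y[i[1]], res_tbl$z[i[1]])
}

#' Measure the chi angles of a residue
#'
#' @param res_tbl atom tibble slice of a single residue.
#' @param res_name 3-letter code naming the chi definitions to use.
#' @return named numeric vector (chi1, chi2, ...) with entries only for
#'   torsions whose four defining atoms are present.
#' @export
measure_chi <- function(res_tbl, res_name) {
  defs <- CHI_ATOMS[[toupper(res_name)]]
  if (is.null(defs)) return(numeric(0))
  out <- numeric(0)
  for (k in seq_along(defs)) {
    pts <- lapply(defs[[k]], atom_xyz, res_tbl = res_tbl)
    if (any(vapply(pts, is.null, logical(1)))) next
    out[paste0("chi", k)] <- dihedral_angle(pts[[1]], pts[[2]],
                                            pts[[3]], pts[[4]])
  }
  out
}

# Descendants of an atom in the side-chain construction tree (children
# recursively), e.g. everything distal to CB for a chi1 rotation.
sidechain_descendants <- function(res_name, of_atom) {
  zmat <- SIDE_CHAIN_ZMAT[[toupper(res_name)]]
  if (is.null(zmat)) return(character(0))
  parent <- vapply(zmat, function(z) z$c, character(1))
  names(parent) <- vapply(zmat, function(z) z$atom, character(1))
  out <- character(0)
  frontier <- of_atom
  while (length(frontier) > 0) {
    kids <- names(parent)[parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Rotate one chi torsion of a residue in place
#'
#' Rotates all atoms distal to the torsion's central bond by `delta`
#' degrees, leaving the backbone untouched.
#'
#' @param structure atom tibble.
#' @param chain_id,res_seq residue address.
#' @param which_chi integer chi index (1-4).
#' @param delta rotation in degrees.
#' @return the modified structure.
#' @export
rotate_chi <- function(structure, chain_id, res_seq, which_chi, delta) {
  sel <- structure$chain == chain_id & structure$res_seq == res_seq
  res_tbl <- structure[sel, ]
  res_name <- res_tbl$res_name[1]
  defs <- CHI_ATOMS[[toupper(res_name)]]
  if (is.null(defs) || which_chi > length(defs)) {
    abort(paste0("residue ", res_name, " has no chi", which_chi))
  }
  quad <- defs[[which_chi]]
  b <- atom_xyz(res_tbl, quad[2])
  c_ <- atom_xyz(res_tbl, quad[3])
  if (is.null(b) || is.null(c_)) abort("torsion atoms missing")
  moving <- c(quad[4], sidechain_descendants(res_name, quad[3]))
  idx <- which(sel)[res_tbl$atom %in% unique(moving)]
  if (length(idx) == 0) return(structure)
  xyz <- as.matrix(structure[idx, c("x", "y", "z")])
  # rotating distal atoms by -delta about b->c raises the measured
  # a-b-c-d torsion by +delta under this package's sign convention
  xyz <- rotate_points(xyz, b, c_ - b, -delta)
  structure[idx, c("x", "y", "z")] <- as.data.frame(xyz)
  structure
}

#' Build an ideal-geometry peptide chain
#'
#' Constructs a poly-peptide backbone (with side chains) residue by
#' residue from internal coordinates.  The first residue's N sits at
#' `origin` with the chain propagating along +x before torsions bend it.
#'
#' @param sequence 1-letter amino-acid string (NLE may be given as its
#'   3-letter code inside `res_names`).
#' @param chain_id chain identifier for the built chain.
#' @param phi,psi,omega backbone torsions in degrees, recycled along the
#'   chain; defaults are an extended beta conformation.
#' @param start_res first author residue number.
#' @param origin 3-vector for the first N atom.
#' @param res_names optional character vector of 3-letter codes
#'   overriding `sequence` (for hetero residues).
#' @param het logical, mark records as HETATM.
#' @return atom tibble of the built chain.
#' @export
build_peptide <- function(sequence, chain_id = "P", phi = -139, psi = 135,
                          omega = 180, start_res = 1L,
                          origin = c(0, 0, 0), res_names = NULL,
                          het = FALSE) {
  res3 <- if (is.null(res_names)) {
    aa_one_to_three(strsplit(toupper(sequence), "")[[1]])
  } else {
    toupper(res_names)
  }
  nres <- length(res3)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  omega <- rep_len(omega, nres)

  # Seed atoms for residue 1: N at origin, CA along +x, C in the z=0 plane.
  N1 <- origin
  CA1 <- origin + c(BB_N_CA, 0, 0)
  th <- deg2rad(ANG_N_CA_C)
  C1 <- CA1 + BB_CA_C * c(-cos(th), sin(th), 0)

  rows <- list()
  prevC <- NULL
  N <- N1; CA <- CA1; C <- C1
  for (i in seq_len(nres)) {
    if (i > 1) {
      # Place N(i), CA(i), C(i) from the previous residue's frame.
      N <- place_atom(prev$N, prev$CA, prev$C, BB_C_N, ANG_CA_C_N, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, BB_N_CA, ANG_C_N_CA, omega[i - 1])
      C <- place_atom(prev$C, N, CA, BB_CA_C, ANG_N_CA_C, phi[i])
    }
    # Carbonyl O: in the peptide plane, opposite the next N (psi + 180).
    O <- place_atom(N, CA, C, BB_C_O, ANG_CA_C_O, psi[i] + 180)
    bb <- tibble(
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(N[1], CA[1], C[1], O[1]),
      y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3])
    )
    side <- build_side_chain(list(N = N, CA = CA, C = C), res3[i])
    res_rows <- bind_rows(bb, side)
    res_rows$chain <- chain_id
    res_rows$res_seq <- start_res + i - 1L
    res_rows$ins <- ""
    res_rows$res_name <- res3[i]
    res_rows$occ <- 1
    res_rows$het <- het
    rows[[i]] <- res_rows
    prev <- list(N = N, CA = CA, C = C)
    prevC <- C
  }
  new_structure(bind_rows(rows), source_id = "built")
}
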