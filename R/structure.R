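# Structure data model: a structure is a tibble of atom records, one row per
# atom, ordered as in the source file.  Columns:
#   chain     chain identifier (single character)
#   res_seq   author residue number
#   ins       insertion code ("" when absent)
#   res_name  3-letter residue name (standard or hetero)
#   atom      atom name
#   element   chemical element symbol
#   x, y, z   coordinates, Angstrom
#   occ       occupancy
#   het       TRUE for HETATM records
#   is_backbone  TRUE for N, CA, C, O, OXT and backbone hydrogens
# The tibble carries a "source_id" attribute (free text, e.g. a PDB id).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                    "HA", "HA2", "HA3")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- setNames(AA3, AA1)

#' Convert residue names between 3-letter and 1-letter codes
#'
#' Non-standard residue names map to `"X"` (respectively `"UNK"`).
#'
#' @param x character vector of residue codes.
#' @return character vector of the converted codes.
#' @export
aa_three_to_one <- function(x) {
  out <- unname(AA1[toupper(x)])
  out[is.na(out)] <- "X"
  out
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  out <- unname(AA3_FROM_1[toupper(x)])
  out[is.na(out)] <- "UNK"
  out
}

new_structure <- function(atoms, source_id = "") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "res_seq", "ins", "res_name", "atom", "element",
              "x", "y", "z", "occ", "het")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("structure table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms$is_backbone <- atoms$atom %in% BACKBONE_ATOMS &
    atoms$res_name %in% AA3
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in structure")
  }
  attr(atoms, "source_id") <- source_id
  atoms
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure an atom tibble as returned by [parse_pdb()].
#' @return an n x 3 numeric matrix (columns x, y, z).
#' @export
atom_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

set_atom_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

# Unique residue table (chain, res_seq, ins, res_name) in file order.
residue_table <- function(structure) {
  distinct(structure, .data$chain, .data$res_seq, .data$ins, .data$res_name)
}

res_id <- function(chain, res_seq, ins = "") {
  paste0(chain, "/", res_seq, ifelse(ins == "" | is.na(ins), "", ins))
}

#' One-letter sequence of a chain
#'
#' @param structure an atom tibble.
#' @param chain_id chain identifier.
#' @return a single string; non-standard residues appear as `"X"`.
#' @export
chain_sequence <- function(structure, chain_id) {
  res <- residue_table(filter(structure, .data$chain == chain_id))
  paste(aa_three_to_one(res$res_name), collapse = "")
}

#' Parse a PDB-format document
#'
#' Reads the ATOM/HETATM records of the first model.  Alternate locations
#' are resolved by keeping the highest-occupancy copy of each atom (ties:
#' first encountered).  Waters and everything else present in the file are
#' kept; downstream operations exclude waters themselves where relevant.
#'
#' @param text PDB document as a single string or a character vector of
#'   lines.
#' @param source_id identifier stored with the structure (defaults to "").
#' @return an atom tibble (see package overview for the column contract).
#' @export
parse_pdb <- function(text, source_id = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  if (!any(grepl("^(ATOM|HETATM)", rec))) {
    offending <- if (length(lines) > 0) lines[1] else "<empty input>"
    abort(paste0("no ATOM/HETATM records found; first line was: ",
                 offending))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  read_pdb(tmp, source_id = source_id)
}

#' @rdname parse_pdb
#' @param file path to a PDB file.
#' @export
read_pdb <- function(file, source_id = NULL) {
  if (is.null(source_id)) {
    source_id <- sub("\\.pdb$", "", basename(file))
  }
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    res_seq = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    res_name = at$resid,
    atom = at$elety,
    element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt)
  )
  # Alternate locations: keep the highest-occupancy copy of each atom.
  atoms <- atoms |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$res_seq, .data$ins, .data$res_name,
             .data$atom) |>
    filter(.data$.ord == .data$.ord[which.max(.data$occ)]) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord", -"alt")
  new_structure(atoms, source_id = source_id)
}

guess_element <- function(elesy, elety) {
  out <- toupper(elesy)
  need <- is.na(out) | out == ""
  if (any(need)) {
    nm <- gsub("[^A-Za-z]", "", elety[need])
    out[need] <- toupper(substr(nm, 1, 1))
  }
  if (any(is.na(out) | out == "")) abort("atom with empty element symbol")
  out
}

#' Write a structure as a PDB-format document
#'
#' @param structure an atom tibble.
#' @param file optional path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return invisibly the lines written (or the lines themselves when
#'   `file` is `NULL`).
#' @export
write_pdb <- function(structure, file = NULL) {
  if (nrow(structure) == 0) abort("cannot write an empty structure")
  if (any(nchar(structure$atom) > 4)) {
    bad <- structure$atom[nchar(structure$atom) > 4][1]
    abort(paste0("atom name exceeds the PDB field width: ", bad))
  }
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = tmp,
    xyz = as.vector(t(atom_coords(structure))),
    type = ifelse(structure$het, "HETATM", "ATOM"),
    resno = structure$res_seq,
    resid = structure$res_name,
    eleno = seq_len(nrow(structure)),
    elety = structure$atom,
    chain = structure$chain,
    insert = ifelse(structure$ins == "", NA, structure$ins),
    o = structure$occ,
    b = rep(0, nrow(structure)),
    elesy = structure$element,
    verbose = FALSE
  )
  lines <- readLines(tmp)
  if (is.null(file)) unlink(tmp)
  invisible(lines)
}

#' Rigid-body superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mov_coords` and `ref_coords` over matched rows.
#'
#' @param ref_coords,mov_coords N x 3 matrices of matched coordinates,
#'   N >= 3, not all collinear.
#' @return an object of class `subsites_superposition`: a list with
#'   `rotation` (3x3, det +1), `translation` (3-vector) and `rmsd`
#'   (Angstrom).  Applying `x %*% t(rotation) + translation` to the moving
#'   coordinates maps them onto the reference frame.
#' @export
superpose <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords)
  mov_coords <- as.matrix(mov_coords)
  if (!all(dim(ref_coords) == dim(mov_coords))) {
    abort("coordinate sets must have identical dimensions")
  }
  n <- nrow(ref_coords)
  if (n < 3) abort("superposition requires at least 3 matched atoms")
  rc <- colMeans(ref_coords)
  mc <- colMeans(mov_coords)
  A <- sweep(ref_coords, 2, rc)
  B <- sweep(mov_coords, 2, mc)
  sv_a <- svd(A)$d
  sv_b <- svd(B)$d
  if (sv_a[2] < 1e-8 || sv_b[2] < 1e-8) {
    abort("degenerate (collinear) coordinate sets cannot be superposed")
  }
  H <- crossprod(B, A)             # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- rc - as.vector(R %*% mc)
  moved <- mov_coords %*% t(R)
  moved <- sweep(moved, 2, t_vec, FUN = "+")
  rmsd <- sqrt(mean(rowSums((moved - ref_coords)^2)))
  res <- list(rotation = R, translation = t_vec, rmsd = rmsd)
  class(res) <- "subsites_superposition"
  res
}

#' Apply a superposition to coordinates or a structure
#'
#' @param x an n x 3 matrix or an atom tibble.
#' @param sp a `subsites_superposition`.
#' @return object of the same kind as `x`, transformed.
#' @export
apply_superposition <- function(x, sp) {
  if (is.matrix(x)) {
    sweep(x %*% t(sp$rotation), 2, sp$translation, FUN = "+")
  } else {
    set_atom_coords(x, apply_superposition(atom_coords(x), sp))
  }
}

#' @export
print.subsites_superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition: rmsd %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (open 10, extend 0.5 by default).  The identity fraction is the number
#' of identical aligned columns divided by the total number of alignment
#' columns, gaps included; `X` never counts as a match.
#'
#' @param query,target amino-acid strings over the 20 standard letters
#'   (plus `X`).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param substitution_matrix scoring matrix name understood by
#'   `Biostrings::pairwiseAlignment()`.
#' @return an object of class `subsites_alignment`: list with
#'   `aligned_query`, `aligned_target` (gapped strings of equal length),
#'   `identity_fraction` and `score`.
#' @export
align_sequences <- function(query, target, gap_open = 10, gap_extend = 0.5,
                            substitution_matrix = "BLOSUM62") {
  check_aa_string(query)
  check_aa_string(target)
  pa <- Biostrings::pairwiseAlignment(
    query, target,
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  aq <- as.character(Biostrings::pattern(pa))
  at <- as.character(Biostrings::subject(pa))
  qs <- strsplit(aq, "")[[1]]
  ts <- strsplit(at, "")[[1]]
  matches <- sum(qs == ts & qs != "-" & qs != "X")
  res <- list(
    aligned_query = aq,
    aligned_target = at,
    identity_fraction = matches / length(qs),
    score = Biostrings::score(pa)
  )
  class(res) <- "subsites_alignment"
  res
}

check_aa_string <- function(s) {
  if (length(s) != 1 || is.na(s) || nchar(s) == 0) {
    abort("sequence must be a single non-empty string")
  }
  bad <- gsub(paste0("[", paste(c(AA1, "X"), collapse = ""), "]"), "",
              toupper(s))
  if (nchar(bad) > 0) {
    abort(paste0("illegal characters in sequence: ",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.subsites_alignment <- function(x, ...) {
  cat(x$aligned_query, "\n", x$aligned_target, "\n", sep = "")
  cat(sprintf("identity %.1f%%, score %.1f\n",
              100 * x$identity_fraction, x$score))
  invisible(x)
}

# Aligned residue index pairs (query_pos, target_pos), 1-based over the
# ungapped sequences; used for catalytic transfer and CA matching.
alignment_index_map <- function(aln) {
  qs <- strsplit(aln$aligned_query, "")[[1]]
  ts <- strsplit(aln$aligned_target, "")[[1]]
  qi <- cumsum(qs != "-")
  ti <- cumsum(ts != "-")
  keep <- qs != "-" & ts != "-"
  cbind(query = qi[keep], target = ti[keep])
}
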