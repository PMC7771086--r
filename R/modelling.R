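# Substrate modelling: mapping non-natural amino acids (NNAAs) onto the
# closest natural residue by circular-fingerprint Tanimoto similarity,
# ideal-geometry side-chain mutation, geometric reconstruction of
# missing P positions, and random peptide library generation/threading.

#' Circular (Morgan-style) fingerprint of a chemical graph
#'
#' Iteratively hashes each atom's neighbourhood (element, degree, bond
#' orders) out to `radius` bonds and returns the set of distinct
#' neighbourhood identifiers across all radii.
#'
#' @param graph list with `elements` and `bonds` as produced by
#'   [residue_graph()].
#' @param radius neighbourhood radius in bonds (default 2).
#' @return character vector: the fingerprint identifier set.
#' @export
circular_fingerprint <- function(graph, radius = 2) {
  n <- length(graph$elements)
  if (n == 0) return(character(0))
  nb <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[k, "i"]; j <- graph$bonds[k, "j"]
      o <- graph$bonds[k, "order"]
      nb[[i]] <- rbind(nb[[i]], c(j, o))
      nb[[j]] <- rbind(nb[[j]], c(i, o))
    }
  }
  degree <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  inv <- paste0(graph$elements, "/", degree)
  all_ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(paste0("(", inv[i], ")"))
      parts <- sort(paste0(nb[[i]][, 2], ":", inv[nb[[i]][, 1]]))
      paste0("(", inv[i], "|", paste(parts, collapse = ","), ")")
    }, character(1))
    all_ids <- c(all_ids, inv)
  }
  unique(all_ids)
}

#' Tanimoto coefficient between two fingerprint sets
#'
#' @param fp_a,fp_b character vectors as returned by
#'   [circular_fingerprint()].  Two empty fingerprints (e.g. two
#'   glycines) count as identical.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) == 0 && length(fp_b) == 0) return(1)
  length(intersect(fp_a, fp_b)) / length(union(fp_a, fp_b))
}

#' Map a non-natural amino acid onto its closest natural analogue
#'
#' Compares the NNAA side-chain graph against each candidate natural
#' amino acid by fingerprint Tanimoto similarity and returns the best
#' candidate.  A best similarity at or below `floor` marks the residue
#' as unreplaceable (the complex is discarded downstream).  Candidate
#' ties break alphabetically.
#'
#' @param nnaa_graph chemical graph of the modified side chain
#'   ([residue_graph()] form).
#' @param candidates character vector of 1-letter candidate codes.
#' @param fingerprinter function(graph) returning an identifier set;
#'   defaults to [circular_fingerprint()].
#' @param floor similarity floor below which no replacement is accepted.
#' @param nnaa_name label stored with the result.
#' @return list of class `subsites_nnaa_mapping`: `nnaa_name`,
#'   `candidate` (1-letter or NA), `similarity`, `replaceable` and the
#'   per-candidate table `all`.
#' @export
map_nnaa_to_natural <- function(nnaa_graph, candidates = AA1,
                                fingerprinter = circular_fingerprint,
                                floor = 0.4, nnaa_name = "NNAA") {
  if (length(candidates) == 0) abort("empty candidate set")
  candidates <- sort(unique(toupper(candidates)))
  fp <- fingerprinter(nnaa_graph)
  sims <- vapply(candidates, function(aa) {
    tanimoto(fp, fingerprinter(residue_graph(aa_one_to_three(aa))))
  }, numeric(1))
  best <- which.max(sims)  # candidates sorted: ties break alphabetically
  replaceable <- sims[best] > floor
  out <- list(
    nnaa_name = nnaa_name,
    candidate = if (replaceable) candidates[best] else NA_character_,
    similarity = unname(sims[best]),
    replaceable = replaceable,
    all = tibble(candidate = candidates, similarity = unname(sims))
  )
  class(out) <- "subsites_nnaa_mapping"
  out
}

#' @export
print.subsites_nnaa_mapping <- function(x, ...) {
  if (x$replaceable) {
    cat(sprintf("%s -> %s (Tanimoto %.3f)\n", x$nnaa_name, x$candidate,
                x$similarity))
  } else {
    cat(sprintf("%s unreplaceable (best Tanimoto %.3f)\n", x$nnaa_name,
                x$similarity))
  }
  invisible(x)
}

# Count steric clashes (< cutoff A) between the heavy atoms of
# `idx` and all heavy atoms outside their own residues.
clash_count <- function(structure, idx, cutoff = 2.0) {
  idx <- idx[structure$element[idx] != "H"]
  if (length(idx) == 0) return(0L)
  other <- setdiff(which(structure$element != "H" &
                           !is_water(structure$res_name)), idx)
  if (length(other) == 0) return(0L)
  a_key <- res_id(structure$chain[idx], structure$res_seq[idx],
                  structure$ins[idx])
  b_key <- res_id(structure$chain[other], structure$res_seq[other],
                  structure$ins[other])
  d <- cross_dist(atom_coords(structure)[idx, , drop = FALSE],
                  atom_coords(structure)[other, , drop = FALSE])
  same <- outer(a_key, b_key, "==")
  # the peptide bond and its 1-3 neighbours between adjacent residues
  # are covalent geometry, not clashes
  bb_names <- c("N", "CA", "C", "O")
  adjacent <- outer(structure$chain[idx], structure$chain[other], "==") &
    abs(outer(structure$res_seq[idx], structure$res_seq[other], "-")) == 1 &
    outer(structure$atom[idx] %in% bb_names,
          structure$atom[other] %in% bb_names, "&")
  sum(d < cutoff & !same & !adjacent)
}

#' Mutate one residue's side chain
#'
#' Replaces the side chain with an ideal-geometry side chain of
#' `new_aa`, leaving the backbone untouched.  Chi angles are copied from
#' the template residue wherever the defining atoms correspond by name;
#' remaining angles come from a small most-common-rotamer table.  The
#' heavy-atom clash count of the new side chain against the rest of the
#' structure (pairs closer than 2 Angstrom) is attached as attribute
#' `clash_count`.
#'
#' @param structure atom tibble.
#' @param chain_id,res_seq residue address.
#' @param new_aa 1-letter target amino acid.
#' @return the mutated structure.
#' @export
mutate_residue <- function(structure, chain_id, res_seq, new_aa) {
  new3 <- aa_one_to_three(new_aa)
  sel <- which(structure$chain == chain_id & structure$res_seq == res_seq)
  if (length(sel) == 0) abort("target residue not found")
  res_tbl <- structure[sel, ]
  have_bb <- c("N", "CA", "C", "O") %in% res_tbl$atom
  if (!all(have_bb)) {
    abort(paste0("residue lacks backbone atoms: ",
                 paste(c("N", "CA", "C", "O")[!have_bb], collapse = ", ")))
  }
  if (res_tbl$res_name[1] == new3) {
    out <- structure
    attr(out, "clash_count") <- clash_count(out, sel)
    return(out)
  }
  chi <- measure_chi(res_tbl, new3)
  bb_rows <- res_tbl[res_tbl$atom %in% BACKBONE_ATOMS |
                       res_tbl$atom %in% c("N", "CA", "C", "O", "OXT"), ]
  side <- build_side_chain(
    list(N = atom_xyz(res_tbl, "N"), CA = atom_xyz(res_tbl, "CA"),
         C = atom_xyz(res_tbl, "C")),
    new3, chi = chi
  )
  if (nrow(side) > 0) {
    side$chain <- chain_id
    side$res_seq <- res_seq
    side$ins <- res_tbl$ins[1]
    side$res_name <- new3
    side$occ <- 1
    side$het <- FALSE
  }
  bb_rows$res_name <- new3
  bb_rows$het <- FALSE
  new_res <- bind_rows(bb_rows, side)
  out <- bind_rows(
    structure[seq_len(min(sel) - 1), ],
    new_res,
    if (max(sel) < nrow(structure))
      structure[(max(sel) + 1):nrow(structure), ]
  )
  out <- new_structure(out, source_id = attr(structure, "source_id") %||% "")
  new_sel <- which(out$chain == chain_id & out$res_seq == res_seq &
                     !out$is_backbone)
  attr(out, "clash_count") <- clash_count(out, new_sel)
  out
}

unmodellable <- function(msg) {
  abort(msg, class = "subsites_unmodellable")
}

#' Reconstruct missing substrate positions
#'
#' Extends a partial bound peptide to the full 8 residues spanning
#' P4-P4' with ideal backbone geometry (C-N 1.33 Angstrom, trans
#' peptide), scanning backbone torsions on a 30-degree grid and keeping
#' the least-clashing conformer of each added residue.  If no grid
#' point is clash-free for some residue the complex is unmodellable and
#' an error of class `subsites_unmodellable` is raised.
#'
#' @param structure atom tibble (complex).
#' @param assignment a `subsites_pockets` covering at least 3
#'   consecutive pockets of the peptide.
#' @param target_sequence 8-letter sequence for P4-P4'; must agree with
#'   the residues already present.
#' @param grid_step torsion scan step in degrees.
#' @return the extended structure; attribute `pocket_map` maps the full
#'   peptide residue numbering onto P4-P4'.
#' @export
reconstruct_missing <- function(structure, assignment, target_sequence,
                                grid_step = 30) {
  target_sequence <- toupper(target_sequence)
  if (nchar(target_sequence) != 8) abort("target sequence must have 8 letters")
  letters8 <- strsplit(target_sequence, "")[[1]]
  pm <- filter(assignment$peptide_map, !is.na(.data$pocket))
  if (nrow(pm) < 3) abort("existing peptide must cover at least 3 pockets")
  pidx <- pocket_index(pm$pocket)
  if (any(diff(pidx) != 1)) {
    abort("existing assigned pockets must be consecutive")
  }
  # consistency with the existing residues
  existing_aa <- aa_three_to_one(pm$res_name)
  mismatch <- existing_aa != letters8[pidx] & existing_aa != "X"
  if (any(mismatch)) {
    abort(paste0("target sequence inconsistent with bound residues at ",
                 paste(P_LABELS[pidx[mismatch]], collapse = ", ")))
  }
  chain_id <- assignment$peptide_chain
  out <- structure
  # --- extend N-terminally (positions pidx[1]-1 down to 1)
  n_missing_n <- pidx[1] - 1
  first_res <- pm$res_seq[1]
  for (k in seq_len(n_missing_n)) {
    pos <- pidx[1] - k
    anchor_seq <- first_res - k + 1L
    out <- extend_terminus(out, chain_id, anchor_seq, new_seq = anchor_seq - 1L,
                           aa = letters8[pos], direction = "N",
                           grid_step = grid_step,
                           label = P_LABELS[pos])
  }
  # --- extend C-terminally
  last_idx <- pidx[length(pidx)]
  n_missing_c <- 8 - last_idx
  last_res <- pm$res_seq[nrow(pm)]
  for (k in seq_len(n_missing_c)) {
    pos <- last_idx + k
    anchor_seq <- last_res + k - 1L
    out <- extend_terminus(out, chain_id, anchor_seq, new_seq = anchor_seq + 1L,
                           aa = letters8[pos], direction = "C",
                           grid_step = grid_step,
                           label = P_LABELS[pos])
  }
  pep_res <- residue_table(filter(out, .data$chain == chain_id))
  if (nrow(pep_res) != 8) {
    unmodellable(sprintf("reconstruction produced %d peptide residues, not 8",
                         nrow(pep_res)))
  }
  attr(out, "pocket_map") <- tibble(res_seq = pep_res$res_seq,
                                    pocket = POCKET_LABELS)
  out
}

# Add one residue at a chain terminus with a torsion grid scan.
extend_terminus <- function(structure, chain_id, anchor_seq, new_seq, aa,
                            direction, grid_step, label) {
  anchor <- structure[structure$chain == chain_id &
                        structure$res_seq == anchor_seq, ]
  N0 <- atom_xyz(anchor, "N"); CA0 <- atom_xyz(anchor, "CA")
  C0 <- atom_xyz(anchor, "C")
  if (is.null(N0) || is.null(CA0) || is.null(C0)) {
    abort("anchor residue lacks backbone atoms")
  }
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  # extended conformation first so it wins clash-count ties
  order_pref <- order(abs(grid + 139) + abs(grid - 135) * 0)
  phis <- grid[order(abs(((grid + 139 + 180) %% 360) - 180))]
  psis <- grid[order(abs(((grid - 135 + 180) %% 360) - 180))]
  best <- NULL
  best_clash <- Inf
  for (phi in phis) {
    for (psi in psis) {
      res <- build_terminal_residue(N0, CA0, C0, aa, direction, phi, psi)
      cand <- res
      cand$chain <- chain_id
      cand$res_seq <- new_seq
      cand$ins <- ""
      cand$res_name <- aa_one_to_three(aa)
      cand$occ <- 1
      cand$het <- FALSE
      trial <- new_structure(bind_rows(structure, cand),
                             source_id = attr(structure, "source_id") %||% "")
      idx <- which(trial$chain == chain_id & trial$res_seq == new_seq)
      cl <- clash_count(trial, idx)
      if (cl < best_clash) {
        best_clash <- cl
        best <- trial
        if (cl == 0) break
      }
    }
    if (best_clash == 0) break
  }
  if (best_clash > 0) {
    unmodellable(sprintf(
      "no clash-free conformation for %s (%s-terminal extension): min %d clash(es)",
      label, direction, best_clash))
  }
  # keep residues in chain order
  arrange_structure(best, chain_id)
}

arrange_structure <- function(structure, chain_id) {
  new_structure(arrange(structure, .data$chain != .data$chain[1],
                        .data$chain, .data$res_seq),
                source_id = attr(structure, "source_id") %||% "")
}

build_terminal_residue <- function(N0, CA0, C0, aa, direction, phi, psi) {
  if (direction == "C") {
    N <- place_atom(N0, CA0, C0, BB_C_N, ANG_CA_C_N, psi)
    CA <- place_atom(CA0, C0, N, BB_N_CA, ANG_C_N_CA, 180)
    C <- place_atom(C0, N, CA, BB_CA_C, ANG_N_CA_C, phi)
    O <- place_atom(N, CA, C, BB_C_O, ANG_CA_C_O, psi + 180)
  } else {
    C <- place_atom(C0, CA0, N0, BB_C_N, ANG_C_N_CA, phi)
    CA <- place_atom(CA0, N0, C, BB_CA_C, ANG_CA_C_N, 180)
    N <- place_atom(N0, C, CA, BB_N_CA, ANG_N_CA_C, psi)
    O <- place_atom(N0, CA, C, BB_C_O, ANG_CA_C_O, 180)
  }
  bb <- tibble(
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = c(N[1], CA[1], C[1], O[1]),
    y = c(N[2], CA[2], C[2], O[2]),
    z = c(N[3], CA[3], C[3], O[3])
  )
  side <- build_side_chain(list(N = N, CA = CA, C = C), aa_one_to_three(aa))
  bind_rows(bb, side)
}

#' Generate a random peptide library
#'
#' Sequences are drawn i.i.d. uniformly over the 20 standard amino
#' acids at each position, reproducibly for a fixed seed.
#'
#' @param n number of peptides (480 by default).
#' @param length peptide length (8).
#' @param seed integer RNG seed.
#' @param library_id label stored with the library.
#' @return tibble of class `subsites_library` with column `sequence`;
#'   attributes `seed` and `library_id`.
#' @export
generate_library <- function(n = 480, length = 8, seed = 1,
                             library_id = "L1") {
  if (n < 1) abort("library size must be at least 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(AA1, length, replace = TRUE), collapse = "")
  }, character(1))
  out <- tibble(sequence = seqs)
  attr(out, "seed") <- seed
  attr(out, "library_id") <- library_id
  class(out) <- c("subsites_library", class(out))
  out
}

#' Read/write peptide libraries as plain text
#'
#' One 8-mer per line; a `# seed:` header line records the seed.
#'
#' @param library a [generate_library()] tibble.
#' @param file path.
#' @return `write_library` the path invisibly; `read_library` the
#'   library tibble.
#' @export
write_library <- function(library, file) {
  writeLines(c(paste0("# seed: ", attr(library, "seed") %||% NA),
               library$sequence), file)
  invisible(file)
}

#' @rdname write_library
#' @export
read_library <- function(file) {
  lines <- readLines(file)
  seed_line <- grep("^# seed:", lines, value = TRUE)
  seed <- if (length(seed_line) > 0)
    suppressWarnings(as.integer(sub("^# seed:\\s*", "", seed_line[1])))
  else NA_integer_
  seqs <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- tibble(sequence = seqs)
  attr(out, "seed") <- seed
  class(out) <- c("subsites_library", class(out))
  out
}

# Side-chain relaxation hook: greedy per-torsion grid scan (30-degree
# steps, chi1 outward) minimising the clash count, with the residue's
# non-bonded energy against the rest of the structure as tie-break.
# Deterministic; the current conformation wins exact ties.
relax_sidechain <- function(structure, chain_id, res_seq,
                            model = energy_model(), grid_step = 30) {
  res_tbl <- structure[structure$chain == chain_id &
                         structure$res_seq == res_seq, ]
  res_name <- res_tbl$res_name[1]
  defs <- CHI_ATOMS[[res_name]]
  if (is.null(defs) || res_name == "PRO") return(structure)
  idx0 <- which(structure$chain == chain_id & structure$res_seq == res_seq &
                  !(structure$atom %in% BACKBONE_ATOMS))
  if (length(idx0) == 0) return(structure)
  score <- function(s) {
    cl <- clash_count(s, idx0)
    e <- energy_between(s, idx0, setdiff(seq_len(nrow(s)), idx0), model)
    c(cl, e)
  }
  cur <- structure
  cur_score <- score(cur)
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  for (k in seq_along(defs)) {
    chi_now <- measure_chi(cur[cur$chain == chain_id &
                                 cur$res_seq == res_seq, ], res_name)
    key <- paste0("chi", k)
    if (!key %in% names(chi_now)) next
    for (target in grid) {
      cand <- rotate_chi(cur, chain_id, res_seq, k,
                         target - chi_now[[key]])
      cand_score <- score(cand)
      if (cand_score[1] < cur_score[1] ||
          (cand_score[1] == cur_score[1] && cand_score[2] < cur_score[2])) {
        cur <- cand
        cur_score <- cand_score
      }
    }
    if (cur_score[1] > 0 && k == length(defs)) break
  }
  cur
}

#' Thread a peptide library onto a template complex
#'
#' Models one complex per library sequence by iterative single
#' substitutions at P4 through P4' (N- to C-terminal), invoking the
#' side-chain relaxation hook after each mutation.
#'
#' @param structure template complex whose peptide chain carries exactly
#'   8 residues.
#' @param peptide_chain peptide chain id.
#' @param library a [generate_library()] tibble (or any tibble with a
#'   `sequence` column of 8-mers).
#' @param relax logical; run the relaxation hook after each mutation.
#' @return named list of structures, one per sequence, in library order.
#' @export
thread_library <- function(structure, peptide_chain, library,
                           relax = TRUE) {
  pep_res <- residue_table(filter(structure, .data$chain == peptide_chain))
  if (nrow(pep_res) != 8) {
    abort("template peptide must span the 8 positions P4-P4'")
  }
  out <- purrr::map(library$sequence, function(seq) {
    letters8 <- strsplit(toupper(seq), "")[[1]]
    cur <- structure
    for (i in seq_len(8)) {
      before <- cur$res_name[cur$chain == peptide_chain &
                               cur$res_seq == pep_res$res_seq[i]][1]
      cur <- mutate_residue(cur, peptide_chain, pep_res$res_seq[i],
                            letters8[i])
      if (relax && before != aa_one_to_three(letters8[i])) {
        cur <- relax_sidechain(cur, peptide_chain, pep_res$res_seq[i])
      }
    }
    cur
  })
  names(out) <- library$sequence
  out
}
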