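# Annotation workflow: peptide-like ligand detection, catalytic-site
# occupancy by accessibility change, pocket assignment from a reference
# complex, projection of the reference annotation onto other structures,
# gap closing, capping-group removal, the minimum-coverage filter and
# catalytic-residue inference by homology.

#' The eight pocket labels, N- to C-terminal
#' @export
POCKET_LABELS <- c("S4", "S3", "S2", "S1", "S1'", "S2'", "S3'", "S4'")

#' The eight substrate position labels, N- to C-terminal
#' @export
P_LABELS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

pocket_index <- function(pocket) match(pocket, POCKET_LABELS)

new_pocket_assignment <- function(peptide_map, pocket_residues,
                                  peptide_chain) {
  s1 <- "S1" %in% peptide_map$pocket
  s1p <- "S1'" %in% peptide_map$pocket
  out <- list(
    peptide_map = peptide_map,
    pocket_residues = pocket_residues,
    peptide_chain = peptide_chain,
    cleavage_site_present = s1 && s1p
  )
  class(out) <- "subsites_pockets"
  out
}

#' @export
print.subsites_pockets <- function(x, ...) {
  cat("Pocket assignment (peptide chain ", x$peptide_chain, "):\n", sep = "")
  lab <- ifelse(is.na(x$peptide_map$pocket), "-", x$peptide_map$pocket)
  cat(" ", paste(aa_three_to_one(x$peptide_map$res_name), lab,
                 sep = ":", collapse = " "), "\n")
  cat(sprintf("  %d pocket residues, cleavage site %s\n",
              nrow(x$pocket_residues),
              if (x$cleavage_site_present) "present" else "absent"))
  invisible(x)
}

#' Detect peptide-like ligand chains
#'
#' Candidate substrate chains: length within `[min_len, max_len]`
#' residues (waters ignored), at least one residue whose name is in
#' `peptide_like_names`, and not composed exclusively of unknown (UNK)
#' residues.
#'
#' @param structure atom tibble.
#' @param peptide_like_names residue names accepted as peptide-like; the
#'   default is the 20 standard residues plus a small extendable hetero
#'   list standing in for the peptide-like class of the Chemical
#'   Component Dictionary.
#' @param min_len,max_len inclusive residue-count bounds (3 and 12).
#' @return tibble with one row per candidate: chain, length, sequence,
#'   n_peptide_like.
#' @export
detect_peptide_ligands <- function(structure,
                                   peptide_like_names = c(AA3, "NLE", "ACE",
                                                          "ORN", "ABA", "DAL"),
                                   min_len = 3, max_len = 12) {
  res <- residue_table(filter(structure, !is_water(.data$res_name)))
  out <- res |>
    group_by(.data$chain) |>
    summarise(
      length = n(),
      n_peptide_like = sum(.data$res_name %in% peptide_like_names),
      all_unk = all(.data$res_name == "UNK"),
      sequence = paste(aa_three_to_one(.data$res_name), collapse = ""),
      .groups = "drop"
    ) |>
    filter(.data$length >= min_len, .data$length <= max_len,
           .data$n_peptide_like >= 1, !.data$all_unk) |>
    select(-"all_unk")
  out
}

#' Catalytic-site occupancy by accessibility change
#'
#' Computes the accessible surface area of the annotated catalytic
#' residues with and without the candidate ligand chain.  The ligand is
#' deemed to occupy the catalytic site when the summed accessibility
#' increase upon ligand removal is strictly greater than
#' `threshold` (0 square Angstrom).
#'
#' @param structure atom tibble (complex).
#' @param catalytic tibble with columns `chain`, `res_seq` (and
#'   optionally `role`) naming the catalytic residues.
#' @param ligand_chain chain id of the candidate substrate.
#' @param threshold accessibility-change threshold, Angstrom^2.
#' @param n_sphere_points quadrature points for the area engine.
#' @return logical flag, with the summed accessibility change attached
#'   as attribute `delta_asa`.
#' @export
catalytic_site_occupancy <- function(structure, catalytic, ligand_chain,
                                     threshold = 0, n_sphere_points = 480) {
  if (is.null(catalytic) || nrow(catalytic) == 0) {
    abort("structure lacks annotated catalytic residues and cannot be analysed")
  }
  body <- filter(structure, !is_water(.data$res_name))
  key <- paste(body$chain, body$res_seq)
  cat_key <- paste(catalytic$chain, catalytic$res_seq)
  if (!all(cat_key %in% key)) {
    abort(paste0("catalytic residues not present in structure: ",
                 paste(setdiff(cat_key, key), collapse = "; ")))
  }
  idx_with <- which(key %in% cat_key)
  asa_with <- shrake_rupley_asa(body, n_sphere_points = n_sphere_points,
                                subset = idx_with)
  stripped <- filter(body, .data$chain != ligand_chain)
  key2 <- paste(stripped$chain, stripped$res_seq)
  idx_wo <- which(key2 %in% cat_key)
  asa_without <- shrake_rupley_asa(stripped,
                                   n_sphere_points = n_sphere_points,
                                   subset = idx_wo)
  delta <- sum(asa_without$residue_asa$asa) - sum(asa_with$residue_asa$asa)
  out <- delta > threshold
  attr(out, "delta_asa") <- delta
  out
}

#' Assign protease residues to pockets from a reference peptide
#'
#' For each reference peptide residue, every protease residue with at
#' least one atom within `cutoff` of at least one atom of that peptide
#' residue joins the corresponding pocket.  A protease residue may
#' belong to several pockets.  Waters are excluded.
#'
#' @param structure atom tibble containing the reference complex.
#' @param peptide_chain peptide chain id.
#' @param ref_positions tibble with columns `res_seq` and `pocket`
#'   giving the pocket label of each peptide residue, in chain order.
#' @param cutoff distance cutoff in Angstrom (4.5).
#' @return a `subsites_pockets` assignment.
#' @export
assign_pockets_from_reference <- function(structure, peptide_chain,
                                          ref_positions, cutoff = 4.5) {
  if (cutoff <= 0) abort("cutoff must be positive")
  body <- filter(structure, !is_water(.data$res_name))
  pep <- filter(body, .data$chain == peptide_chain)
  prot <- filter(body, .data$chain != peptide_chain)
  missing_res <- setdiff(ref_positions$res_seq, unique(pep$res_seq))
  if (length(missing_res) > 0) {
    abort(paste0("reference peptide residues missing from chain ",
                 peptide_chain, ": ", paste(missing_res, collapse = ", ")))
  }
  prot_xyz <- atom_coords(prot)
  prot_res <- residue_table(prot)
  pockets <- purrr::pmap(ref_positions, function(res_seq, pocket, ...) {
    pxyz <- atom_coords(filter(pep, .data$res_seq == !!res_seq))
    d <- cross_dist(prot_xyz, pxyz)
    close_atom <- apply(d, 1, min) <= cutoff
    hit <- distinct(prot[close_atom, ],
                    .data$chain, .data$res_seq, .data$ins, .data$res_name)
    if (nrow(hit) == 0) return(NULL)
    hit$pocket <- pocket
    hit
  })
  pocket_residues <- bind_rows(pockets)
  pep_res <- residue_table(pep) |>
    left_join(select(ref_positions, "res_seq", "pocket"), by = "res_seq")
  new_pocket_assignment(pep_res, pocket_residues, peptide_chain)
}

# Longest protease chain id (most residues), used for sequence-guided
# superposition.
main_protease_chain <- function(structure, peptide_chain) {
  res <- residue_table(filter(structure, !is_water(.data$res_name),
                              .data$chain != peptide_chain))
  counts <- res |> group_by(.data$chain) |> summarise(n = n(), .groups = "drop")
  counts$chain[which.max(counts$n)]
}

#' Project a reference pocket annotation onto another complex
#'
#' Superposes the target complex onto the reference (sequence-guided:
#' protease sequences are aligned and matched CA atoms superposed by
#' least squares), then assigns each target peptide residue the pocket
#' of the reference peptide residue around which most of its atoms lie
#' within `proj_cutoff`.  Ties go to the N-terminal-most reference
#' residue; residues with no atom within the cutoff stay unassigned.
#'
#' @param ref_structure,ref_assignment the annotated reference complex.
#' @param target_structure atom tibble of the complex to annotate.
#' @param target_peptide_chain peptide chain id in the target.
#' @param proj_cutoff projection cutoff in Angstrom (2.0).
#' @param identity_floor minimum protease sequence identity for the
#'   superposition to be trusted.
#' @return a `subsites_pockets` assignment for the target complex.
#' @export
project_annotation <- function(ref_structure, ref_assignment,
                               target_structure, target_peptide_chain,
                               proj_cutoff = 2.0, identity_floor = 0.3) {
  ref_chain <- main_protease_chain(ref_structure,
                                   ref_assignment$peptide_chain)
  tgt_chain <- main_protease_chain(target_structure, target_peptide_chain)
  ref_seq <- chain_sequence(ref_structure, ref_chain)
  tgt_seq <- chain_sequence(target_structure, tgt_chain)
  aln <- align_sequences(ref_seq, tgt_seq)
  if (aln$identity_fraction < identity_floor) {
    abort(sprintf(
      "protease sequence identity %.2f below the configured floor %.2f",
      aln$identity_fraction, identity_floor))
  }
  map <- alignment_index_map(aln)
  ref_ca <- filter(ref_structure, .data$chain == ref_chain,
                   .data$atom == "CA")
  tgt_ca <- filter(target_structure, .data$chain == tgt_chain,
                   .data$atom == "CA")
  sp <- superpose(atom_coords(ref_ca)[map[, "query"], , drop = FALSE],
                  atom_coords(tgt_ca)[map[, "target"], , drop = FALSE])
  moved <- apply_superposition(target_structure, sp)

  ref_pep <- filter(ref_structure,
                    .data$chain == ref_assignment$peptide_chain)
  tgt_pep <- filter(moved, .data$chain == target_peptide_chain,
                    !is_water(.data$res_name))
  ref_map <- ref_assignment$peptide_map
  tgt_res <- residue_table(tgt_pep)
  tgt_res$pocket <- purrr::pmap_chr(
    tgt_res[, c("res_seq", "ins")],
    function(res_seq, ins) {
      txyz <- atom_coords(filter(tgt_pep, .data$res_seq == !!res_seq,
                                 .data$ins == !!ins))
      counts <- vapply(seq_len(nrow(ref_map)), function(r) {
        rxyz <- atom_coords(filter(ref_pep,
                                   .data$res_seq == ref_map$res_seq[r]))
        sum(apply(cross_dist(txyz, rxyz), 1, min) <= proj_cutoff)
      }, numeric(1))
      if (max(counts) == 0) return(NA_character_)
      ref_map$pocket[which.max(counts)]  # which.max: N-terminal-most tie-break
    }
  )
  # Pocket residues for the target follow from its own geometry.
  assign_pockets_from_reference(
    target_structure, target_peptide_chain,
    filter(tgt_res, !is.na(.data$pocket))[, c("res_seq", "pocket")]
  ) -> base
  new_pocket_assignment(tgt_res, base$pocket_residues, target_peptide_chain)
}

#' Close label gaps in a pocket assignment
#'
#' When the projected labels of a contiguous peptide break into two runs
#' whose labels are not mutually consecutive, the shorter run is
#' re-labelled to continue the longer run (the longer run is taken to
#' have been properly assigned; ties keep the N-terminal run fixed).
#'
#' @param assignment a `subsites_pockets`.
#' @return the corrected assignment.
#' @export
close_annotation_gaps <- function(assignment) {
  pm <- assignment$peptide_map
  idx <- pocket_index(pm$pocket)
  pos <- seq_len(nrow(pm))
  assigned <- which(!is.na(idx))
  if (length(assigned) < 2) return(assignment)
  offset <- idx[assigned] - pos[assigned]
  # runs of constant offset over consecutively assigned residues
  brk <- c(TRUE, diff(offset) != 0)
  run_id <- cumsum(brk)
  runs <- split(assigned, run_id)
  while (length(runs) > 1) {
    r1 <- runs[[1]]
    r2 <- runs[[2]]
    keep_first <- length(r1) >= length(r2)
    keeper <- if (keep_first) r1 else r2
    mover <- if (keep_first) r2 else r1
    off <- idx[keeper[1]] - keeper[1]
    idx[mover] <- mover + off
    runs[[2]] <- c(r1, r2)
    runs <- runs[-1]
  }
  idx[idx < 1 | idx > 8] <- NA
  pm$pocket <- POCKET_LABELS[idx]
  new_pocket_assignment(pm, assignment$pocket_residues,
                        assignment$peptide_chain)
}

#' Remove capping groups from a peptide chain
#'
#' Drops residues whose names are in `cap_names` (acetyl and
#' diazomethane-type caps by default) from the given chain.
#'
#' @param structure atom tibble.
#' @param chain_id peptide chain to strip.
#' @param cap_names residue names treated as caps.
#' @return the structure without the capping residues.
#' @export
strip_capping_groups <- function(structure, chain_id,
                                 cap_names = c("ACE", "NME", "NH2",
                                               "DAM", "0QE", "CH2")) {
  filter(structure,
         !(.data$chain == chain_id & .data$res_name %in% cap_names))
}

#' Keep-or-discard decision for an assignment
#'
#' Substrates with fewer than `min_residues` residues assigned to
#' binding pockets are discarded.
#'
#' @param assignment a `subsites_pockets`.
#' @param min_residues minimum number of assigned peptide residues (3).
#' @return list with `keep` (logical), `n_assigned` and `reason`.
#' @export
filter_assignment <- function(assignment, min_residues = 3) {
  n <- sum(!is.na(assignment$peptide_map$pocket))
  keep <- n >= min_residues
  list(
    keep = keep,
    n_assigned = n,
    reason = if (keep) "" else
      sprintf("only %d residue(s) in the binding pockets (minimum %d)",
              n, min_residues)
  )
}

#' Infer catalytic residues by homology
#'
#' Aligns the query sequence against an ordered library of annotated
#' sequences; the first alignment with identity above `identity_floor`
#' transfers the catalytic positions through the alignment columns.
#' Catalytic positions aligned to a query gap are dropped with a
#' warning.
#'
#' @param query_seq query amino-acid string.
#' @param library list of entries, each a list with `sequence` (string)
#'   and `catalytic` (tibble with `pos`, 1-based position in the
#'   sequence, and `role`).
#' @param identity_floor identity fraction that must be exceeded (0.5).
#' @return tibble with `pos` (query positions) and `role`, or `NULL`
#'   when no library entry passes (not annotatable).
#' @export
infer_catalytic_by_homology <- function(query_seq, library,
                                        identity_floor = 0.5) {
  if (length(library) == 0) abort("annotated library is empty")
  for (entry in library) {
    aln <- align_sequences(query_seq, entry$sequence)
    if (aln$identity_fraction <= identity_floor) next
    map <- alignment_index_map(aln)
    hits <- match(entry$catalytic$pos, map[, "target"])
    if (anyNA(hits)) {
      warn(paste0("catalytic position(s) aligned to a query gap dropped: ",
                  paste(entry$catalytic$pos[is.na(hits)], collapse = ", ")))
    }
    keep <- !is.na(hits)
    if (!any(keep)) next
    return(tibble(pos = map[hits[keep], "query"],
                  role = entry$catalytic$role[keep]))
  }
  NULL
}

#' Read a catalytic-residue annotation table
#'
#' Expects delimited text with columns `pdb_id`, `chain`, `res_seq`,
#' `role` (tab- or comma-separated, header required).
#'
#' @param file path.
#' @return tibble of the entries.
#' @export
read_catalytic_annotation <- function(file) {
  tab <- readr::read_delim(file, delim = guess_delim(file),
                           show_col_types = FALSE, trim_ws = TRUE)
  needed <- c("pdb_id", "chain", "res_seq", "role")
  if (!all(needed %in% names(tab))) {
    abort(paste0("catalytic annotation must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  tab$res_seq <- as.integer(tab$res_seq)
  tab
}

guess_delim <- function(file) {
  first <- readLines(file, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a pocket assignment as delimited text
#'
#' One row per structure, mirroring the annotation table layout: PDB id,
#' peptide amino acids, pocket positions, PDB residue numbers, chain id
#' and family id.
#'
#' @param assignment a `subsites_pockets`.
#' @param file path; when `NULL` the row is returned instead.
#' @param pdb_id,family_id identifier strings stored with the row.
#' @return the tibble row, invisibly when written.
#' @export
write_assignment <- function(assignment, file = NULL, pdb_id = "",
                             family_id = "") {
  pm <- filter(assignment$peptide_map, !is.na(.data$pocket))
  row <- tibble(
    pdb_id = pdb_id,
    peptide_aa = paste(aa_three_to_one(pm$res_name), collapse = ""),
    pockets = paste(pm$pocket, collapse = "-"),
    res_numbers = paste(pm$res_seq, collapse = "-"),
    chain_id = assignment$peptide_chain,
    family_id = family_id
  )
  if (!is.null(file)) {
    readr::write_tsv(row, file)
    return(invisible(row))
  }
  row
}
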