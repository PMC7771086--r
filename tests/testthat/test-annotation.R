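fx <- make_toy_complex()

test_that("peptide-like ligand detection applies the length and UNK filters", {
  lig <- detect_peptide_ligands(fx$structure)
  expect_equal(nrow(lig), 1)
  expect_equal(lig$chain, "P")
  expect_equal(lig$length, 8)

  # a 2-residue chain is below the minimum length
  short <- make_toy_complex(fixture_spec(peptide_length = 2))
  expect_false("P" %in% detect_peptide_ligands(short$structure)$chain)

  # a chain made exclusively of unknown residues is excluded
  unk <- build_peptide(strrep("A", 5), chain_id = "Z")
  unk$res_name <- "UNK"
  s <- subsites:::new_structure(dplyr::bind_rows(fx$structure, unk))
  expect_false("Z" %in% detect_peptide_ligands(s)$chain)
})

test_that("catalytic-site occupancy flips with ligand distance and is monotone", {
  occ <- catalytic_site_occupancy(fx$structure, fx$catalytic, "P")
  expect_true(occ)
  expect_gt(attr(occ, "delta_asa"), 0)

  far <- shift_chain(fx$structure, "P", dx = 50)
  occ_far <- catalytic_site_occupancy(far, fx$catalytic, "P")
  expect_false(occ_far)
  expect_equal(attr(occ_far, "delta_asa"), 0, tolerance = 1e-9)

  # monotone: moving away never turns occupancy back on
  flags <- vapply(c(0, 8, 20, 50), function(d) {
    as.logical(catalytic_site_occupancy(shift_chain(fx$structure, "P",
                                                    dx = d),
                                        fx$catalytic, "P"))
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))

  expect_error(
    catalytic_site_occupancy(fx$structure, fx$catalytic[0, ], "P"),
    "catalytic"
  )
})

test_that("pocket membership respects the 4.5 Angstrom cutoff", {
  # one peptide residue at the origin, one protease residue at a
  # controlled minimum distance
  pep <- build_peptide("A", chain_id = "P")
  prot <- build_peptide("G", chain_id = "E")
  gap <- function(d) {
    # translate so the minimum cross distance is exactly d
    p2 <- shift_chain(prot, "E", dy = 30)
    m <- min(subsites:::cross_dist(atom_coords(pep), atom_coords(p2)))
    shift_chain(prot, "E", dy = 30 - (m - d))
  }
  ref <- tibble::tibble(res_seq = 1L, pocket = "S1")
  near <- subsites:::new_structure(dplyr::bind_rows(pep, gap(4.4)))
  asg <- assign_pockets_from_reference(near, "P", ref)
  expect_equal(asg$pocket_residues$pocket, "S1")
  far <- subsites:::new_structure(dplyr::bind_rows(pep, gap(4.6)))
  expect_equal(nrow(assign_pockets_from_reference(far, "P",
                                                  ref)$pocket_residues), 0)
})

test_that("a protease residue can belong to several pockets", {
  asg <- assign_pockets_from_reference(fx$structure, "P", fx$ref_positions)
  multi <- asg$pocket_residues |>
    dplyr::count(chain, res_seq) |>
    dplyr::filter(n > 1)
  expect_gt(nrow(multi), 0)
})

test_that("fixture assignment recovers the construction ground truth", {
  asg <- assign_pockets_from_reference(fx$structure, "P", fx$ref_positions)
  expect_equal(pocket_membership(asg), pocket_membership(fx$truth))
  expect_true(asg$cleavage_site_present)
  expect_equal(asg$peptide_map$pocket, POCKET_LABELS)
})

test_that("pocket assignment is invariant under global rigid transforms", {
  set.seed(99)
  base <- pocket_membership(
    assign_pockets_from_reference(fx$structure, "P", fx$ref_positions))
  for (k in 1:3) {
    tf <- random_rigid_transform()
    moved <- apply_rigid(fx$structure, tf)
    asg <- assign_pockets_from_reference(moved, "P", fx$ref_positions)
    expect_equal(pocket_membership(asg), base)
  }
})

test_that("projection onto an identical complex reproduces the annotation", {
  ref_asg <- assign_pockets_from_reference(fx$structure, "P",
                                           fx$ref_positions)
  proj <- project_annotation(fx$structure, ref_asg, fx$structure, "P")
  expect_equal(proj$peptide_map$pocket, ref_asg$peptide_map$pocket)
})

test_that("a one-position backbone shift moves the projected labels by one", {
  # poly-alanine peptide so every residue carries the same atom set
  fa <- make_toy_complex(fixture_spec(peptide_sequence = "AAAAAAAA"))
  ref_asg <- assign_pockets_from_reference(fa$structure, "P",
                                           fa$ref_positions)
  ca <- dplyr::filter(fa$structure, chain == "P", atom == "CA")
  rise <- (ca$x[8] - ca$x[1]) / 7
  target <- shift_chain(fa$structure, "P", dx = rise)
  proj <- project_annotation(fa$structure, ref_asg, target, "P")
  # residue i now sits where residue i+1 sat: labels shift C-terminally
  expect_equal(proj$peptide_map$pocket[1:7], POCKET_LABELS[2:8])
})

test_that("projection ties go to the N-terminal-most reference residue", {
  # reference: 3-residue peptide, pockets S2-S1-S1'
  ref <- build_peptide("AAA", chain_id = "P")
  prot <- shift_chain(build_peptide("GGGGG", chain_id = "E"), "E", dy = 4.8)
  ref_cx <- subsites:::new_structure(dplyr::bind_rows(ref, prot))
  ref_asg <- assign_pockets_from_reference(
    ref_cx, "P", tibble::tibble(res_seq = 1:3,
                                pocket = c("S2", "S1", "S1'")))
  # target peptide residue: two atoms on residue 1, two on residue 2
  r1 <- dplyr::filter(ref, res_seq == 1, atom %in% c("N", "CA"))
  r2 <- dplyr::filter(ref, res_seq == 2, atom %in% c("N", "CA"))
  tgt_res <- dplyr::bind_rows(r1, r2)
  tgt_res$chain <- "Q"
  tgt_res$res_seq <- 1L
  tgt_res$atom <- c("N", "CA", "C", "O")
  tgt_cx <- subsites:::new_structure(dplyr::bind_rows(tgt_res, prot))
  proj <- project_annotation(ref_cx, ref_asg, tgt_cx, "Q")
  expect_equal(proj$peptide_map$pocket, "S2")
})

test_that("gap closing relabels the shorter run to join the longer one", {
  mk <- function(pockets) {
    pm <- tibble::tibble(chain = "P", res_seq = seq_along(pockets),
                         ins = "", res_name = "ALA", pocket = pockets)
    subsites:::new_pocket_assignment(pm, fx$truth$pocket_residues, "P")
  }
  # S4 | S2 S1: single N-terminal residue joins the longer C-run as S3
  out <- close_annotation_gaps(mk(c("S4", "S2", "S1")))
  expect_equal(out$peptide_map$pocket, c("S3", "S2", "S1"))
  # gap-free assignments are unchanged
  out2 <- close_annotation_gaps(mk(c("S3", "S2", "S1")))
  expect_equal(out2$peptide_map$pocket, c("S3", "S2", "S1"))
  # equal run lengths: the N-terminal run stays fixed
  out3 <- close_annotation_gaps(mk(c("S4", "S2")))
  expect_equal(out3$peptide_map$pocket, c("S4", "S3"))
  # labels end up consecutive along the chain
  out4 <- close_annotation_gaps(mk(c("S4", NA, "S2", "S1", "S1'")))
  idx <- subsites:::pocket_index(out4$peptide_map$pocket)
  expect_true(all(diff(idx[!is.na(idx)]) ==
                    diff(which(!is.na(idx)))))
})

test_that("capping groups are stripped and stripping is idempotent", {
  pep <- build_peptide("AAAAA", chain_id = "P", start_res = 2L)
  cap <- tibble::tibble(
    chain = "P", res_seq = 1L, ins = "", res_name = "ACE",
    atom = c("C", "O", "CH3"), element = c("C", "O", "C"),
    x = -2, y = 0, z = c(0, 1, 2), occ = 1, het = TRUE
  )
  s <- subsites:::new_structure(dplyr::bind_rows(cap, pep))
  stripped <- strip_capping_groups(s, "P")
  expect_false("ACE" %in% stripped$res_name)
  expect_equal(nrow(dplyr::distinct(stripped, res_seq)), 5)
  expect_equal(strip_capping_groups(stripped, "P"), stripped)
  # uncapped peptides are unchanged
  expect_equal(strip_capping_groups(pep, "P"), pep)
})

test_that("assignments with fewer than three pocket residues are discarded", {
  mk <- function(pockets) {
    pm <- tibble::tibble(chain = "P", res_seq = seq_along(pockets),
                         ins = "", res_name = "ALA", pocket = pockets)
    subsites:::new_pocket_assignment(pm, fx$truth$pocket_residues, "P")
  }
  expect_false(filter_assignment(mk(c("S2", "S1", NA)))$keep)
  expect_true(filter_assignment(mk(c("S3", "S2", "S1")))$keep)
  expect_true(filter_assignment(mk(POCKET_LABELS))$keep)
  expect_match(filter_assignment(mk(c("S1", NA)))$reason, "minimum")
})

test_that("catalytic inference transfers through the first passing alignment", {
  seq1 <- "ACDEFGHIKLMNPQRSTVWY"
  lib <- list(
    list(sequence = seq1,
         catalytic = tibble::tibble(pos = c(5L, 9L), role = c("n", "b")))
  )
  # identical query: transferred verbatim
  hit <- infer_catalytic_by_homology(seq1, lib)
  expect_equal(hit$pos, c(5L, 9L))
  expect_equal(hit$role, c("n", "b"))

  # low identity: not annotatable
  expect_null(infer_catalytic_by_homology(strrep("A", 20), lib))

  # catalytic position aligned to a query gap is dropped with a warning
  query <- paste0(substr(seq1, 1, 4), substr(seq1, 6, 20))  # position 5 deleted
  expect_warning(hit2 <- infer_catalytic_by_homology(query, lib),
                 "gap")
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$role, "b")

  # first passing library entry wins
  lib2 <- list(
    list(sequence = seq1,
         catalytic = tibble::tibble(pos = 1L, role = "first")),
    list(sequence = seq1,
         catalytic = tibble::tibble(pos = 2L, role = "second"))
  )
  expect_equal(infer_catalytic_by_homology(seq1, lib2)$role, "first")
  expect_error(infer_catalytic_by_homology(seq1, list()), "empty")
})
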