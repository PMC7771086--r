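test_that("fingerprint similarity is 1 for identical molecules and ranks analogues", {
  leu <- residue_graph("LEU")
  expect_equal(tanimoto(circular_fingerprint(leu),
                        circular_fingerprint(leu)), 1)
  # two glycines (empty side chains) count as identical
  expect_equal(tanimoto(character(0), character(0)), 1)

  # norleucine is closer to leucine than to alanine, and an independent
  # walk-signature oracle agrees on the ordering
  nle <- residue_graph("NLE")
  sim_l <- tanimoto(circular_fingerprint(nle),
                    circular_fingerprint(residue_graph("LEU")))
  sim_a <- tanimoto(circular_fingerprint(nle),
                    circular_fingerprint(residue_graph("ALA")))
  expect_gt(sim_l, sim_a)
  expect_gt(walk_similarity(nle, residue_graph("LEU")),
            walk_similarity(nle, residue_graph("ALA")))
})

test_that("NNAA mapping picks the best candidate and signals unreplaceable", {
  nle <- residue_graph("NLE")
  m <- map_nnaa_to_natural(nle, c("L", "A"), floor = 0, nnaa_name = "NLE")
  expect_true(m$replaceable)
  expect_equal(m$candidate, "L")
  expect_true(all(m$all$similarity >= 0 & m$all$similarity <= 1))

  # candidate order must not matter
  m2 <- map_nnaa_to_natural(nle, c("A", "L"), floor = 0)
  expect_equal(m2$candidate, m$candidate)
  expect_equal(m2$similarity, m$similarity)

  # an aromatic query against tiny aliphatic candidates falls below the
  # floor
  trp <- residue_graph("TRP")
  m3 <- map_nnaa_to_natural(trp, c("G", "A"), floor = 0.4)
  expect_false(m3$replaceable)
  expect_true(is.na(m3$candidate))
  expect_error(map_nnaa_to_natural(nle, character(0)), "empty")
})

test_that("identity mutation leaves the structure untouched", {
  fx <- make_toy_complex()
  m <- mutate_residue(fx$structure, "P", 2, "A")
  expect_equal(atom_coords(m), atom_coords(fx$structure))
  expect_equal(m$atom, fx$structure$atom)
})

test_that("mutating to glycine leaves exactly the backbone atom set", {
  fx <- make_toy_complex()
  m <- mutate_residue(fx$structure, "P", 4, "G")
  res <- dplyr::filter(m, chain == "P", res_seq == 4)
  expect_setequal(res$atom, c("N", "CA", "C", "O"))
  expect_equal(res$res_name, rep("GLY", 4))
  # backbone coordinates unchanged to 1e-9
  bb_old <- dplyr::filter(fx$structure, chain == "P", res_seq == 4,
                          atom %in% c("N", "CA", "C", "O"))
  bb_new <- dplyr::filter(m, chain == "P", res_seq == 4,
                          atom %in% c("N", "CA", "C", "O"))
  expect_lt(max(abs(atom_coords(bb_old) - atom_coords(bb_new))), 1e-9)
})

test_that("mutation clash counts see a tight cavity", {
  # open solvent: an isolated dipeptide has room for tryptophan
  pep <- build_peptide("GG", chain_id = "P")
  open_m <- mutate_residue(pep, "P", 1, "W")
  expect_equal(attr(open_m, "clash_count"), 0)

  # tight cavity: a dense carbon box engulfing the side-chain region
  grid <- expand.grid(x = seq(-6, 8, by = 1.4), y = seq(-6, 6, by = 1.4),
                      z = seq(-6, 6, by = 1.4))
  ca <- subsites:::atom_xyz(dplyr::filter(pep, res_seq == 1), "CA")
  keep <- sqrt((grid$x - ca[1])^2 + (grid$y - ca[2])^2 +
                 (grid$z - ca[3])^2) > 2.5
  grid <- grid[keep, ]
  box <- tibble::tibble(
    chain = "X", res_seq = 1L, ins = "", res_name = "UNK",
    atom = paste0("C", seq_len(nrow(grid))), element = "C",
    x = grid$x, y = grid$y, z = grid$z, occ = 1, het = TRUE
  )
  cavity <- subsites:::new_structure(dplyr::bind_rows(pep, box))
  cav_m <- mutate_residue(cavity, "P", 1, "W")
  expect_gt(attr(cav_m, "clash_count"), 0)

  # missing backbone atoms are an error
  broken <- dplyr::filter(pep, !(res_seq == 2 & atom == "CA"))
  expect_error(mutate_residue(broken, "P", 2, "A"), "backbone")
})

test_that("reconstruction spans P4-P4' with ideal peptide bonds", {
  fx4 <- make_toy_complex(fixture_spec(peptide_length = 4))
  asg4 <- assign_pockets_from_reference(fx4$structure, "P",
                                        fx4$ref_positions)
  r8 <- reconstruct_missing(fx4$structure, asg4, "KATLSVNE")
  pep_res <- dplyr::distinct(dplyr::filter(r8, chain == "P"), res_seq)
  expect_equal(nrow(pep_res), 8)
  pmap <- attr(r8, "pocket_map")
  expect_equal(pmap$pocket, POCKET_LABELS)
  # every peptide bond within 1.33 +/- 0.02 Angstrom
  pep <- dplyr::filter(r8, chain == "P")
  rs <- sort(pep_res$res_seq)
  for (i in head(rs, -1)) {
    C <- subsites:::atom_xyz(pep[pep$res_seq == i, ], "C")
    N <- subsites:::atom_xyz(pep[pep$res_seq == i + 1, ], "N")
    expect_equal(sqrt(sum((C - N)^2)), 1.33, tolerance = 0.02 / 1.33)
  }
})

test_that("an already complete peptide is returned unchanged", {
  fx <- make_toy_complex()
  asg <- assign_pockets_from_reference(fx$structure, "P",
                                       fx$ref_positions)
  out <- reconstruct_missing(fx$structure, asg, "KATLSVNE")
  expect_equal(atom_coords(out), atom_coords(fx$structure))
})

test_that("inconsistent target sequences and short templates are rejected", {
  fx4 <- make_toy_complex(fixture_spec(peptide_length = 4))
  asg4 <- assign_pockets_from_reference(fx4$structure, "P",
                                        fx4$ref_positions)
  expect_error(reconstruct_missing(fx4$structure, asg4, "WWWWSVNE"),
               "inconsistent")
  expect_error(reconstruct_missing(fx4$structure, asg4, "KATLSVN"),
               "8 letters")
})

test_that("a blocked prime side makes reconstruction unmodellable", {
  fxb <- make_toy_complex(fixture_spec(peptide_length = 4,
                                       blocked_prime_side = TRUE))
  asgb <- assign_pockets_from_reference(fxb$structure, "P",
                                        fxb$ref_positions)
  expect_error(reconstruct_missing(fxb$structure, asgb, "KATLSVNE"),
               class = "subsites_unmodellable")
})

test_that("library generation is reproducible and shaped as requested", {
  l1 <- generate_library(480, seed = 7)
  l2 <- generate_library(480, seed = 7)
  expect_identical(l1$sequence, l2$sequence)
  expect_equal(nrow(l1), 480)
  expect_true(all(nchar(l1$sequence) == 8))
  expect_true(all(strsplit(paste(l1$sequence, collapse = ""), "")[[1]] %in%
                    subsites:::AA1))
  expect_error(generate_library(0), "at least 1")
  # round trip through the plain-text format
  f <- tempfile()
  write_library(l1, f)
  l3 <- read_library(f)
  expect_equal(l3$sequence, l1$sequence)
  expect_equal(attr(l3, "seed"), 7L)
})

test_that("large libraries are uniform per position (chi-square)", {
  lib <- generate_library(20000, seed = 3)
  letters_mat <- do.call(rbind, strsplit(lib$sequence, ""))
  pass <- vapply(1:8, function(j) {
    counts <- table(factor(letters_mat[, j], levels = subsites:::AA1))
    stats::chisq.test(counts)$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 7)
})

test_that("threading preserves the backbone and follows the library order", {
  fx <- make_toy_complex()
  template_seq <- "KATLSVNE"
  lib <- tibble::tibble(sequence = c(template_seq, "KATLSVNA"))
  out <- thread_library(fx$structure, "P", lib)
  expect_equal(names(out), lib$sequence)
  # identity sequence: unchanged complex
  expect_equal(atom_coords(out[[1]]), atom_coords(fx$structure))
  # single substitution: only the last residue's side chain differs
  changed <- out[[2]]
  for (i in 1:7) {
    a <- dplyr::filter(fx$structure, chain == "P", res_seq == i)
    b <- dplyr::filter(changed, chain == "P", res_seq == i)
    expect_equal(atom_coords(a), atom_coords(b), info = paste("res", i))
  }
  res8 <- dplyr::filter(changed, chain == "P", res_seq == 8)
  expect_equal(res8$res_name[1], "ALA")
  # backbone conservation across the whole peptide
  bb <- function(s) atom_coords(dplyr::filter(
    s, chain == "P", atom %in% c("N", "CA", "C", "O")))
  expect_lt(max(abs(bb(changed) - bb(fx$structure))), 1e-9)
})
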