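lone_atom <- function(element = "C") {
  subsites:::new_structure(tibble::tibble(
    chain = "A", res_seq = 1L, ins = "", res_name = "UNK",
    atom = "C1", element = element, x = 0, y = 0, z = 0,
    occ = 1, het = TRUE
  ))
}

test_that("a lone atom's area matches the analytic sphere", {
  asa <- shrake_rupley_asa(lone_atom())
  expect_equal(asa$atom_asa$asa, 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.015)
})

test_that("a fully enclosed atom has zero accessible area", {
  # surround the probe with a dense shell of overlapping atoms
  dirs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  shell <- t(apply(dirs, 1, function(d) 2.0 * d / sqrt(sum(d^2))))
  s <- subsites:::new_structure(tibble::tibble(
    chain = "A", res_seq = c(1L, rep(5L, nrow(shell))), ins = "",
    res_name = "UNK",
    atom = paste0("C", seq_len(nrow(shell) + 1)), element = "C",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    occ = 1, het = TRUE
  ))
  asa <- shrake_rupley_asa(s, subset = 1L)
  expect_equal(asa$atom_asa$asa, 0)
})

test_that("symmetric atoms get equal areas and unknown elements error", {
  s <- subsites:::new_structure(tibble::tibble(
    chain = "A", res_seq = c(1L, 5L), ins = "", res_name = "UNK",
    atom = c("C1", "C2"), element = "C", x = c(0, 3), y = 0, z = 0,
    occ = 1, het = TRUE
  ))
  asa <- shrake_rupley_asa(s)
  expect_equal(asa$atom_asa$asa[1], asa$atom_asa$asa[2], tolerance = 1e-9)

  bad <- lone_atom(element = "QQ")
  expect_error(shrake_rupley_asa(bad), "QQ")
})

test_that("area quadrature is converged at the default point count", {
  fx <- make_toy_complex(fixture_spec(peptide_length = 4))
  s <- fx$structure
  a1 <- shrake_rupley_asa(s)$residue_asa
  a2 <- shrake_rupley_asa(s, n_sphere_points = 2 * 3840)$residue_asa
  rel <- abs(a1$asa - a2$asa) / pmax(a2$asa, 1)
  expect_lt(max(rel), 0.01)
})

test_that("burial only reduces accessibility relative to isolated chains", {
  fx <- make_toy_complex(fixture_spec(peptide_length = 4))
  s <- fx$structure
  whole <- sum(shrake_rupley_asa(s)$residue_asa$asa)
  parts <- sum(vapply(unique(s$chain), function(ch) {
    sum(shrake_rupley_asa(dplyr::filter(s, chain == ch))$residue_asa$asa)
  }, numeric(1)))
  expect_lte(whole, parts)
})

test_that("relative accessibility normalises by the Gly-X-Gly maxima", {
  expect_equal(relative_asa(subsites:::MAX_ASA[["ALA"]], "ALA"), 1)
  expect_equal(relative_asa(0, "TRP"), 0)
  expect_error(relative_asa(50, "XYZ"), "reference")
  # the central residue of an extended Gly-Ala-Gly tripeptide is close
  # to its reference maximum
  gag <- build_peptide("GAG", chain_id = "P")
  asa <- shrake_rupley_asa(gag)
  ala <- dplyr::filter(asa$residue_asa, res_name == "ALA")
  expect_equal(relative_asa(ala$asa, "ALA"), 1, tolerance = 0.15)
})

# -- hydrogen bonds ---------------------------------------------------------

# Donor backbone N (with CA and preceding C defining the amide H) in
# chain P; acceptor carbonyl O in chain E, placed along the N-H axis.
hbond_geometry <- function(d_on, angle_offset = 0) {
  N <- c(0, 0, 0)
  CA <- c(1.45, 0, 0)
  Cprev <- c(-0.7, 1.2, 0)
  H <- N + 0.98 * subsites:::unit(subsites:::unit(N - CA) +
                                    subsites:::unit(N - Cprev))
  dir <- subsites:::rotate_points(matrix(H - N, 1), c(0, 0, 0),
                                  c(0, 0, 1), angle_offset)[1, ]
  O <- N + subsites:::unit(dir) * d_on
  C <- O + c(0, 0, 1.23)
  don <- tibble::tibble(
    chain = "P", res_seq = c(1L, 2L, 2L, 2L, 2L), ins = "",
    res_name = "ALA",
    atom = c("C", "N", "CA", "C", "O"), element = c("C", "N", "C", "C", "O"),
    x = c(Cprev[1], N[1], CA[1], 3, 3.5),
    y = c(Cprev[2], N[2], CA[2], 1, 2),
    z = 0, occ = 1, het = FALSE
  )
  acc <- tibble::tibble(
    chain = "E", res_seq = 9L, ins = "", res_name = "ALA",
    atom = c("O", "C"), element = c("O", "C"),
    x = c(O[1], C[1]), y = c(O[2], C[2]), z = c(O[3], C[3]),
    occ = 1, het = FALSE
  )
  subsites:::new_structure(dplyr::bind_rows(don, acc))
}

test_that("hydrogen bonds follow the distance and angle criteria", {
  # ideal N-H...O at 2.9 Angstrom, collinear -> one bond
  hb <- detect_hbonds(hbond_geometry(2.9), "P")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O")
  expect_equal(hb$part, "main")
  # beyond the donor-acceptor ceiling -> none
  expect_equal(nrow(detect_hbonds(hbond_geometry(5.0), "P")), 0)
  # acceptor rotated so the D-H-A angle collapses to ~60 degrees -> none
  expect_equal(nrow(detect_hbonds(hbond_geometry(2.9, 120), "P")), 0)
})

test_that("non-bonded contacts respect the cutoff and exclude H-bond pairs", {
  mk_pair <- function(d) {
    subsites:::new_structure(tibble::tibble(
      chain = c("P", "E"), res_seq = 1L, ins = "", res_name = "UNK",
      atom = c("C1", "C2"), element = "C", x = c(0, d), y = 0, z = 0,
      occ = 1, het = TRUE
    ))
  }
  expect_equal(nrow(detect_nonbonded(mk_pair(3.8), "P")), 1)
  expect_equal(nrow(detect_nonbonded(mk_pair(4.0), "P")), 0)
  # an H-bonded donor/acceptor pair is not double-counted
  s <- hbond_geometry(2.9)
  hb <- detect_hbonds(s, "P")
  nb <- detect_nonbonded(s, "P", hbonds = hb)
  keys <- paste(nb$donor_atom, nb$acceptor_atom)
  expect_false("N O" %in% keys)
})

# -- per-frame observables and averaging ------------------------------------

test_that("frame observables carry six observables for the 8 positions", {
  fx <- make_toy_complex()
  asg <- assign_pockets_from_reference(fx$structure, "P",
                                       fx$ref_positions)
  obs <- frame_observables(fx$structure, asg, "P")
  expect_equal(nrow(obs), 8)
  expect_setequal(as.character(obs$position), P_LABELS)
  expect_true(all(c("rel_asa", "hb_main", "hb_side", "nb_main",
                    "nb_side", "energy") %in% names(obs)))
  expect_true(all(obs$hb_main >= 0 & obs$nb_main >= 0))
  expect_true(all(obs$rel_asa >= 0 & obs$rel_asa < 1.3))
  # the engineered S1 cage buries P1 the most
  expect_equal(as.character(obs$position[which.min(obs$rel_asa)]), "P1")

  # a fully solvated peptide far from the protease: no contacts, high
  # accessibility
  far <- shift_chain(fx$structure, "P", dx = 200)
  obs_far <- frame_observables(far, asg, "P")
  expect_true(all(obs_far$hb_main == 0 & obs_far$hb_side == 0 &
                    obs_far$nb_main == 0 & obs_far$nb_side == 0))
  expect_true(all(obs_far$rel_asa > 0.3))
  expect_true(all(abs(obs_far$energy) < 1e-9))
})

test_that("averaging matches the summation oracle and is linear", {
  mk_record <- function(run, frame, vals) {
    tibble::tibble(
      position = factor(rep(P_LABELS, each = 1), levels = P_LABELS),
      aa = "A", rel_asa = vals, hb_main = 0L, hb_side = 0L,
      nb_main = 0L, nb_side = 0L, energy = 2 * vals,
      run = run, frame = frame
    )
  }
  rec <- dplyr::bind_rows(
    mk_record(1, 1, rep(0.4, 8)),
    mk_record(1, 2, rep(0.6, 8)),
    mk_record(2, 1, rep(0.8, 8))
  )
  avg <- average_observables(rec)
  cell <- dplyr::filter(avg$cell, observable == "rel_asa")
  expect_true(all(abs(cell$mean - mean(c(0.4, 0.6, 0.8))) < 1e-12))
  expect_true(all(cell$n_frames == 3))

  # single record: identity
  one <- average_observables(mk_record(1, 1, rep(0.5, 8)))
  expect_true(all(dplyr::filter(one$cell,
                                observable == "rel_asa")$mean == 0.5))

  # random tensor vs brute-force mean
  set.seed(17)
  recs <- dplyr::bind_rows(lapply(1:5, function(f) {
    mk_record(1, f, runif(8))
  }))
  avg2 <- average_observables(recs)
  for (p in P_LABELS) {
    manual <- mean(recs$rel_asa[recs$position == p])
    got <- dplyr::filter(avg2$cell, observable == "rel_asa",
                         position == p)$mean
    expect_equal(got, manual, tolerance = 1e-12)
  }

  # linearity: scaling the raw records scales the averages
  recs_scaled <- recs
  recs_scaled$rel_asa <- 3 * recs_scaled$rel_asa
  avg3 <- average_observables(recs_scaled)
  expect_equal(
    dplyr::filter(avg3$cell, observable == "rel_asa")$mean,
    3 * dplyr::filter(avg2$cell, observable == "rel_asa")$mean,
    tolerance = 1e-12
  )
  expect_error(average_observables(recs[0, ]), "no frames")
})
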