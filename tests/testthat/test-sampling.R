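# Two isolated carbon probes in separate, non-adjacent residues.
two_carbons <- function(r) {
  subsites:::new_structure(tibble::tibble(
    chain = c("A", "B"), res_seq = c(1L, 5L), ins = "",
    res_name = "UNK", atom = "C1", element = "C",
    x = c(0, r), y = 0, z = 0, occ = 1, het = TRUE
  ))
}

test_that("the Lennard-Jones term hits -epsilon at the minimum distance", {
  rmin <- 2 * subsites:::LJ_RMIN[["C"]]
  e <- total_energy(two_carbons(rmin))
  expect_equal(e, -subsites:::LJ_EPS[["C"]], tolerance = 1e-9)
  # far beyond the cutoff the interaction vanishes
  expect_equal(total_energy(two_carbons(50)), 0)
  # coincident atoms are an error
  expect_error(total_energy(two_carbons(0)), "zero distance")
})

test_that("total energy matches a brute-force pair-sum oracle", {
  fx <- make_toy_complex(fixture_spec(peptide_length = 3))
  s <- fx$structure
  expect_equal(total_energy(s), naive_energy(s), tolerance = 1e-8)
  # and with non-default weights
  m <- energy_model(w_lj = 0.5, w_coulomb = 2, w_hbond = 0, dielectric = 6)
  expect_equal(total_energy(s, m), naive_energy(s, m), tolerance = 1e-8)
})

test_that("interface energy decomposes exactly over peptide positions", {
  fx <- make_toy_complex()
  s <- fx$structure
  per_pos <- interface_energy_per_position(s, "P")
  pep <- which(s$chain == "P")
  prot <- which(s$chain != "P")
  total_interface <- subsites:::energy_between(s, pep, prot, energy_model())
  expect_equal(sum(per_pos$energy), total_interface, tolerance = 1e-6)

  # a far-away peptide has a vanishing interface at every position
  far <- shift_chain(s, "P", dx = 100)
  expect_true(all(abs(
    interface_energy_per_position(far, "P")$energy) < 1e-9))
})

test_that("a single-contact geometry concentrates the interface at P1", {
  # peptide along x, far from everything except one probe residue next
  # to the P1 side chain
  pep <- build_peptide("AAAAAAAA", chain_id = "P")
  p1 <- dplyr::filter(pep, res_seq == 4)
  cb <- subsites:::atom_xyz(p1, "CB")
  ca <- subsites:::atom_xyz(p1, "CA")
  tip <- cb + subsites:::unit(cb - ca) * 3.9
  probe <- subsites:::new_structure(tibble::tibble(
    chain = "E", res_seq = 1L, ins = "", res_name = "UNK",
    atom = "C1", element = "C", x = tip[1], y = tip[2],
    z = tip[3], occ = 1, het = TRUE
  ))
  s <- subsites:::new_structure(dplyr::bind_rows(pep, probe))
  e <- interface_energy_per_position(s, "P")
  expect_equal(which.max(abs(e$energy)), 4)
})

test_that("backrub rotations are rigid about the pivot axis", {
  fx <- make_toy_complex()
  s <- fx$structure
  # zero angle leaves coordinates untouched
  z <- backrub_rotate(s, "P", 2, 5, 0)
  expect_equal(atom_coords(z$structure), atom_coords(s))

  out <- backrub_rotate(s, "P", 2, 5, 7.5)
  moved <- out$structure
  ca <- function(st, i) subsites:::atom_xyz(
    st[st$chain == "P" & st$res_seq == i, ], "CA")
  # pivot CA atoms stay put
  expect_equal(ca(moved, 2), ca(s, 2), tolerance = 1e-9)
  expect_equal(ca(moved, 5), ca(s, 5), tolerance = 1e-9)
  # moved atoms match an explicit Rodrigues rotation oracle
  p1 <- ca(s, 2)
  axis <- ca(s, 5) - p1
  expected <- subsites:::rotate_points(
    atom_coords(s)[out$moved, , drop = FALSE], p1, axis, 7.5)
  expect_equal(unname(atom_coords(moved)[out$moved, , drop = FALSE]),
               unname(expected), tolerance = 1e-9)
  # all bond lengths on the chain are preserved
  bonds_of <- function(st) {
    pep <- dplyr::filter(st, chain == "P")
    vapply(1:7, function(i) {
      C <- subsites:::atom_xyz(pep[pep$res_seq == i, ], "C")
      N <- subsites:::atom_xyz(pep[pep$res_seq == i + 1, ], "N")
      sqrt(sum((C - N)^2))
    }, numeric(1))
  }
  expect_equal(bonds_of(moved), bonds_of(s), tolerance = 1e-6)
  expect_error(backrub_rotate(s, "P", 1, 1, 5), "2-12")
})

test_that("side-chain torsion rotation changes chi by exactly the delta", {
  fx <- make_toy_complex()
  s <- fx$structure
  res <- s[s$chain == "P" & s$res_seq == 4, ]
  chi_before <- measure_chi(res, "LEU")
  out <- rotate_chi(s, "P", 4, 1, 23)
  chi_after <- measure_chi(out[out$chain == "P" & out$res_seq == 4, ], "LEU")
  d <- (chi_after[["chi1"]] - chi_before[["chi1"]] + 180) %% 360 - 180
  expect_equal(d, 23, tolerance = 1e-6)
  # backbone untouched
  bb <- function(st) atom_coords(dplyr::filter(
    st, chain == "P", atom %in% c("N", "CA", "C", "O")))
  expect_equal(bb(out), bb(s), tolerance = 1e-12)
})

test_that("the Metropolis rule accepts downhill always and uphill at exp(-dE/kT)", {
  expect_true(all(metropolis_accept(rep(-5, 100), 1.2)))
  expect_true(all(metropolis_accept(rep(0, 100), 1.2)))
  set.seed(31)
  n <- 1e5
  acc <- mean(metropolis_accept(rep(1.2, n), kT = 1.2))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  expect_error(metropolis_accept(1, kT = 0), "positive")
})

test_that("a two-state chain reaches the Boltzmann ratio", {
  set.seed(5)
  kT <- 1.2
  dE <- 1.0
  n <- 1e5
  state <- 0L
  visits_high <- 0L
  for (i in seq_len(n)) {
    proposed_delta <- if (state == 0L) dE else -dE
    if (metropolis_accept(proposed_delta, kT)) state <- 1L - state
    visits_high <- visits_high + state
  }
  p_high <- visits_high / n
  p_expected <- exp(-dE / kT) / (1 + exp(-dE / kT))
  se <- sqrt(p_expected * (1 - p_expected) / n) * 10  # autocorrelated chain
  expect_lt(abs(p_high - p_expected), 3 * se)
})

test_that("sampling yields n_steps/stride frames, reproducibly per seed", {
  fx <- make_toy_complex(fixture_spec(peptide_length = 4))
  cfg <- sampler_config(n_steps = 200, frame_stride = 10, seed = 3)
  t1 <- run_sampling(fx$structure, "P", cfg)
  expect_equal(n_frames(t1), 20)
  expect_equal(t1$steps, seq(10, 200, by = 10))
  expect_true(all(is.finite(t1$energies)))
  t2 <- run_sampling(fx$structure, "P", cfg)
  expect_identical(t1$energies, t2$energies)
  expect_identical(t1$frames[[20]], t2$frames[[20]])

  # chain connectivity: backbone bonds within 0.05 A of the start
  check_frame <- frame_structure(t1, n_frames(t1))
  pep0 <- dplyr::filter(fx$structure, chain == "P")
  pepF <- dplyr::filter(check_frame, chain == "P")
  for (i in 1:3) {
    b0 <- sqrt(sum((subsites:::atom_xyz(pep0[pep0$res_seq == i, ], "C") -
                      subsites:::atom_xyz(pep0[pep0$res_seq == i + 1, ], "N"))^2))
    bF <- sqrt(sum((subsites:::atom_xyz(pepF[pepF$res_seq == i, ], "C") -
                      subsites:::atom_xyz(pepF[pepF$res_seq == i + 1, ], "N"))^2))
    expect_lt(abs(bF - b0), 0.05)
  }

  # tidiers
  td <- tidy(t1)
  expect_equal(nrow(td), 20)
  expect_named(td, c("frame", "step", "energy"))
  gl <- glance(t1)
  expect_equal(gl$n_frames, 20)
  expect_true(gl$acceptance_rate >= 0 && gl$acceptance_rate <= 1)
})

test_that("invalid sampler configurations are rejected", {
  expect_error(sampler_config(n_steps = 0), "at least 1")
  expect_error(sampler_config(kT = -1), "positive")
  expect_error(sampler_config(n_steps = 10, frame_stride = 20), "frame_stride")
})
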