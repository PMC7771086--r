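aa20 <- sort(subsites:::AA1)

test_that("specificity matrices load, normalise and validate", {
  f <- tempfile(fileext = ".tsv")
  mat <- matrix(1, 20, 8, dimnames = list(aa20, P_LABELS))
  readr::write_tsv(tibble::as_tibble(mat, rownames = "aa"), f)
  sm <- load_specificity_matrix(f)
  expect_true(all(abs(sm$freq - 0.05) < 1e-12))
  expect_true(all(abs(colSums(sm$freq) - 1) < 1e-9))

  # one-hot column stays one-hot after normalisation
  mat2 <- mat
  mat2[, "P1"] <- 0
  mat2["K", "P1"] <- 7
  readr::write_tsv(tibble::as_tibble(mat2, rownames = "aa"), f)
  sm2 <- load_specificity_matrix(f)
  expect_equal(sm2$freq["K", "P1"], 1)
  expect_equal(sum(sm2$freq[, "P1"] > 0), 1)

  # zero-total column is degenerate
  mat3 <- mat
  mat3[, "P2"] <- 0
  readr::write_tsv(tibble::as_tibble(mat3, rownames = "aa"), f)
  expect_error(load_specificity_matrix(f), "zero total")

  # malformed dimensions and bad letters
  expect_error(specificity_matrix(matrix(1, 19, 8)), "20 x 8")
  expect_error(specificity_matrix(matrix(-1, 20, 8,
                                         dimnames = list(aa20, NULL))),
               "non-negative")
  badaa <- c(aa20[-1], "B")
  readr::write_tsv(tibble::as_tibble(
    matrix(1, 20, 8, dimnames = list(badaa, P_LABELS)), rownames = "aa"), f)
  expect_error(load_specificity_matrix(f), "ambiguous|amino")
})

test_that("per-position entropy hits its analytic anchors", {
  expect_equal(position_entropy(rep(0.05, 20)), 1)
  expect_equal(position_entropy(c(1, rep(0, 19))), 0)
  two <- c(0.5, 0.5, rep(0, 18))
  expect_equal(position_entropy(two), log(2) / log(20), tolerance = 1e-12)
  expect_error(position_entropy(rep(0.1, 20)), "sum to 1")
})

test_that("entropy is bounded, permutation-invariant and concave", {
  set.seed(23)
  for (k in 1:25) {
    col <- rexp(20)
    col <- col / sum(col)
    h <- position_entropy(col)
    expect_gte(h, 0)
    expect_lte(h, 1 + 1e-12)
    expect_equal(position_entropy(sample(col)), h, tolerance = 1e-12)
  }
  # concavity under mixing
  for (k in 1:10) {
    a <- rexp(20); a <- a / sum(a)
    b <- rexp(20); b <- b / sum(b)
    expect_gte(position_entropy((a + b) / 2) + 1e-12,
               (position_entropy(a) + position_entropy(b)) / 2)
  }
})

test_that("total cleavage entropy spans [0, 8] and is additive", {
  uniform <- make_toy_matrix(promiscuous_positions = P_LABELS)
  e_u <- cleavage_entropy(uniform)
  expect_equal(total_cleavage_entropy(e_u), 8)
  expect_equal(e_u$H, rep(1, 8))

  onehot <- make_toy_matrix(specific_positions = P_LABELS,
                            promiscuous_positions = character(0))
  e_o <- cleavage_entropy(onehot)
  expect_equal(total_cleavage_entropy(e_o), 0)

  mixed <- make_toy_matrix(specific_positions = "P1",
                           promiscuous_positions = setdiff(P_LABELS, "P1"))
  e_m <- cleavage_entropy(mixed)
  expect_equal(total_cleavage_entropy(e_m), sum(e_m$H), tolerance = 1e-12)
  expect_equal(e_m$H[e_m$position == "P1"], 0)
  expect_equal(sum(e_m$H), 7)

  gl <- glance(e_m)
  expect_equal(gl$H_cleavage, 7)
})

test_that("per-position Spearman handles order, reversal, ties and constants", {
  ent <- tibble::tibble(structure = "s1", position = P_LABELS,
                        H = c(0.9, 0.8, 0.5, 0.1, 0.2, 0.6, 0.7, 0.95))
  same <- tibble::tibble(structure = "s1", observable = "rel_asa",
                         position = P_LABELS, value = ent$H)
  expect_equal(spearman_per_position(same, ent)$rho_mean, 1)
  rev <- same
  rev$value <- -ent$H
  expect_equal(spearman_per_position(rev, ent)$rho_mean, -1)

  # ties: equals the explicit average-rank formula
  tied <- same
  tied$value <- c(1, 1, 2, 2, 3, 3, 4, 4)
  got <- spearman_per_position(tied, ent)$rho_mean
  expect_equal(got, rank_rho(tied$value, ent$H), tolerance = 1e-12)

  # a constant profile is dropped with a warning
  both <- dplyr::bind_rows(
    same,
    tibble::tibble(structure = "s2", observable = "rel_asa",
                   position = P_LABELS, value = 1)
  )
  ent2 <- dplyr::bind_rows(ent, dplyr::mutate(ent, structure = "s2"))
  expect_warning(out <- spearman_per_position(both, ent2), "constant")
  expect_equal(out$n_structures, 1)
  expect_equal(out$rho_mean, 1)
})

test_that("toy matrices demand a clean partition of the positions", {
  expect_error(make_toy_matrix(specific_positions = "P1",
                               promiscuous_positions = P_LABELS),
               "overlap")
  expect_error(make_toy_matrix(specific_positions = "P1",
                               promiscuous_positions = c("P2", "P3")),
               "partition")
})
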