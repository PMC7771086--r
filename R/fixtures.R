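# Deterministic toy fixtures: an ideal-geometry beta-groove "protease"
# holding an extended peptide, with catalytic residues next to the
# P1/P1' junction, an S1 cradle that buries P1, optional prime-side
# blockage and an optional non-natural residue; plus toy specificity
# matrices with entropies known by construction.  The fixtures exist to
# exercise contracts, not to claim physical realism.

#' Specification of a toy protease-peptide complex
#'
#' @param seed integer seed (used for the random parts of matrix
#'   fixtures; the complex itself is fully deterministic).
#' @param peptide_length bound-peptide length, 2-12 residues.
#' @param groove_offset distance of the two groove strands from the
#'   peptide axis, Angstrom.
#' @param groove_depth gap between the P1 side-chain tip and the S1
#'   cradle, Angstrom; smaller is deeper burial.
#' @param blocked_prime_side add a dense obstacle where the prime-side
#'   positions would be modelled.
#' @param nnaa_at optional peptide position index carrying a
#'   norleucine instead of its natural residue.
#' @param peptide_sequence 1-letter sequence (recycled default).
#' @return list of class `subsites_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, peptide_length = 8, groove_offset = 4.8,
                         groove_depth = 4.4, blocked_prime_side = FALSE,
                         nnaa_at = NULL,
                         peptide_sequence = "KATLSVNEAGTF") {
  if (peptide_length < 2 || peptide_length > 12) {
    abort("peptide_length must lie in [2, 12]")
  }
  if (!is.null(nnaa_at) &&
      (nnaa_at < 1 || nnaa_at > peptide_length)) {
    abort("nnaa_at outside the peptide")
  }
  out <- list(seed = as.integer(seed), peptide_length = peptide_length,
              groove_offset = groove_offset, groove_depth = groove_depth,
              blocked_prime_side = blocked_prime_side, nnaa_at = nnaa_at,
              peptide_sequence = substr(peptide_sequence, 1, peptide_length))
  class(out) <- "subsites_fixture_spec"
  out
}

# Canonical orientation for groove assembly: chain axis (first CA to
# last CA) along +x, mean alternation-corrected side-chain direction
# along +z, first CA at the origin.  Makes fixed y-offsets perpendicular
# to every chain.
orient_extended <- function(s) {
  ca <- filter(s, .data$atom == "CA")
  xyz <- atom_coords(s)
  origin <- c(ca$x[1], ca$y[1], ca$z[1])
  xyz <- sweep(xyz, 2, origin)
  u <- unit(c(ca$x[nrow(ca)], ca$y[nrow(ca)], ca$z[nrow(ca)]) - origin)
  # rotate u onto x
  axis1 <- vcross(u, c(1, 0, 0))
  if (vnorm(axis1) > 1e-8) {
    ang1 <- rad2deg(acos(max(-1, min(1, u[1]))))
    xyz <- rotate_points(xyz, c(0, 0, 0), axis1, ang1)
  }
  s2 <- set_atom_coords(s, xyz)
  # roll: alternation-corrected mean CB (or carbonyl O) direction -> +z
  ca2 <- filter(s2, .data$atom == "CA")
  dirs <- purrr::map(seq_len(nrow(ca2)), function(i) {
    rs <- ca2$res_seq[i]
    ref <- filter(s2, .data$res_seq == rs, .data$chain == ca2$chain[i],
                  .data$atom == "CB")
    if (nrow(ref) == 0) {
      ref <- filter(s2, .data$res_seq == rs, .data$chain == ca2$chain[i],
                    .data$atom == "O")
    }
    if (nrow(ref) == 0) return(NULL)
    v <- c(ref$x[1] - ca2$x[i], ref$y[1] - ca2$y[i], ref$z[1] - ca2$z[i])
    v * (-1)^(i + 1)
  })
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  if (length(dirs) > 0) {
    w <- Reduce(`+`, dirs)
    w[1] <- 0  # project off the chain axis
    if (vnorm(w) > 1e-8) {
      ang2 <- rad2deg(atan2(w[2], w[3]))
      xyz <- rotate_points(atom_coords(s2), c(0, 0, 0), c(1, 0, 0), ang2)
      s2 <- set_atom_coords(s2, xyz)
    }
  }
  s2
}

#' Build a toy protease-peptide complex
#'
#' Constructs an extended peptide (chain P) flanked by two parallel
#' beta strands (chain E) forming a groove, a three-residue cradle
#' under the P1 side chain (the "S1 pocket"), and catalytic Ser/His
#' residues on the top strand next to the P1/P1' junction (within the
#' ~5 Angstrom contact range of the scissile bond).  Ground-truth
#' pocket membership is recorded by direct construction-time distance
#' checks, independently of the annotation code.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `subsites_fixture`: `structure`, `catalytic`
#'   (tibble chain/res_seq/role), `ref_positions` (tibble
#'   res_seq/pocket), `truth` (a `subsites_pockets`) and `spec`.
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  L <- spec$peptide_length
  pep <- orient_extended(build_peptide(spec$peptide_sequence, chain_id = "P"))
  pep_ca <- filter(pep, .data$atom == "CA")
  rise <- if (L > 1) {
    (pep_ca$x[nrow(pep_ca)] - pep_ca$x[1]) / (L - 1)
  } else 3.4

  strand_len <- L + 5L
  overhang <- 2L
  # Catalytic Ser (top strand) and His (bottom strand) flank the P1/P1'
  # junction.  Strand residues alternate which face of the pleat their
  # side chain points to; the indices are parity-corrected so both
  # catalytic side chains point away from the groove.
  p1 <- min(4L, L)
  # strand residue i + overhang sits across peptide residue i
  top_idx <- p1 + overhang           # across P1
  if (top_idx %% 2L == 1L) top_idx <- top_idx + 1L
  bottom_idx <- p1 + 1L + overhang   # across P1'
  if (bottom_idx %% 2L == 0L) bottom_idx <- bottom_idx + 1L
  cat_idx <- c(top_idx, bottom_idx)
  # catalytic Ser on the top strand, His on the bottom strand: both
  # next to the junction, side chains oriented away from the groove
  top_seq <- rep("G", strand_len)
  top_seq[cat_idx[1]] <- "S"
  bottom_seq <- rep("G", strand_len)
  bottom_seq[cat_idx[2]] <- "H"
  top <- build_peptide(paste(top_seq, collapse = ""),
                       chain_id = "E", start_res = 101L)
  bottom <- build_peptide(paste(bottom_seq, collapse = ""),
                          chain_id = "E", start_res = 201L)
  shift <- function(s, dx, dy, dz) {
    s$x <- s$x + dx; s$y <- s$y + dy; s$z <- s$z + dz; s
  }
  # Register the strands onto the peptide by superposing their middle
  # CA atoms (residue i + overhang onto peptide residue i): torsions
  # are identical, so the whole strand keeps a constant lateral offset
  # along the groove (sheet-like, hydrogen-bond capable) instead of
  # drifting at the ends.
  register_strand <- function(strand, dy) {
    bb <- c("N", "CA", "C")
    pep_bb <- filter(pep, .data$atom %in% bb)
    st_bb <- filter(strand, .data$atom %in% bb,
                    .data$res_seq %in%
                      (min(strand$res_seq) + overhang - 1L + seq_len(L)))
    sp <- superpose(atom_coords(pep_bb), atom_coords(st_bb))
    shift(apply_superposition(strand, sp), 0, dy, 0)
  }
  top <- register_strand(top, spec$groove_offset)
  bottom <- register_strand(bottom, -spec$groove_offset)

  parts <- list(pep, top, bottom)

  # S1 cradle: three glycines beyond the P1 side-chain tip.
  if (L >= 4) {
    p1_res <- pep[pep$res_seq == p1, ]
    ca <- atom_xyz(p1_res, "CA")
    side <- p1_res[!p1_res$atom %in% c("N", "CA", "C", "O"), ]
    if (nrow(side) > 0) {
      # farthest side-chain heavy atom = the tip the cage forms around
      sxyz <- as.matrix(side[, c("x", "y", "z")])
      dist_from_ca <- sqrt(rowSums(sweep(sxyz, 2, ca)^2))
      tip <- sxyz[which.max(dist_from_ca), ]
      u <- unit(tip - ca)
      v <- unit(vcross(u, c(1, 0, 0)))  # lateral pocket direction
      w <- vcross(u, v)
      inner <- list(u,
                    unit(u + v), unit(u - v),
                    unit(u + w), unit(u - w),
                    unit(u + v + w), unit(u + v - w),
                    unit(u - v + w), unit(u - v - w),
                    unit(u + 2 * v), unit(u - 2 * v))
      placements <- lapply(inner, function(d) tip + d * spec$groove_depth)
      for (k in seq_along(placements)) {
        # non-consecutive numbering: the cage residues are not bonded
        pocket_res <- build_peptide("G", chain_id = "E",
                                    start_res = 300L + 10L * k)
        c_ca <- filter(pocket_res, .data$atom == "CA")
        target <- placements[[k]]
        pocket_res <- shift(pocket_res, target[1] - c_ca$x[1],
                            target[2] - c_ca$y[1], target[3] - c_ca$z[1])
        parts <- c(parts, list(pocket_res))
      }
    }
  }

  # Prime-side blockage: a dense grid of carbon atoms filling the
  # region where C-terminal extension would have to go.
  if (isTRUE(spec$blocked_prime_side)) {
    x_last <- pep_ca$x[nrow(pep_ca)]
    gx <- seq(x_last + 1.5, x_last + 11, by = 1.6)
    gy <- seq(-4.5, 4.5, by = 1.6)
    gz <- seq(-4.5, 4.5, by = 1.6)
    grid <- expand.grid(x = gx, y = gy, z = gz)
    block <- tibble(
      chain = "B", res_seq = 1L, ins = "", res_name = "UNK",
      atom = paste0("C", seq_len(nrow(grid))),
      element = "C", x = grid$x, y = grid$y, z = grid$z,
      occ = 1, het = TRUE
    )
    parts <- c(parts, list(block))
  }

  structure <- new_structure(bind_rows(parts), source_id = "toy_complex")

  # Settle the P1 side chain into the cage it was built around.
  if (L >= 4) {
    structure <- relax_sidechain(structure, "P", p1)
  }

  # Settle the catalytic side chains into clash-free rotamers.
  for (rs in c(100L + cat_idx[1], 200L + cat_idx[2])) {
    idx <- which(structure$chain == "E" & structure$res_seq == rs &
                   !(structure$atom %in% c("N", "CA", "C", "O")))
    if (length(idx) == 0) next
    res_name <- structure$res_name[idx[1]]
    nchi <- length(CHI_ATOMS[[res_name]] %||% list())
    if (nchi == 0) next
    best <- structure
    best_clash <- clash_count(structure, idx)
    for (c1 in c(-65, 65, 180)) {
      for (c2 in if (nchi >= 2) c(90, -90, 180) else 0) {
        cand <- structure
        cur <- measure_chi(cand[cand$chain == "E" & cand$res_seq == rs, ],
                           res_name)
        cand <- rotate_chi(cand, "E", rs, 1, c1 - cur[["chi1"]])
        if (nchi >= 2 && "chi2" %in% names(cur)) {
          cand <- rotate_chi(cand, "E", rs, 2, c2 - cur[["chi2"]])
        }
        cl <- clash_count(cand, idx)
        if (cl < best_clash) {
          best <- cand
          best_clash <- cl
          if (cl == 0) break
        }
      }
      if (best_clash == 0) break
    }
    structure <- best
  }

  if (!is.null(spec$nnaa_at)) {
    structure <- swap_in_nnaa(structure, "P", spec$nnaa_at)
  }

  catalytic <- tibble(
    chain = "E", res_seq = c(100L + cat_idx[1], 200L + cat_idx[2]),
    role = c("nucleophile", "base")
  )
  ref_positions <- tibble(res_seq = seq_len(min(L, 8L)),
                          pocket = POCKET_LABELS[seq_len(min(L, 8L))])
  truth <- fixture_truth(structure, "P", ref_positions)
  out <- list(structure = structure, catalytic = catalytic,
              ref_positions = ref_positions, truth = truth, spec = spec)
  class(out) <- "subsites_fixture"
  out
}

# Replace a peptide residue's side chain with norleucine (HETATM).
swap_in_nnaa <- function(structure, chain_id, res_seq) {
  sel <- which(structure$chain == chain_id & structure$res_seq == res_seq)
  res_tbl <- structure[sel, ]
  bb <- res_tbl[res_tbl$atom %in% c("N", "CA", "C", "O"), ]
  side <- build_side_chain(
    list(N = atom_xyz(res_tbl, "N"), CA = atom_xyz(res_tbl, "CA"),
         C = atom_xyz(res_tbl, "C")), "NLE")
  side$chain <- chain_id
  side$res_seq <- res_seq
  side$ins <- ""
  side$res_name <- "NLE"
  side$occ <- 1
  side$het <- TRUE
  bb$res_name <- "NLE"
  bb$het <- TRUE
  out <- bind_rows(
    structure[seq_len(min(sel) - 1), ],
    bind_rows(bb, side),
    if (max(sel) < nrow(structure))
      structure[(max(sel) + 1):nrow(structure), ]
  )
  new_structure(out, source_id = attr(structure, "source_id") %||% "")
}

# Ground-truth pocket membership by plain construction-time loops
# (deliberately naive and independent of the annotation code path).
fixture_truth <- function(structure, peptide_chain, ref_positions,
                          cutoff = 4.5) {
  pep <- structure[structure$chain == peptide_chain &
                     !is_water(structure$res_name), ]
  prot <- structure[structure$chain != peptide_chain &
                      !is_water(structure$res_name), ]
  prot_res <- unique(paste(prot$chain, prot$res_seq))
  rows <- list()
  for (k in seq_len(nrow(ref_positions))) {
    prs <- ref_positions$res_seq[k]
    pxyz <- pep[pep$res_seq == prs, c("x", "y", "z")]
    for (pr in prot_res) {
      parts <- strsplit(pr, " ")[[1]]
      sub <- prot[prot$chain == parts[1] &
                    prot$res_seq == as.integer(parts[2]), ]
      hit <- FALSE
      for (i in seq_len(nrow(sub))) {
        for (j in seq_len(nrow(pxyz))) {
          dd <- sqrt((sub$x[i] - pxyz$x[j])^2 + (sub$y[i] - pxyz$y[j])^2 +
                       (sub$z[i] - pxyz$z[j])^2)
          if (dd <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) {
        rows[[length(rows) + 1]] <- tibble(
          chain = parts[1], res_seq = as.integer(parts[2]), ins = "",
          res_name = sub$res_name[1], pocket = ref_positions$pocket[k]
        )
      }
    }
  }
  pep_res <- residue_table(pep) |>
    left_join(select(ref_positions, "res_seq", "pocket"), by = "res_seq")
  new_pocket_assignment(pep_res, bind_rows(rows), peptide_chain)
}

#' Build a toy specificity matrix with known entropies
#'
#' Specific positions get a one-hot column (entropy 0); promiscuous
#' positions a uniform column (entropy 1).  The one-hot amino acid at
#' each specific position is drawn reproducibly from the seed.
#'
#' @param specific_positions,promiscuous_positions character vectors of
#'   P labels partitioning P4-P4'.
#' @param seed integer seed.
#' @return a `subsites_specmat`.
#' @export
make_toy_matrix <- function(specific_positions = character(0),
                            promiscuous_positions = P_LABELS,
                            seed = 1) {
  specific_positions <- as.character(specific_positions)
  promiscuous_positions <- as.character(promiscuous_positions)
  if (length(intersect(specific_positions, promiscuous_positions)) > 0) {
    abort("specific and promiscuous positions overlap")
  }
  if (!setequal(c(specific_positions, promiscuous_positions), P_LABELS)) {
    abort("positions must partition P4-P4'")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  aa_sorted <- sort(AA1)
  mat <- matrix(0, 20, 8, dimnames = list(aa_sorted, P_LABELS))
  for (p in P_LABELS) {
    if (p %in% promiscuous_positions) {
      mat[, p] <- 1 / 20
    } else {
      mat[sample(aa_sorted, 1), p] <- 1
    }
  }
  specificity_matrix(mat, "fractions", family_id = "toy")
}
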