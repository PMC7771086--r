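# Metropolis Monte Carlo sampling of the protease-peptide complex with
# backrub-style rigid-segment backbone rotations and Gaussian side-chain
# torsion moves.  The flexible region defaults to the peptide plus the
# pocket residues; the rest of the protease stays frozen.

#' Sampler configuration
#'
#' @param n_steps Monte Carlo steps (5000).
#' @param kT Metropolis temperature factor in model energy units (1.2).
#' @param frame_stride record one frame every `frame_stride` steps, so
#'   the defaults yield 5000/10 = 500 frames.
#' @param seed integer RNG seed.
#' @param p_backbone probability of proposing a backbone (backrub) move
#'   rather than a side-chain move.
#' @param max_angle maximum backrub rotation, degrees (11).
#' @param sidechain_sigma side-chain torsion step standard deviation,
#'   degrees (20).
#' @return list of class `subsites_sampler_config`.
#' @export
sampler_config <- function(n_steps = 5000, kT = 1.2, frame_stride = 10,
                           seed = 1, p_backbone = 0.5, max_angle = 11,
                           sidechain_sigma = 20) {
  if (n_steps < 1) abort("n_steps must be at least 1")
  if (kT <= 0) abort("kT must be positive")
  if (frame_stride < 1 || frame_stride > n_steps) {
    abort("frame_stride must lie in [1, n_steps]")
  }
  out <- list(n_steps = as.integer(n_steps), kT = kT,
              frame_stride = as.integer(frame_stride),
              seed = as.integer(seed), p_backbone = p_backbone,
              max_angle = max_angle, sidechain_sigma = sidechain_sigma)
  class(out) <- "subsites_sampler_config"
  out
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-delta_e / kT))`; vectorised
#' over `delta_e`.
#'
#' @param delta_e energy change(s) of the proposal.
#' @param kT temperature factor, > 0.
#' @return logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_e, kT = 1.2) {
  if (kT <= 0) abort("kT must be positive")
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e / kT)
}

#' Deterministic backrub rotation
#'
#' Rigidly rotates the backbone segment between the CA atoms of
#' `res_start` and `res_end` (the carbonyl of the first pivot, all atoms
#' of the interior residues, and the amide of the last pivot) about the
#' CA-CA axis.  Bond lengths are preserved exactly.
#'
#' @param structure atom tibble.
#' @param chain_id chain holding the segment.
#' @param res_start,res_end pivot residue numbers (inclusive span of
#'   2-12 residues).
#' @param angle rotation angle in degrees.
#' @return list with the rotated `structure` and `moved` (row indices).
#' @export
backrub_rotate <- function(structure, chain_id, res_start, res_end, angle) {
  span <- res_end - res_start + 1
  if (span < 2 || span > 12) abort("backrub segment must span 2-12 residues")
  in_chain <- structure$chain == chain_id
  ca1 <- which(in_chain & structure$res_seq == res_start &
                 structure$atom == "CA")
  ca2 <- which(in_chain & structure$res_seq == res_end &
                 structure$atom == "CA")
  if (length(ca1) == 0 || length(ca2) == 0) abort("pivot CA atoms missing")
  p1 <- as.numeric(structure[ca1[1], c("x", "y", "z")])
  p2 <- as.numeric(structure[ca2[1], c("x", "y", "z")])
  moved <- which(
    (in_chain & structure$res_seq == res_start &
       structure$atom %in% c("C", "O")) |
      (in_chain & structure$res_seq > res_start &
         structure$res_seq < res_end) |
      (in_chain & structure$res_seq == res_end &
         structure$atom %in% c("N", "H"))
  )
  if (length(moved) == 0 || abs(angle) < 1e-12) {
    return(list(structure = structure, moved = moved))
  }
  xyz <- as.matrix(structure[moved, c("x", "y", "z")])
  xyz <- rotate_points(xyz, p1, p2 - p1, angle)
  structure[moved, c("x", "y", "z")] <- as.data.frame(xyz)
  list(structure = structure, moved = moved)
}

# Runs of consecutive residue numbers eligible for backrub pivots.
flexible_runs <- function(flexible) {
  flexible |>
    group_by(.data$chain) |>
    arrange(.data$res_seq, .by_group = TRUE) |>
    mutate(run = cumsum(c(1, diff(.data$res_seq) != 1))) |>
    group_by(.data$chain, .data$run) |>
    summarise(from = min(.data$res_seq), to = max(.data$res_seq),
              len = n(), .groups = "drop") |>
    filter(.data$len >= 2)
}

#' Random backrub proposal
#'
#' Chooses a random flexible segment of 2-12 consecutive residues and a
#' rotation angle uniform in `[-max_angle, max_angle]`.
#'
#' @param structure atom tibble.
#' @param flexible tibble (chain, res_seq) of flexible residues.
#' @param max_angle maximum rotation in degrees.
#' @return as [backrub_rotate()]; `NULL` when no eligible segment.
#' @export
backrub_move <- function(structure, flexible, max_angle = 11) {
  runs <- flexible_runs(flexible)
  if (nrow(runs) == 0) return(NULL)
  r <- runs[sample.int(nrow(runs), 1), ]
  max_span <- min(12, r$to - r$from + 1)
  span <- 1 + sample.int(max_span - 1, 1)
  start <- r$from + sample.int(r$to - r$from + 1 - span + 1, 1) - 1
  angle <- runif(1, -max_angle, max_angle)
  backrub_rotate(structure, r$chain, start, start + span - 1, angle)
}

#' Random side-chain torsion proposal
#'
#' Perturbs one random chi angle of one random flexible residue by a
#' Gaussian step; residues without rotatable chi torsions (glycine,
#' alanine, proline) are skipped and resampled.
#'
#' @param structure atom tibble.
#' @param flexible tibble (chain, res_seq) of flexible residues.
#' @param sigma step standard deviation, degrees.
#' @return list with `structure` and `moved` row indices; `NULL` when no
#'   residue is rotatable.
#' @export
sidechain_move <- function(structure, flexible, sigma = 20) {
  res <- residue_table(structure) |>
    dplyr::semi_join(flexible, by = c("chain", "res_seq")) |>
    filter(!(.data$res_name %in% c("GLY", "ALA", "PRO")),
           .data$res_name %in% names(CHI_ATOMS))
  if (nrow(res) == 0) return(NULL)
  pick <- res[sample.int(nrow(res), 1), ]
  defs <- CHI_ATOMS[[pick$res_name]]
  k <- sample.int(length(defs), 1)
  delta <- rnorm(1, 0, sigma)
  before <- structure
  out <- rotate_chi(structure, pick$chain, pick$res_seq, k, delta)
  moved <- which(out$x != before$x | out$y != before$y | out$z != before$z)
  list(structure = out, moved = moved)
}

#' Run Metropolis Monte Carlo sampling
#'
#' Alternates backrub and side-chain proposals by the configured
#' weights, accepts by the Metropolis rule at the configured kT, and
#' records a coordinate frame every `frame_stride` steps (accepted or
#' not), yielding `n_steps / frame_stride` frames.
#'
#' @param structure the complex to sample.
#' @param peptide_chain peptide chain id.
#' @param config a [sampler_config()].
#' @param model a [energy_model()].
#' @param pocket_residues optional tibble (chain, res_seq) of protease
#'   residues sampled alongside the peptide; when `NULL`, protease
#'   residues with any atom within 4.5 Angstrom of the peptide are
#'   used.
#' @param run_index label of this run (alpha in the averaging).
#' @return object of class `subsites_trajectory`: frames (list of
#'   coordinate matrices), per-frame energies and steps, the template
#'   structure, acceptance count and the configuration.
#' @export
run_sampling <- function(structure, peptide_chain,
                         config = sampler_config(),
                         model = energy_model(),
                         pocket_residues = NULL, run_index = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  pep <- filter(structure, .data$chain == peptide_chain)
  if (nrow(pep) == 0) abort("peptide chain not found")
  if (is.null(pocket_residues)) {
    prot <- filter(structure, .data$chain != peptide_chain,
                   !is_water(.data$res_name))
    d <- cross_dist(atom_coords(prot), atom_coords(pep))
    near <- apply(d, 1, min) <= 4.5
    pocket_residues <- distinct(prot[near, ], .data$chain, .data$res_seq)
  }
  flexible <- bind_rows(
    distinct(pep, .data$chain, .data$res_seq),
    pocket_residues[, c("chain", "res_seq")]
  ) |> distinct()

  cur <- structure
  e_total <- total_energy(cur, model)
  if (!is.finite(e_total)) abort("non-finite starting energy")
  n_frames <- config$n_steps %/% config$frame_stride
  frames <- vector("list", n_frames)
  energies <- numeric(n_frames)
  steps <- integer(n_frames)
  accepted <- 0L
  fi <- 0L
  all_idx <- seq_len(nrow(cur))
  pc <- energy_precompute(cur)

  for (step in seq_len(config$n_steps)) {
    use_backbone <- runif(1) < config$p_backbone
    prop <- if (use_backbone) {
      backrub_move(cur, flexible, config$max_angle)
    } else {
      sidechain_move(cur, flexible, config$sidechain_sigma)
    }
    if (!is.null(prop) && length(prop$moved) > 0) {
      moved <- prop$moved
      rest <- setdiff(all_idx, moved)
      e_old <- energy_between(cur, moved, rest, model, pc) +
        energy_within(cur, moved, model, pc)
      pc_new <- pc
      pc_new$xyz <- atom_coords(prop$structure)
      e_new <- energy_between(prop$structure, moved, rest, model, pc_new) +
        energy_within(prop$structure, moved, model, pc_new)
      delta <- e_new - e_old
      if (!is.finite(delta)) abort("energy divergence during sampling")
      if (metropolis_accept(delta, config$kT)) {
        cur <- prop$structure
        pc <- pc_new
        e_total <- e_total + delta
        accepted <- accepted + 1L
      }
    }
    if (step %% config$frame_stride == 0) {
      fi <- fi + 1L
      frames[[fi]] <- atom_coords(cur)
      energies[fi] <- e_total
      steps[fi] <- step
    }
  }
  out <- list(
    frames = frames, energies = energies, steps = steps,
    template = structure, final = cur, peptide_chain = peptide_chain,
    acceptance = accepted, config = config, run_index = run_index,
    flexible = flexible
  )
  class(out) <- "subsites_trajectory"
  out
}

#' Number of frames in a trajectory
#' @param trajectory a `subsites_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Materialise one frame as a structure
#'
#' @param trajectory a `subsites_trajectory`.
#' @param f frame index.
#' @return atom tibble with the frame's coordinates.
#' @export
frame_structure <- function(trajectory, f) {
  set_atom_coords(trajectory$template, trajectory$frames[[f]])
}

#' @export
print.subsites_trajectory <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo trajectory: %d frames / %d steps, %.1f%% accepted, kT %.2f\n",
    n_frames(x), x$config$n_steps, 100 * x$acceptance / x$config$n_steps,
    x$config$kT))
  invisible(x)
}

#' Write a trajectory as a multi-MODEL PDB document
#'
#' @param trajectory a `subsites_trajectory`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- write_pdb(frame_structure(trajectory, f))
    writeLines(lines[!grepl("^END", lines)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Energy series of a trajectory as a tibble
#'
#' @param x a `subsites_trajectory`.
#' @param ... unused.
#' @return tibble with step, frame and energy columns.
#' @export
tidy.subsites_trajectory <- function(x, ...) {
  tibble(frame = seq_along(x$steps), step = x$steps, energy = x$energies)
}

#' One-row summary of a trajectory
#'
#' @param x a `subsites_trajectory`.
#' @param ... unused.
#' @return tibble with frame count, steps, acceptance rate and energy
#'   summaries.
#' @export
glance.subsites_trajectory <- function(x, ...) {
  tibble(
    n_frames = n_frames(x),
    n_steps = x$config$n_steps,
    kT = x$config$kT,
    acceptance_rate = x$acceptance / x$config$n_steps,
    energy_mean = mean(x$energies),
    energy_min = min(x$energies)
  )
}
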