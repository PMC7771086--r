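# Per-frame, per-position structural observables and their averaging.
# Six observables per substrate position: relative accessible surface
# area, hydrogen-bond counts (main/side chain), non-bonded contact
# counts (main/side chain) and the per-residue interface energy.

OBSERVABLE_NAMES <- c("rel_asa", "hb_main", "hb_side", "nb_main",
                      "nb_side", "energy")

# P-position labels for a peptide residue numbering, from an assignment
# or a pocket_map attribute.
position_map <- function(assignment) {
  if (inherits(assignment, "subsites_pockets")) {
    pm <- assignment$peptide_map
    tibble(res_seq = pm$res_seq,
           position = P_LABELS[pocket_index(pm$pocket)])
  } else {
    tibble(res_seq = assignment$res_seq,
           position = P_LABELS[pocket_index(assignment$pocket)])
  }
}

#' Observables of one frame
#'
#' Computes, for every assigned substrate position of the frame: the
#' relative accessible surface area of the residue in the complex, the
#' numbers of cross-partition hydrogen bonds and non-bonded contacts
#' split by main/side chain (classified on the peptide-side atom), and
#' the residue's interface energy.
#'
#' @param frame atom tibble (one conformation of the complex).
#' @param assignment a `subsites_pockets` (or a tibble with `res_seq`
#'   and `pocket`) mapping peptide residues to pockets.
#' @param peptide_chain peptide chain id.
#' @param model a [energy_model()].
#' @param n_sphere_points area quadrature points per atom.
#' @return tibble with position, aa and the six observable columns.
#' @export
frame_observables <- function(frame, assignment, peptide_chain,
                              model = energy_model(),
                              n_sphere_points = 240) {
  pmap_tbl <- position_map(assignment) |> filter(!is.na(.data$position))
  body <- filter(frame, !is_water(.data$res_name))
  pep_idx <- which(body$chain == peptide_chain &
                     body$res_seq %in% pmap_tbl$res_seq)
  asa <- shrake_rupley_asa(body, n_sphere_points = n_sphere_points,
                           subset = pep_idx)
  res_asa <- asa$residue_asa |>
    mutate(rel_asa = relative_asa(.data$asa, .data$res_name))
  hb <- detect_hbonds(body, peptide_chain)
  nb <- detect_nonbonded(body, peptide_chain, hbonds = hb)
  count_part <- function(records, which_part) {
    records |>
      filter(.data$part == which_part) |>
      group_by(res_seq = .data$pep_res_seq) |>
      summarise(n = n(), .groups = "drop")
  }
  en <- interface_energy_per_position(body, peptide_chain, model)
  out <- pmap_tbl |>
    left_join(select(res_asa, "res_seq", "res_name", "rel_asa"),
              by = "res_seq") |>
    left_join(count_part(hb, "main") |> dplyr::rename(hb_main = "n"),
              by = "res_seq") |>
    left_join(count_part(hb, "side") |> dplyr::rename(hb_side = "n"),
              by = "res_seq") |>
    left_join(count_part(nb, "main") |> dplyr::rename(nb_main = "n"),
              by = "res_seq") |>
    left_join(count_part(nb, "side") |> dplyr::rename(nb_side = "n"),
              by = "res_seq") |>
    left_join(select(en, "res_seq", "energy"), by = "res_seq") |>
    mutate(
      aa = aa_three_to_one(.data$res_name),
      across(c("hb_main", "hb_side", "nb_main", "nb_side"),
             ~ tidyr::replace_na(.x, 0L))
    ) |>
    select("position", "aa", dplyr::all_of(OBSERVABLE_NAMES))
  out$position <- factor(out$position, levels = P_LABELS)
  out
}

#' Observables along a trajectory
#'
#' Applies [frame_observables()] to every stored frame.
#'
#' @param trajectory a `subsites_trajectory`.
#' @param assignment pocket assignment of the sampled complex.
#' @param model a [energy_model()].
#' @param stride evaluate every `stride`-th stored frame.
#' @param n_sphere_points area quadrature points.
#' @return tibble of raw records with run, frame, position, aa and the
#'   observable columns.
#' @export
observe_trajectory <- function(trajectory, assignment,
                               model = energy_model(), stride = 1,
                               n_sphere_points = 240) {
  idx <- seq(1, n_frames(trajectory), by = stride)
  rows <- purrr::map(idx, function(f) {
    frame_observables(frame_structure(trajectory, f), assignment,
                      trajectory$peptide_chain, model,
                      n_sphere_points = n_sphere_points) |>
      mutate(run = trajectory$run_index, frame = f)
  })
  bind_rows(rows)
}

#' Average raw observable records into an observable table
#'
#' Computes the per-cell averages O_ij = (1/N_f) sum over runs alpha and
#' frames f of o_ij^(alpha f), where N_f counts the frames contributing
#' to cell (i, j); then averages over the amino acids observed at each
#' position, and records a min-max normalisation of each observable
#' across the eight positions (the raw averages are always retained).
#'
#' @param records tibble from [observe_trajectory()] (rows from several
#'   runs may be bound together).
#' @return object of class `subsites_observables`: list with `cell`
#'   (observable, position, aa, mean, n_frames), `position` (observable,
#'   position, mean, normalized) and `n_frames_total`.
#' @export
average_observables <- function(records) {
  if (nrow(records) == 0) abort("no frames to average")
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(OBSERVABLE_NAMES),
                        names_to = "observable", values_to = "value")
  cell <- long |>
    group_by(.data$observable, .data$position, .data$aa) |>
    summarise(mean = mean(.data$value), n_frames = n(), .groups = "drop")
  position <- cell |>
    group_by(.data$observable, .data$position) |>
    summarise(mean = mean(.data$mean), .groups = "drop") |>
    group_by(.data$observable) |>
    mutate(normalized = if (max(.data$mean) > min(.data$mean)) {
      (.data$mean - min(.data$mean)) / (max(.data$mean) - min(.data$mean))
    } else {
      rep(0.5, dplyr::n())
    }) |>
    ungroup()
  out <- list(cell = cell, position = position,
              n_frames_total = nrow(distinct(records, .data$run,
                                             .data$frame)))
  class(out) <- "subsites_observables"
  out
}

#' @export
print.subsites_observables <- function(x, ...) {
  cat(sprintf("Observable table over %d frames\n", x$n_frames_total))
  print(tidyr::pivot_wider(x$position[, c("observable", "position", "mean")],
                           names_from = "position", values_from = "mean"))
  invisible(x)
}

#' Cell-level averages of an observable table
#' @param x a `subsites_observables`.
#' @param ... unused.
#' @return the `cell` tibble (observable, position, aa, mean, n_frames).
#' @export
tidy.subsites_observables <- function(x, ...) x$cell

#' One-row summary of an observable table
#' @param x a `subsites_observables`.
#' @param ... unused.
#' @return tibble with frame and cell counts.
#' @export
glance.subsites_observables <- function(x, ...) {
  tibble(
    n_frames = x$n_frames_total,
    n_cells = nrow(x$cell),
    n_positions = dplyr::n_distinct(x$position$position),
    n_observables = dplyr::n_distinct(x$cell$observable)
  )
}

#' Per-position summary profile of one observable
#'
#' @param observables a `subsites_observables`.
#' @param observable one of `rel_asa`, `hb_main`, `hb_side`, `nb_main`,
#'   `nb_side`, `energy`.
#' @return tibble (position, mean, normalized) ordered P4 to P4'.
#' @export
position_profile <- function(observables, observable = "rel_asa") {
  if (!observable %in% OBSERVABLE_NAMES) {
    abort(paste0("unknown observable: ", observable))
  }
  observables$position |>
    filter(.data$observable == !!observable) |>
    arrange(.data$position) |>
    select("position", "mean", "normalized")
}
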