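# End-to-end orchestration: annotate -> model -> sample -> observe ->
# entropy -> compare, with a discard manifest mirroring the annotation
# filters and per-stage outputs written to a run directory.

#' Pipeline configuration
#'
#' Flat list of the stage defaults; serialisable as key=value text with
#' [write_config()] / [read_config()].
#'
#' @param pocket_cutoff pocket-assignment cutoff, Angstrom (4.5).
#' @param proj_cutoff annotation-projection cutoff, Angstrom (2.0).
#' @param identity_floor catalytic-transfer identity floor (0.5).
#' @param min_assigned minimum assigned residues to keep a substrate (3).
#' @param library_n peptides per random library (480).
#' @param n_steps,kT,frame_stride sampler settings (5000, 1.2, 10).
#' @param seed master seed; stage seeds derive from it.
#' @param n_sphere_points area quadrature per atom in the observable
#'   stage.
#' @param p_backbone,max_angle sampler move settings.
#' @return list of class `subsites_config`.
#' @export
pipeline_config <- function(pocket_cutoff = 4.5, proj_cutoff = 2.0,
                            identity_floor = 0.5, min_assigned = 3,
                            library_n = 480, n_steps = 5000, kT = 1.2,
                            frame_stride = 10, seed = 1,
                            n_sphere_points = 240, p_backbone = 0.5,
                            max_angle = 11) {
  out <- list(
    pocket_cutoff = pocket_cutoff, proj_cutoff = proj_cutoff,
    identity_floor = identity_floor, min_assigned = min_assigned,
    library_n = library_n, n_steps = n_steps, kT = kT,
    frame_stride = frame_stride, seed = seed,
    n_sphere_points = n_sphere_points, p_backbone = p_backbone,
    max_angle = max_angle
  )
  class(out) <- "subsites_config"
  out
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' @param config a [pipeline_config()].
#' @param file path.
#' @return `write_config` the path invisibly; `read_config` the
#'   configuration.
#' @export
write_config <- function(config, file) {
  writeLines(paste0(names(config), "=",
                    vapply(config, as.character, character(1))), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  defaults <- pipeline_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  defaults[names(vals)] <- vals
  class(defaults) <- "subsites_config"
  defaults
}

#' Run the full pipeline on a set of complexes
#'
#' Executes annotate, model, sample, observe, entropy and compare for
#' every input complex, writing per-stage outputs and a discard
#' manifest (with the filter reasons) to `out_dir`.  Every input
#' structure ends up either in the results or in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param inputs list with components:
#'   \describe{
#'     \item{structures}{named list of atom tibbles (or PDB paths).}
#'     \item{catalytic}{tibble with `pdb_id`, `chain`, `res_seq`,
#'       `role` (or a file path for [read_catalytic_annotation()]).}
#'     \item{reference}{list with `id` (name of the reference
#'       structure) and `ref_positions` (tibble res_seq/pocket for its
#'       peptide).}
#'     \item{peptide_chains}{named character vector: peptide chain per
#'       structure (auto-detected when missing).}
#'     \item{specmat}{a `subsites_specmat` or a file path; entropies
#'       are computed from it.}
#'   }
#' @param out_dir run directory (created).
#' @return list of class `subsites_run`: per-structure results, the
#'   discard manifest, the observable tables, entropy profile and
#'   per-position Spearman comparison.
#' @export
run_pipeline <- function(config, inputs, out_dir = tempfile("subsites_run_")) {
  chain_for <- function(chains, id) {
    if (!is.null(chains) && id %in% names(chains)) chains[[id]] else NA
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.txt"))
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  logf("pipeline start, seed %d", config$seed)

  structures <- inputs$structures
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    abort("inputs$structures must be a named list")
  }
  structures <- purrr::map(structures, function(s) {
    if (is.character(s)) read_pdb(s) else s
  })
  catalytic <- inputs$catalytic
  if (is.character(catalytic)) {
    catalytic <- read_catalytic_annotation(catalytic)
  }
  specmat <- inputs$specmat
  if (is.character(specmat)) specmat <- load_specificity_matrix(specmat)

  discards <- list()
  discard <- function(id, stage, reason) {
    logf("discard %s at %s: %s", id, stage, reason)
    discards[[length(discards) + 1]] <<-
      tibble(structure = id, stage = stage, reason = reason)
  }

  ref_id <- inputs$reference$id
  ref_structure <- structures[[ref_id]]
  if (is.null(ref_structure)) abort("reference structure not found in inputs")

  results <- list()
  records_all <- list()
  profiles <- list()

  for (id in names(structures)) {
    s <- structures[[id]]
    logf("annotate %s", id)
    pep_chain <- chain_for(inputs$peptide_chains, id)
    ligands <- detect_peptide_ligands(s)
    if (is.na(pep_chain)) {
      if (nrow(ligands) == 0) {
        discard(id, "annotate", "no peptide-like ligand of 3-12 residues")
        next
      }
      pep_chain <- ligands$chain[1]
    } else if (!pep_chain %in% ligands$chain) {
      discard(id, "annotate", "designated chain fails the ligand filters")
      next
    }
    s <- strip_capping_groups(s, pep_chain)
    cat_here <- catalytic
    if ("pdb_id" %in% names(cat_here)) {
      cat_here <- filter(cat_here, .data$pdb_id == id)
    }
    occ <- tryCatch(
      catalytic_site_occupancy(s, cat_here, pep_chain),
      error = function(e) {
        discard(id, "annotate", conditionMessage(e))
        NULL
      }
    )
    if (is.null(occ)) next
    if (!occ) {
      discard(id, "annotate", "ligand does not occupy the catalytic site")
      next
    }
    assignment <- if (id == ref_id) {
      assign_pockets_from_reference(s, pep_chain,
                                    inputs$reference$ref_positions,
                                    cutoff = config$pocket_cutoff)
    } else {
      ref_chain <- chain_for(inputs$peptide_chains, ref_id)
      if (is.na(ref_chain)) ref_chain <- pep_chain
      ref_assignment <- assign_pockets_from_reference(
        ref_structure, ref_chain,
        inputs$reference$ref_positions, cutoff = config$pocket_cutoff)
      project_annotation(ref_structure, ref_assignment, s, pep_chain,
                         proj_cutoff = config$proj_cutoff)
    }
    assignment <- close_annotation_gaps(assignment)
    verdict <- filter_assignment(assignment, config$min_assigned)
    if (!verdict$keep) {
      discard(id, "annotate", verdict$reason)
      next
    }
    write_assignment(assignment,
                     file.path(out_dir, paste0("assignment_", id, ".tsv")),
                     pdb_id = id)

    logf("model %s", id)
    # modified residues: at most one per peptide, replaced by its most
    # similar natural amino acid (fingerprint Tanimoto); unreplaceable
    # or unparameterised residues discard the complex
    pep_res <- residue_table(filter(s, .data$chain == pep_chain))
    nnaa <- pep_res[!pep_res$res_name %in% AA3, ]
    if (nrow(nnaa) > 1) {
      discard(id, "model", "more than one modified residue in the peptide")
      next
    }
    if (nrow(nnaa) == 1) {
      g <- tryCatch(residue_graph(nnaa$res_name), error = function(e) NULL)
      if (is.null(g)) {
        discard(id, "model", paste0("no chemical graph for modified residue ",
                                    nnaa$res_name))
        next
      }
      mapping <- map_nnaa_to_natural(g, nnaa_name = nnaa$res_name)
      if (!mapping$replaceable) {
        discard(id, "model", sprintf(
          "modified residue %s unreplaceable (best Tanimoto %.2f)",
          nnaa$res_name, mapping$similarity))
        next
      }
      logf("%s: %s -> %s (Tanimoto %.2f)", id, nnaa$res_name,
           mapping$candidate, mapping$similarity)
      s <- mutate_residue(s, pep_chain, nnaa$res_seq, mapping$candidate)
      s <- relax_sidechain(s, pep_chain, nnaa$res_seq)
      # refresh the assignment's residue names after the replacement
      assignment$peptide_map <- residue_table(
        filter(s, .data$chain == pep_chain)) |>
        left_join(select(assignment$peptide_map, "res_seq", "pocket"),
                  by = "res_seq")
    }
    covered <- sum(!is.na(assignment$peptide_map$pocket))
    complex8 <- s
    if (covered < 8) {
      existing <- aa_three_to_one(assignment$peptide_map$res_name)
      target <- rep("A", 8)
      pidx <- pocket_index(assignment$peptide_map$pocket)
      target[pidx[!is.na(pidx)]] <- existing[!is.na(pidx)]
      complex8 <- tryCatch(
        reconstruct_missing(s, assignment, paste(target, collapse = "")),
        subsites_unmodellable = function(e) {
          discard(id, "model", conditionMessage(e))
          NULL
        }
      )
      if (is.null(complex8)) next
      pmap8 <- attr(complex8, "pocket_map")
    } else {
      pmap8 <- assignment$peptide_map[, c("res_seq", "pocket")]
    }

    logf("sample %s", id)
    library <- generate_library(config$library_n, seed = config$seed)
    if (id == names(structures)[1]) {
      write_library(library, file.path(out_dir, "library.txt"))
    }
    threaded <- thread_library(complex8, pep_chain, library)
    model <- energy_model()
    records <- purrr::imap(threaded, function(cx, seq) {
      cfg <- sampler_config(
        n_steps = config$n_steps, kT = config$kT,
        frame_stride = config$frame_stride,
        seed = config$seed + match(seq, names(threaded)),
        p_backbone = config$p_backbone, max_angle = config$max_angle
      )
      traj <- run_sampling(cx, pep_chain, cfg, model)
      observe_trajectory(traj, pmap8, model,
                         n_sphere_points = config$n_sphere_points) |>
        mutate(run = match(seq, names(threaded)))
    })
    records <- bind_rows(records)
    obs <- average_observables(records)
    readr::write_tsv(obs$cell,
                     file.path(out_dir, paste0("observables_", id, ".tsv")))
    readr::write_tsv(obs$position,
                     file.path(out_dir, paste0("positions_", id, ".tsv")))
    results[[id]] <- list(assignment = assignment, observables = obs)
    records_all[[id]] <- records
    profiles[[id]] <- obs$position |>
      mutate(structure = id) |>
      select("structure", "observable", "position", value = "mean")
  }

  entropy <- NULL
  comparison <- NULL
  if (!is.null(specmat) && length(profiles) > 0) {
    logf("entropy + compare")
    entropy <- cleavage_entropy(specmat)
    readr::write_tsv(tidy(entropy), file.path(out_dir, "entropy.tsv"))
    ent_prof <- purrr::map(names(profiles), function(id) {
      tibble(structure = id, position = entropy$position, H = entropy$H)
    }) |> bind_rows()
    comparison <- spearman_per_position(bind_rows(profiles), ent_prof)
    readr::write_tsv(comparison, file.path(out_dir, "spearman.tsv"))
  }

  manifest <- if (length(discards) > 0) bind_rows(discards) else
    tibble(structure = character(0), stage = character(0),
           reason = character(0))
  readr::write_tsv(manifest, file.path(out_dir, "discards.tsv"))
  logf("pipeline end: %d kept, %d discarded", length(results),
       nrow(manifest))

  out <- list(
    results = results, manifest = manifest, entropy = entropy,
    comparison = comparison, out_dir = out_dir, config = config,
    exit_code = if (length(results) == 0) 2L
                else if (nrow(manifest) > 0) 1L else 0L
  )
  class(out) <- "subsites_run"
  out
}

#' @export
print.subsites_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d complex(es) analysed, %d discarded -> %s\n",
              length(x$results), nrow(x$manifest), x$out_dir))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
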