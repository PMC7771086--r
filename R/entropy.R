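# Specificity matrices and cleavage entropy.  A specificity matrix
# holds, for each of the eight substrate positions P4-P4', the
# occurrence fraction n_ij of each of the 20 amino acids among the
# protease's known substrates.  The per-position cleavage entropy is
# the base-20 Shannon entropy
#     H(j) = -sum_i n_ij * log20(n_ij)        (0*log(0) := 0)
# which is 0 for absolute prevalence of one amino acid and 1 for equal
# usage of all 20; the total cleavage entropy is the sum over the eight
# positions and ranges from 0 to 8.

#' Construct a specificity matrix
#'
#' @param mat numeric 20 x 8 matrix; rows named by the 20 standard
#'   1-letter codes, columns by the positions P4-P4' (any order of rows
#'   is accepted and re-sorted; unnamed columns are taken as P4..P4').
#' @param counts_or_fractions `"auto"` (detect by column sums),
#'   `"counts"` or `"fractions"`.
#' @param family_id free-text label (e.g. a MEROPS identifier).
#' @param substrate_count total substrates behind the counts, when
#'   known.
#' @return object of class `subsites_specmat` with the normalised
#'   fraction matrix in `$freq`.
#' @export
specificity_matrix <- function(mat, counts_or_fractions = "auto",
                               family_id = "", substrate_count = NA) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 20 || ncol(mat) != 8) {
    abort(sprintf("specificity matrix must be 20 x 8, got %d x %d",
                  nrow(mat), ncol(mat)))
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("specificity matrix entries must be finite and non-negative")
  }
  rn <- toupper(rownames(mat) %||% AA1[order(AA1)])
  bad <- setdiff(rn, AA1)
  if (length(bad) > 0) {
    abort(paste0("row names must be the 20 standard amino acids; found: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(rn) || length(setdiff(AA1, rn)) > 0) {
    abort("rows must cover each of the 20 amino acids exactly once")
  }
  rownames(mat) <- rn
  mat <- mat[sort(AA1), , drop = FALSE]
  if (is.null(colnames(mat))) colnames(mat) <- P_LABELS
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    abort(paste0("column(s) with zero total: ",
                 paste(colnames(mat)[totals <= 0], collapse = ", ")))
  }
  mode <- match.arg(counts_or_fractions, c("auto", "counts", "fractions"))
  is_fraction <- switch(mode,
    auto = all(abs(totals - 1) < 1e-6),
    counts = FALSE,
    fractions = TRUE
  )
  if (is_fraction && any(abs(totals - 1) > 1e-6)) {
    abort("declared fractions do not sum to 1 per column")
  }
  freq <- sweep(mat, 2, totals, "/")
  out <- list(freq = freq, family_id = family_id,
              substrate_count = substrate_count)
  class(out) <- "subsites_specmat"
  out
}

#' Load a specificity matrix from delimited text
#'
#' Expects rows = amino acids (1-letter codes in the first column) and
#' columns P4, P3, P2, P1, P1', P2', P3', P4'.  Counts are converted to
#' fractions by column totals.
#'
#' @param file path to a tab- or comma-separated table.
#' @param counts_or_fractions see [specificity_matrix()].
#' @param family_id label for the matrix.
#' @return a `subsites_specmat`.
#' @export
load_specificity_matrix <- function(file, counts_or_fractions = "auto",
                                    family_id = "") {
  tab <- readr::read_delim(file, delim = guess_delim(file),
                           show_col_types = FALSE, trim_ws = TRUE)
  if (ncol(tab) != 9) {
    abort(sprintf(
      "expected 9 columns (amino acid + 8 positions), found %d", ncol(tab)))
  }
  aa <- toupper(as.character(tab[[1]]))
  if (any(aa %in% c("B", "Z", "X", "J", "U", "O"))) {
    abort("ambiguous amino-acid letters (B, Z, X, ...) are not accepted")
  }
  mat <- as.matrix(tab[, -1])
  mode(mat) <- "numeric"
  rownames(mat) <- aa
  specificity_matrix(mat, counts_or_fractions, family_id = family_id)
}

#' Write a specificity matrix
#' @param specmat a `subsites_specmat`.
#' @param file output path (TSV).
#' @return the path invisibly.
#' @export
write_specificity_matrix <- function(specmat, file) {
  tab <- as_tibble(specmat$freq, rownames = "aa")
  readr::write_tsv(tab, file)
  invisible(file)
}

#' @export
print.subsites_specmat <- function(x, ...) {
  cat(sprintf("Specificity matrix%s (20 x 8, fractions)\n",
              if (nzchar(x$family_id)) paste0(" [", x$family_id, "]") else ""))
  print(round(x$freq[1:4, ], 3))
  cat("...\n")
  invisible(x)
}

#' Per-position cleavage entropy (base-20)
#'
#' @param column numeric vector of 20 fractions summing to 1.
#' @return entropy in `[0, 1]`.
#' @export
position_entropy <- function(column) {
  if (length(column) != 20) abort("a position column has 20 entries")
  if (any(column < 0)) abort("fractions must be non-negative")
  if (abs(sum(column) - 1) > 1e-6) abort("fractions must sum to 1")
  nz <- column[column > 0]
  -sum(nz * log(nz, base = 20)) + 0  # "+ 0" normalises IEEE negative zero
}

#' Cleavage entropy profile of a specificity matrix
#'
#' Per-position entropies H(j) and their sum, the total cleavage
#' entropy, which ranges between 0 (fully specific at every position)
#' and 8 (fully promiscuous).
#'
#' @param specmat a `subsites_specmat`.
#' @return object of class `subsites_entropy`: tibble with `position`
#'   and `H`, plus attributes `H_cleavage` and `family_id`.
#' @export
cleavage_entropy <- function(specmat) {
  H <- apply(specmat$freq, 2, position_entropy)
  out <- tibble(position = factor(colnames(specmat$freq), levels = P_LABELS),
                H = unname(H))
  attr(out, "H_cleavage") <- sum(H)
  attr(out, "family_id") <- specmat$family_id
  class(out) <- c("subsites_entropy", class(out))
  out
}

#' Total cleavage entropy of an entropy profile
#' @param entropy a `subsites_entropy`.
#' @return scalar in `[0, 8]`.
#' @export
total_cleavage_entropy <- function(entropy) attr(entropy, "H_cleavage")

#' @export
tidy.subsites_entropy <- function(x, ...) {
  tibble(position = x$position, H = x$H)
}

#' @export
glance.subsites_entropy <- function(x, ...) {
  tibble(H_cleavage = attr(x, "H_cleavage"),
         H_min = min(x$H), H_max = max(x$H),
         family_id = attr(x, "family_id") %||% "")
}

#' Average per-position Spearman correlation
#'
#' For each observable and each structure, the Spearman rank
#' correlation between the observable's per-position profile and the
#' entropy profile is computed over the eight positions (average ranks
#' for ties); correlations are then averaged over structures.
#' Structures with a constant profile have undefined correlation and
#' are excluded with a warning.
#'
#' @param observable_profiles tibble with columns `structure`,
#'   `observable`, `position`, `value`.
#' @param entropy_profiles tibble with columns `structure`, `position`,
#'   `H`.
#' @return tibble with `observable`, `rho_mean`, `n_structures`.
#' @export
spearman_per_position <- function(observable_profiles, entropy_profiles) {
  joined <- dplyr::inner_join(
    observable_profiles, entropy_profiles,
    by = c("structure", "position")
  )
  per_structure <- joined |>
    group_by(.data$observable, .data$structure) |>
    summarise(
      rho = if (sd(.data$value) == 0 || sd(.data$H) == 0) NA_real_
            else cor(.data$value, .data$H, method = "spearman"),
      .groups = "drop"
    )
  if (anyNA(per_structure$rho)) {
    dropped <- per_structure |> filter(is.na(.data$rho))
    warn(paste0("undefined correlation (constant profile) dropped for: ",
                paste(unique(dropped$structure), collapse = ", ")))
  }
  per_structure |>
    filter(!is.na(.data$rho)) |>
    group_by(.data$observable) |>
    summarise(rho_mean = mean(.data$rho), n_structures = n(),
              .groups = "drop")
}
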