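#' Weighted endemism of a species
#'
#' The weighted endemism (WE) of a species is the inverse of its range size
#' in grid cells: a species known from a single hexagon scores the maximum
#' value 1, one occupying `k` hexagons scores `1/k`. A cell's WE is the sum
#' of the scores of its species, so every species contributes exactly 1 in
#' total across its range.
#'
#' @param range_size Integer vector of occupied-cell counts (>= 1).
#' @return `1 / range_size`.
#' @export
we_per_species <- function(range_size) {
  stopifnot(all(range_size >= 1), all(range_size == round(range_size)))
  1 / range_size
}

#' Record-count credibility term of the corrected endemism index
#'
#' Maps the number of records of a species onto (0, 1): one record gives
#' 0.00001; 150 or more records give 0.999 (the record-frequency asymptote);
#' counts in between are interpolated linearly.
#'
#' @param n_records Integer vector of record counts (>= 1).
#' @return Numeric vector in `(0, 1)`.
#' @export
#' @examples
#' c_from_records(c(1, 75, 150, 500))
c_from_records <- function(n_records) {
  stopifnot(all(n_records >= 1), all(n_records == round(n_records)))
  lo <- 1e-5; hi <- 0.999
  out <- lo + (pmin(n_records, 150) - 1) * (hi - lo) / 149
  out
}

#' Sampling-effort-corrected weighted endemism
#'
#' Combines three strictly-open-unit-interval quantities into a corrected
#' endemism score:
#' \deqn{\frac{AB}{AB + (1-A)(1-C)}}
#' where `A` is the weighted endemism of the species, `B` the product of the
#' endemism and the species' normalized sampling effort, and `C` the
#' record-count term of [c_from_records()]. The value rises towards 1 when a
#' restricted-range species is both well sampled locally and backed by many
#' records, and falls towards 0 when apparent endemism could be a sampling
#' artefact.
#'
#' @param A Weighted endemism, strictly in (0, 1) (clamp with
#'   [clamp_open()]).
#' @param B Endemism x normalized sampling effort, strictly in (0, 1).
#' @param C Record-count term, strictly in (0, 1).
#' @return Corrected index, strictly in (0, 1).
#' @export
#' @examples
#' corrected_we(0.5, 0.25, 0.5) # 1/3
corrected_we <- function(A, B, C) {
  args <- cbind(A, B, C)
  if (any(args <= 0) || any(args >= 1)) {
    stop("corrected_we(): A, B and C must lie strictly between 0 and 1; clamp inputs first")
  }
  (A * B) / ((A * B) + ((1 - A) * (1 - C)))
}

#' Per-species endemism table
#'
#' Builds the full endemism ledger from cell-assigned occurrences: range
#' size, raw WE, sampling effort, and the corrected index.
#'
#' @param assigned Occurrences with `cell_id` (see [assign_to_cells()]).
#' @param effort Optional output of [sampling_effort()] for the same
#'   occurrence set; computed from `assigned` when missing.
#' @param eps Open-interval clamping margin for the corrected-index inputs.
#' @return Tibble with one row per species: `species_id`, `range_size`,
#'   `n_records`, `we` (= 1/range_size, used in cell sums), `A` (clamped
#'   `we`), `effort`, `B` (= `A * effort`, clamped), `C`, `we_corrected`.
#' @export
endemism_table <- function(assigned, effort = NULL, eps = 1e-5) {
  stopifnot("cell_id" %in% names(assigned))
  if (is.null(effort)) effort <- sampling_effort(assigned, eps = eps)
  ranges <- species_ranges(assigned)
  tab <- ranges |>
    dplyr::count(.data$species_id, name = "range_size") |>
    dplyr::left_join(
      effort[, c("species_id", "n_records", "effort")],
      by = "species_id"
    ) |>
    dplyr::arrange(.data$species_id)
  tab$we <- we_per_species(tab$range_size)
  tab$A <- clamp_open(tab$we, eps)
  tab$B <- clamp_open(tab$A * tab$effort, eps)
  tab$C <- c_from_records(tab$n_records)
  tab$we_corrected <- corrected_we(tab$A, tab$B, tab$C)
  tab
}

#' Per-cell endemism
#'
#' Sums the per-species raw and corrected endemism scores over the species
#' present in each cell. The raw column satisfies the conservation law
#' `sum(cell_we) == number of recorded species`.
#'
#' @param assigned Occurrences with `cell_id`.
#' @param endemism Output of [endemism_table()] (computed if missing).
#' @param grid Optional [hex_grid()] to include empty cells as zeros.
#' @return Tibble `cell_id`, `we`, `we_corrected`.
#' @export
cell_endemism <- function(assigned, endemism = NULL, grid = NULL) {
  if (is.null(endemism)) endemism <- endemism_table(assigned)
  ranges <- species_ranges(assigned)
  out <- ranges |>
    dplyr::left_join(
      endemism[, c("species_id", "we", "we_corrected")],
      by = "species_id"
    ) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      we = sum(.data$we),
      we_corrected = sum(.data$we_corrected),
      .groups = "drop"
    )
  if (!is.null(grid)) {
    out <- dplyr::left_join(grid$cells[, "cell_id"], out, by = "cell_id")
    out$we[is.na(out$we)] <- 0
    out$we_corrected[is.na(out$we_corrected)] <- 0
  }
  dplyr::arrange(tibble::as_tibble(out), .data$cell_id)
}
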