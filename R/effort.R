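#' Per-record sampling effort
#'
#' Local collection density around each record: the number of records of any
#' species within `radius` (50 km by default), divided by the disc area
#' `pi * radius^2`. This is the disc-count kernel used as the sampling-effort
#' estimate that the corrected endemism index consumes.
#'
#' @param occurrences Tibble with `species_id`, `x`, `y`.
#' @param radius Neighbourhood radius in km.
#' @return Input tibble with an `effort_raw` column (records per km2).
#' @export
record_effort <- function(occurrences, radius = 50) {
  stopifnot(nrow(occurrences) >= 1, radius > 0)
  pts <- as_xy_matrix(occurrences)
  n <- nrow(pts)
  counts <- integer(n)
  chunk <- max(1L, floor(5e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(pts[s:e, 1], pts[, 1], "-")^2 +
      outer(pts[s:e, 2], pts[, 2], "-")^2
    counts[s:e] <- rowSums(d2 <= radius^2)
  }
  out <- tibble::as_tibble(occurrences)
  out$effort_raw <- counts / (pi * radius^2)
  out
}

#' Species-level normalized sampling effort
#'
#' For each species the raw efforts of its records are averaged, then all
#' species are normalized by the maximum species-level effort and clamped to
#' the open interval `(eps, 1 - eps)`. The clamping keeps the value strictly
#' inside (0, 1), the domain required by the effort-corrected endemism
#' formula.
#'
#' @inheritParams record_effort
#' @param eps Clamping margin; default `1e-5`.
#' @return Tibble `species_id`, `n_records`, `effort_raw` (mean records/km2
#'   in the 50-km neighbourhoods), `effort` (normalized, in `(eps, 1-eps)`).
#' @export
sampling_effort <- function(occurrences, radius = 50, eps = 1e-5) {
  per_rec <- record_effort(occurrences, radius = radius)
  out <- per_rec |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      effort_raw = mean(.data$effort_raw),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species_id)
  out$effort <- clamp_open(out$effort_raw / max(out$effort_raw), eps)
  out
}

#' Clamp values into an open interval
#'
#' @param x Numeric vector.
#' @param eps Margin.
#' @return `x` clamped into `(eps, 1 - eps)`.
#' @export
clamp_open <- function(x, eps = 1e-5) {
  pmin(1 - eps, pmax(eps, x))
}
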