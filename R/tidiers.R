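#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an SDM fit
#'
#' For GLM fits, the logistic coefficients; for envelope/distance models,
#' the per-axis training summaries.
#'
#' @param x An `sdm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_fit <- function(x, ...) {
  if (x$algorithm == "glm" && !is.null(x$model)) {
    s <- summary(x$model)$coefficients
    return(tibble::tibble(
      term = rownames(s), estimate = s[, 1], std_error = s[, 2],
      statistic = s[, 3], p_value = s[, 4]
    ))
  }
  tibble::tibble(
    term = paste0("axis_", seq_len(4L)),
    note = sprintf("%s training envelope", x$algorithm)
  )
}

#' @rdname tidy.sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, n_train = x$n_train, threshold = x$threshold,
    auc = x$auc, kept = x$keep, range_cells = sum(x$binary)
  )
}

#' Tidy a gap report
#'
#' @param x A `gap_report`.
#' @param ... Unused.
#' @return The `overall` tibble (dimension, pct_inside, pct_outside).
#' @export
tidy.gap_report <- function(x, ...) x$overall

#' @rdname tidy.gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_cells = nrow(x$cells),
    pct_species_outside = x$overall$pct_outside[x$overall$dimension == "species"],
    pct_we_outside = x$overall$pct_outside[x$overall$dimension == "endemism"]
  )
}

#' Tidy a supertree search
#'
#' @param x A `supertree` from [ratchet_search()].
#' @param ... Unused.
#' @return The iteration log (iteration, incumbent score).
#' @export
tidy.supertree <- function(x, ...) x$log

#' @rdname tidy.supertree
#' @export
glance.supertree <- function(x, ...) {
  tibble::tibble(
    n_tips = length(x$tree$tip.label),
    score = x$score,
    iterations = max(x$log$iteration)
  )
}
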