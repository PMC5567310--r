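#' Rank-based AUC with ties credited half
#'
#' @param pos,neg Numeric score vectors for presences and (pseudo-)absences.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

suitability_bioclim <- function(train, cells) {
  # midpoint ECDF: ties count half, so training extremes keep positive
  # suitability while values outside the envelope score exactly 0
  suit <- matrix(NA_real_, nrow(cells), ncol(cells))
  n <- nrow(train)
  for (a in seq_len(ncol(cells))) {
    s <- sort(train[, a])
    le <- findInterval(cells[, a], s)
    lt <- findInterval(cells[, a], s, left.open = TRUE)
    Fa <- (lt + 0.5 * (le - lt)) / n
    suit[, a] <- 1 - 2 * abs(Fa - 0.5)
  }
  apply(suit, 1, min)
}

suitability_domain <- function(train, cells) {
  rng <- apply(train, 2, function(z) diff(range(z)))
  rng[rng <= 0] <- 1e-12
  best <- rep(-Inf, nrow(cells))
  for (i in seq_len(nrow(train))) {
    gower <- 1 - rowMeans(abs(sweep(cells, 2, train[i, ], "-")) /
                            rep(rng, each = nrow(cells)))
    best <- pmax(best, gower)
  }
  pmin(1, pmax(0, best))
}

suitability_mahalanobis <- function(train, cells) {
  mu <- colMeans(train)
  S <- stats::cov(train)
  if (rcond(S) < 1e-12) {
    stop("mahalanobis fit failed: singular training covariance")
  }
  exp(-stats::mahalanobis(cells, mu, S) / 2)
}

suitability_glm <- function(train, absences, cells) {
  df <- as.data.frame(rbind(train, absences))
  names(df) <- paste0("ax", seq_len(ncol(train)))
  df$y <- rep(c(1L, 0L), c(nrow(train), nrow(absences)))
  # separation only yields extreme fitted probabilities, which is harmless
  # for thresholding and rank-based AUC
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  newdf <- as.data.frame(cells)
  names(newdf) <- paste0("ax", seq_len(ncol(cells)))
  list(
    suit = as.numeric(stats::predict(fit, newdata = newdf, type = "response")),
    model = fit
  )
}

#' Draw pseudo-absence cells
#'
#' Uniform random background cells, `factor` per presence, excluding any
#' cell whose centre lies within `exclusion` cell widths of a presence cell
#' centre.
#'
#' @param axes An [env_stack()] (defines the grid).
#' @param presence_cells Integer cell indices of the presences.
#' @param factor Pseudo-absences per presence (default 10).
#' @param exclusion Exclusion radius in cell widths (default 1).
#' @return Integer vector of cell indices (sampled with replacement if the
#'   eligible background is small).
#' @export
draw_pseudo_absences <- function(axes, presence_cells, factor = 10, exclusion = 1) {
  ctr <- env_cell_centers(axes)
  pres <- unique(presence_cells)
  d2min <- rep(Inf, nrow(ctr))
  for (p in pres) {
    d2 <- (ctr[, 1] - ctr[p, 1])^2 + (ctr[, 2] - ctr[p, 2])^2
    d2min <- pmin(d2min, d2)
  }
  eligible <- which(d2min > (exclusion * axes$cellsize)^2)
  n <- factor * length(presence_cells)
  if (length(eligible) == 0) stop("draw_pseudo_absences(): no background cells left")
  sample(eligible, n, replace = length(eligible) < n)
}

#' Fit a species distribution model
#'
#' Fits one of four classic suitability models on environmental principal
#' components and binarizes it at the lowest training-point suitability, so
#' training omission is zero by construction; model adequacy is screened by
#' a pseudo-absence AUC, with `auc > 0.7` the conventional keep rule.
#'
#' Suitability transforms: `bioclim` is the percentile envelope
#' `min_axes(1 - 2|F_a(x) - 0.5|)`; `domain` the best Gower similarity to
#' any training point; `mahalanobis` `exp(-D^2/2)` to the training mean and
#' covariance; `glm` a logistic regression against pseudo-absences.
#'
#' @param presences Tibble with `x`, `y` of the species' records (>= 15).
#' @param axes An [env_stack()] of PCA axes (see [pca_env()]).
#' @param algorithm One of `"bioclim"`, `"domain"`, `"mahalanobis"`, `"glm"`.
#' @param pseudo_absence_cells Optional integer cell indices; drawn with
#'   [draw_pseudo_absences()] when missing.
#' @param seed Seed for the pseudo-absence draw.
#' @param min_presences Minimum usable records (default 15).
#' @return An `sdm_fit`: list with `algorithm`, `suitability` (per cell),
#'   `threshold`, `binary` (logical per cell), `auc`, `keep`
#'   (`auc > 0.7`), `presence_cells`, `pseudo_cells`, `n_train`.
#' @export
fit_sdm <- function(presences, axes, algorithm = c("bioclim", "domain", "mahalanobis", "glm"),
                    pseudo_absence_cells = NULL, seed = 1, min_presences = 15) {
  algorithm <- match.arg(algorithm)
  pcells <- env_locate(axes, presences)
  if (length(pcells) < min_presences) {
    stop(sprintf("too few records to fit an SDM (%d < %d)",
                 length(pcells), min_presences))
  }
  if (is.null(pseudo_absence_cells)) {
    set.seed(seed)
    pseudo_absence_cells <- draw_pseudo_absences(axes, pcells)
  }
  cells <- axes$values
  train <- cells[pcells, , drop = FALSE]
  model <- NULL
  if (algorithm == "glm") {
    g <- suitability_glm(train, cells[pseudo_absence_cells, , drop = FALSE], cells)
    suit <- g$suit
    model <- g$model
  } else {
    suit <- switch(algorithm,
      bioclim = suitability_bioclim(train, cells),
      domain = suitability_domain(train, cells),
      mahalanobis = suitability_mahalanobis(train, cells)
    )
  }
  threshold <- min(suit[pcells])
  binary <- suit >= threshold
  auc <- auc_rank(suit[pcells], suit[pseudo_absence_cells])
  structure(
    list(algorithm = algorithm, suitability = suit, threshold = threshold,
         binary = binary, auc = auc, keep = auc > 0.7,
         presence_cells = pcells, pseudo_cells = pseudo_absence_cells,
         n_train = length(pcells), model = model),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf(
    "<sdm_fit> %s: %d training points, threshold %.4g, AUC %.3f (%s), %d cells in range\n",
    x$algorithm, x$n_train, x$threshold, x$auc,
    if (x$keep) "kept" else "rejected", sum(x$binary)
  ))
  invisible(x)
}

#' Share of a predicted range inside protected areas
#'
#' Percentage of the binary range (restricted to remaining native
#' vegetation) whose cells fall inside PAs. Flagged `NA` when no range cell
#' survives the vegetation mask.
#'
#' @param binary Logical per-cell range mask (or an `sdm_fit`).
#' @param pa_mask Logical per-cell PA membership.
#' @param veg_mask Optional logical per-cell native-vegetation mask
#'   (default: all `TRUE`).
#' @return Percentage in \[0, 100\], or `NA` when undefined.
#' @export
representativeness <- function(binary, pa_mask, veg_mask = NULL) {
  if (inherits(binary, "sdm_fit")) binary <- binary$binary
  if (is.null(veg_mask)) veg_mask <- rep(TRUE, length(binary))
  stopifnot(length(pa_mask) == length(binary), length(veg_mask) == length(binary))
  denom <- sum(binary & veg_mask)
  if (denom == 0) return(NA_real_)
  100 * sum(binary & veg_mask & pa_mask) / denom
}

#' PA membership mask for an environmental grid
#'
#' @param stack An [env_stack()].
#' @param polys List of polygon vertex matrices.
#' @return Logical vector over cells (centre-in-polygon).
#' @export
env_pa_mask <- function(stack, polys) {
  points_in_any(env_cell_centers(stack), polys)
}

#' Fit SDMs for many species and score PA representativeness
#'
#' Per-species, per-algorithm driver: species with fewer than `min_records`
#' usable records are skipped with a logged reason; fits with `auc <= 0.7`
#' are retained in the table but flagged not kept; a failing fit (e.g.
#' singular covariance) skips that species x algorithm only.
#'
#' @param occurrences Tibble `species_id`, `x`, `y`.
#' @param axes [pca_env()] output.
#' @param pa_mask Logical per-cell PA membership (see [env_pa_mask()]).
#' @param veg_mask Optional per-cell native-vegetation mask.
#' @param algorithms Character vector of algorithms to run.
#' @param min_records Minimum records per species (default 15).
#' @param seed Base seed; each species uses `seed` plus its rank.
#' @return Tibble `species_id`, `algorithm`, `n_records`, `auc`,
#'   `threshold`, `pct_inside_pa`, `kept`, `note`.
#' @export
sdm_batch <- function(occurrences, axes, pa_mask, veg_mask = NULL,
                      algorithms = c("bioclim", "domain", "mahalanobis", "glm"),
                      min_records = 15, seed = 1) {
  split_occ <- split(occurrences, occurrences$species_id)
  sp_ids <- sort(names(split_occ))
  rows <- list()
  for (si in seq_along(sp_ids)) {
    sp <- sp_ids[si]
    occ <- split_occ[[sp]]
    if (nrow(occ) < min_records) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species_id = sp, algorithm = NA_character_, n_records = nrow(occ),
        auc = NA_real_, threshold = NA_real_, pct_inside_pa = NA_real_,
        kept = FALSE, note = sprintf("skipped: %d records < %d", nrow(occ), min_records)
      )
      next
    }
    set.seed(seed + si)
    pcells <- env_locate(axes, occ)
    pseudo <- draw_pseudo_absences(axes, pcells)
    for (alg in algorithms) {
      fit <- tryCatch(
        fit_sdm(occ, axes, algorithm = alg,
                pseudo_absence_cells = pseudo, min_presences = min_records),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species_id = sp, algorithm = alg, n_records = nrow(occ),
          auc = NA_real_, threshold = NA_real_, pct_inside_pa = NA_real_,
          kept = FALSE, note = paste("failed:", conditionMessage(fit))
        )
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species_id = sp, algorithm = alg, n_records = nrow(occ),
        auc = fit$auc, threshold = fit$threshold,
        pct_inside_pa = representativeness(fit, pa_mask, veg_mask),
        kept = fit$keep, note = NA_character_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise SDM representativeness by group
#'
#' Medians and quartiles of the percentage of predicted range inside PAs,
#' per algorithm and group, with a Kruskal-Wallis test across groups within
#' each algorithm and pairwise Wilcoxon rank comparisons.
#'
#' @param results [sdm_batch()] output with a `group` column joined on (one
#'   group label per species), or a `groups` lookup supplied separately.
#' @param groups Optional tibble `species_id`, `group`.
#' @return An `sdm_summary`: list with `summary` (tibble: algorithm, group,
#'   n, median, q25, q75), `tests` (tibble: algorithm, H, df, p_value) and
#'   `pairwise` (tibble: algorithm, group1, group2, p_value, Wilcoxon,
#'   Holm-adjusted).
#' @export
sdm_summary <- function(results, groups = NULL) {
  if (!is.null(groups)) {
    results <- dplyr::inner_join(results, groups, by = "species_id")
  }
  stopifnot("group" %in% names(results))
  res <- dplyr::filter(results, .data$kept, !is.na(.data$pct_inside_pa))
  summary <- res |>
    dplyr::group_by(.data$algorithm, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$pct_inside_pa),
      q25 = stats::quantile(.data$pct_inside_pa, 0.25, names = FALSE),
      q75 = stats::quantile(.data$pct_inside_pa, 0.75, names = FALSE),
      .groups = "drop"
    )
  tests <- res |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$group) < 2) {
        return(tibble::tibble(H = NA_real_, df = NA_integer_, p_value = NA_real_))
      }
      if (dplyr::n_distinct(d$pct_inside_pa) == 1) {
        return(tibble::tibble(H = 0, df = as.integer(dplyr::n_distinct(d$group) - 1),
                              p_value = 1))
      }
      kw <- stats::kruskal.test(d$pct_inside_pa, factor(d$group))
      tibble::tibble(
        H = unname(kw$statistic), df = as.integer(kw$parameter),
        p_value = kw$p.value
      )
    }) |>
    dplyr::ungroup()
  pairwise <- res |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::group_modify(function(d, key) {
      gs <- sort(unique(d$group))
      if (length(gs) < 2) return(tibble::tibble())
      combos <- utils::combn(gs, 2)
      ps <- apply(combos, 2, function(gg) {
        stats::wilcox.test(
          d$pct_inside_pa[d$group == gg[1]],
          d$pct_inside_pa[d$group == gg[2]],
          exact = FALSE
        )$p.value
      })
      tibble::tibble(
        group1 = combos[1, ], group2 = combos[2, ],
        p_value = stats::p.adjust(ps, method = "holm")
      )
    }) |>
    dplyr::ungroup()
  structure(list(summary = summary, tests = tests, pairwise = pairwise),
            class = "sdm_summary")
}

#' @export
print.sdm_summary <- function(x, ...) {
  cat("<sdm_summary>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
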