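#' Protection status of points
#'
#' Labels each point with the highest-precedence protected-area category
#' containing it (`strict` > `sustainable` > `indigenous`), or
#' `unprotected`.
#'
#' @param pts Data frame or matrix of `x`, `y` (occurrence records or cell
#'   centroids).
#' @param pas PA tibble with `category` and `geometry` columns.
#' @return Factor with levels strict, sustainable, indigenous, unprotected.
#' @export
classify_protection <- function(pts, pas) {
  pts <- as_xy_matrix(pts)
  lev <- c("strict", "sustainable", "indigenous", "unprotected")
  lab <- rep("unprotected", nrow(pts))
  for (cat in c("indigenous", "sustainable", "strict")) { # ascending precedence
    polys <- pas$geometry[pas$category == cat]
    if (length(polys) == 0) next
    lab[points_in_any(pts, polys)] <- cat
  }
  factor(lab, levels = lev)
}

#' Protection label of every grid cell
#'
#' A cell takes the highest-precedence category of any PA it overlaps (see
#' [cells_overlapping()]), or `unprotected`.
#'
#' @param grid A [hex_grid()].
#' @param pas PA tibble.
#' @return Tibble `cell_id`, `label`.
#' @export
cell_protection <- function(grid, pas) {
  lev <- c("strict", "sustainable", "indigenous", "unprotected")
  lab <- rep("unprotected", nrow(grid$cells))
  for (cat in c("indigenous", "sustainable", "strict")) {
    polys <- pas$geometry[pas$category == cat]
    if (length(polys) == 0) next
    ids <- cells_overlapping(grid, polys)
    lab[match(ids, grid$cells$cell_id)] <- cat
  }
  tibble::tibble(cell_id = grid$cells$cell_id, label = factor(lab, levels = lev))
}

pct <- function(num, den) unname(if (den > 0) 100 * num / den else 0)

#' Protection accounting across the four biodiversity dimensions
#'
#' Partitions species counts (a species is inside if at least one record
#' falls in a PA polygon), weighted-endemism sums, phylogenetic-endemism
#' sums (both cell-valued, partitioned over PA-overlapping vs other cells)
#' and lineage branch length (via [lineage_protection()]) into protected and
#' unprotected shares, overall, per PA category and per biome.
#'
#' @param assigned Occurrences with `cell_id` ([assign_to_cells()]).
#' @param pas PA tibble.
#' @param grid The [hex_grid()] used for assignment.
#' @param tree Optional rooted [ape::phylo] (unit branch lengths for
#'   supertrees); phylogenetic dimensions are skipped when absent.
#' @param biomes Optional biome tibble (`biome_id`, `geometry`).
#' @param endemism Optional [endemism_table()] (computed when missing).
#' @return A `gap_report`: list of tibbles `overall` (dimension,
#'   pct_inside, pct_outside), `by_category` (dimension, category,
#'   pct_of_total), `by_biome`, `species` (species_id, label), `cells`
#'   (cell_id, label, biome_id, n_records, density, we, we_corrected, pwe),
#'   `lineage` ([lineage_protection()] row).
#' @export
protection_proportions <- function(assigned, pas, grid, tree = NULL,
                                   biomes = NULL, endemism = NULL) {
  lev <- c("strict", "sustainable", "indigenous", "unprotected")
  occ_label <- classify_protection(assigned, pas)
  sp_label <- tibble::tibble(species_id = assigned$species_id,
                             label = occ_label) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      label = lev[min(match(.data$label, lev))],
      .groups = "drop"
    )
  sp_label$label <- factor(sp_label$label, levels = lev)
  if (is.null(endemism)) endemism <- endemism_table(assigned)
  ce <- cell_endemism(assigned, endemism, grid = grid)
  cl <- cell_protection(grid, pas)
  counts <- cell_record_counts(assigned, grid)
  cells <- grid$cells[, c("cell_id", "cx", "cy", "area")] |>
    dplyr::left_join(cl, by = "cell_id") |>
    dplyr::left_join(ce, by = "cell_id") |>
    dplyr::left_join(counts, by = "cell_id")
  cells$density <- cells$n_records / cells$area
  if (!is.null(biomes)) {
    bl <- rep(NA_character_, nrow(cells))
    for (b in seq_len(nrow(biomes))) {
      hit <- points_in_poly(cbind(cells$cx, cells$cy), biomes$geometry[[b]])
      bl[is.na(bl) & hit] <- biomes$biome_id[b]
    }
    cells$biome_id <- bl
  } else {
    cells$biome_id <- NA_character_
  }
  ranges <- species_ranges(assigned)
  pw <- if (!is.null(tree)) pwe(tree, ranges) else NULL
  if (!is.null(pw)) {
    cells <- dplyr::left_join(cells, pw$cells, by = "cell_id")
    cells$pwe[is.na(cells$pwe)] <- 0
  } else {
    cells$pwe <- NA_real_
  }
  protected_cells <- cells$cell_id[cells$label != "unprotected"]
  lineage <- if (!is.null(tree)) {
    lineage_protection(tree, ranges, protected_cells)
  } else {
    NULL
  }
  dims <- list(
    species = c(
      inside = sum(sp_label$label != "unprotected"),
      total = nrow(sp_label)
    ),
    endemism = c(
      inside = sum(cells$we[cells$label != "unprotected"]),
      total = sum(cells$we)
    ),
    endemism_corrected = c(
      inside = sum(cells$we_corrected[cells$label != "unprotected"]),
      total = sum(cells$we_corrected)
    )
  )
  if (!is.null(tree)) {
    dims$phylodiversity <- c(
      inside = lineage$protected_length,
      total = lineage$total_length
    )
    dims$phylo_endemism <- c(
      inside = sum(cells$pwe[cells$label != "unprotected"]),
      total = sum(cells$pwe)
    )
  }
  overall <- dplyr::bind_rows(lapply(names(dims), function(d) {
    tibble::tibble(
      dimension = d,
      pct_inside = pct(dims[[d]]["inside"], dims[[d]]["total"]),
      pct_outside = pct(dims[[d]]["total"] - dims[[d]]["inside"], dims[[d]]["total"])
    )
  }))
  by_category <- dplyr::bind_rows(lapply(lev, function(cat) {
    sp <- pct(sum(sp_label$label == cat), nrow(sp_label))
    we <- pct(sum(cells$we[cells$label == cat]), sum(cells$we))
    pe <- if (!is.null(tree)) pct(sum(cells$pwe[cells$label == cat]), sum(cells$pwe)) else NA_real_
    tibble::tibble(
      category = cat,
      dimension = c("species", "endemism", "phylo_endemism"),
      pct_of_total = c(sp, we, pe)
    )
  }))
  by_biome <- NULL
  if (!is.null(biomes)) {
    occ_biome <- rep(NA_character_, nrow(assigned))
    for (b in seq_len(nrow(biomes))) {
      hit <- points_in_poly(assigned, biomes$geometry[[b]])
      occ_biome[is.na(occ_biome) & hit] <- biomes$biome_id[b]
    }
    by_biome <- dplyr::bind_rows(lapply(biomes$biome_id, function(b) {
      in_b <- which(occ_biome == b)
      spb <- tibble::tibble(species_id = assigned$species_id[in_b],
                            protected = occ_label[in_b] != "unprotected") |>
        dplyr::group_by(.data$species_id) |>
        dplyr::summarise(inside = any(.data$protected), .groups = "drop")
      cb <- cells[!is.na(cells$biome_id) & cells$biome_id == b, ]
      tibble::tibble(
        biome_id = b,
        dimension = c("species", "endemism", "phylo_endemism"),
        pct_outside = c(
          pct(sum(!spb$inside), nrow(spb)),
          pct(sum(cb$we[cb$label == "unprotected"]), sum(cb$we)),
          if (!is.null(tree)) pct(sum(cb$pwe[cb$label == "unprotected"]), sum(cb$pwe)) else NA_real_
        )
      )
    }))
  }
  structure(
    list(overall = overall, by_category = by_category, by_biome = by_biome,
         species = sp_label, cells = cells, lineage = lineage),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n")
  print(x$overall)
  invisible(x)
}

#' Per-PA sampling table
#'
#' Record count, record density with its map-legend class, and the 1-km
#' buffer sampled-area fraction for every protected area.
#'
#' @param occurrences Occurrence tibble (`x`, `y`).
#' @param pas PA tibble.
#' @param radius Buffer radius for the sampled fraction, km.
#' @return Tibble `pa_id`, `category`, `year`, `biome_id`, `area`,
#'   `n_records`, `density`, `density_class`, `sampled_fraction`.
#' @export
pa_sampling_table <- function(occurrences, pas, radius = 1) {
  pts <- as_xy_matrix(occurrences)
  dplyr::bind_rows(lapply(seq_len(nrow(pas)), function(i) {
    poly <- pas$geometry[[i]]
    a <- poly_area(poly)
    n <- sum(points_in_poly(pts, poly))
    d <- n / a
    tibble::tibble(
      pa_id = pas$id[i], category = pas$category[i], year = pas$year[i],
      biome_id = pas$biome_id[i], area = a, n_records = n, density = d,
      density_class = density_class(d),
      sampled_fraction = sampled_area_fraction(occurrences, poly, radius = radius)
    )
  }))
}

#' Rank tests of record density and endemism inside vs outside PAs
#'
#' Kruskal-Wallis tests on per-cell record density (hexagonal cells as
#' sampling units) inside vs outside PAs, overall and per biome, plus a
#' Mann-Whitney test on cell weighted endemism inside vs outside.
#'
#' @param cells The `cells` tibble of a [protection_proportions()] report.
#' @return Tibble `scope`, `test`, `statistic`, `p_value`, `method`.
#' @export
inside_outside_tests <- function(cells) {
  protected <- cells$label != "unprotected"
  one_kw <- function(x, g, scope, test) {
    if (length(unique(g)) < 2 || min(table(g)) < 2) {
      return(tibble::tibble(scope = scope, test = test, statistic = NA_real_,
                            p_value = NA_real_, method = "not enough cells"))
    }
    if (length(unique(x)) == 1) { # identical samples: no rank signal at all
      return(tibble::tibble(scope = scope, test = test, statistic = 0,
                            p_value = 1, method = "Kruskal-Wallis rank sum test"))
    }
    kw <- stats::kruskal.test(x, factor(g))
    tibble::tibble(scope = scope, test = test,
                   statistic = unname(kw$statistic), p_value = kw$p.value,
                   method = kw$method)
  }
  out <- list(one_kw(cells$density, protected, "all", "density_kw"))
  if (!all(is.na(cells$biome_id))) {
    for (b in sort(unique(stats::na.omit(cells$biome_id)))) {
      sel <- !is.na(cells$biome_id) & cells$biome_id == b
      out[[length(out) + 1L]] <-
        one_kw(cells$density[sel], protected[sel], b, "density_kw")
    }
  }
  if (sum(protected) >= 2 && sum(!protected) >= 2) {
    mw <- stats::wilcox.test(cells$we[protected], cells$we[!protected],
                             exact = FALSE)
    out[[length(out) + 1L]] <- tibble::tibble(
      scope = "all", test = "we_mw", statistic = unname(mw$statistic),
      p_value = mw$p.value, method = mw$method
    )
  }
  dplyr::bind_rows(out)
}

default_epochs <- function() {
  list(c(1903, 1950), c(1951, 1980), c(1981, 1990), c(1991, 2000), c(2001, 2016))
}

#' Accumulation of biodiversity protection through time
#'
#' Adds PAs in order of designation year and tracks the cumulative share of
#' the four dimensions protected: species (first record inside any
#' designated PA), weighted-endemism and phylogenetic-endemism cell sums,
#' and lineage branch length. Per-epoch slopes come from a linear fit on
#' normalized axes (year rescaled to the epoch span, value as a fraction of
#' the all-PA endpoint) and are reported in degrees.
#'
#' @param assigned Occurrences with `cell_id`.
#' @param pas PA tibble with designation `year` for every PA.
#' @param grid The [hex_grid()].
#' @param tree Optional rooted [ape::phylo].
#' @param endemism Optional [endemism_table()].
#' @param epochs List of `c(start, end)` year pairs.
#' @return List with `series` (tibble `year`, `dimension`, `cumulative`,
#'   `pct_of_final`) and `slopes` (tibble `epoch_start`, `epoch_end`,
#'   `dimension`, `slope_degrees`).
#' @export
accumulation_curves <- function(assigned, pas, grid, tree = NULL,
                                endemism = NULL, epochs = default_epochs()) {
  if (any(is.na(pas$year))) stop("accumulation_curves(): every PA needs a designation year")
  years <- seq(min(vapply(epochs, `[`, numeric(1), 1)),
               max(vapply(epochs, `[`, numeric(1), 2)))
  # first-protection year of each record
  pts <- as_xy_matrix(assigned)
  rec_year <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(pas))) {
    hit <- points_in_poly(pts, pas$geometry[[i]])
    rec_year[hit] <- pmin(rec_year[hit], pas$year[i])
  }
  sp_year <- tapply(rec_year, assigned$species_id, min)
  # first-protection year of each cell
  cell_year <- rep(Inf, nrow(grid$cells))
  for (i in seq_len(nrow(pas))) {
    ids <- cells_overlapping(grid, pas$geometry[i])
    k <- match(ids, grid$cells$cell_id)
    cell_year[k] <- pmin(cell_year[k], pas$year[i])
  }
  if (is.null(endemism)) endemism <- endemism_table(assigned)
  ce <- cell_endemism(assigned, endemism, grid = grid)
  ce_year <- cell_year[match(ce$cell_id, grid$cells$cell_id)]
  dims <- list(
    species = list(vals = rep(1, length(sp_year)), yr = as.numeric(sp_year)),
    endemism = list(vals = ce$we, yr = ce_year)
  )
  if (!is.null(tree)) {
    ranges <- species_ranges(assigned)
    pw <- pwe(tree, ranges)
    br_year <- vapply(pw$branch_cells, function(cs) {
      if (length(cs) == 0) return(Inf)
      min(cell_year[match(cs, grid$cells$cell_id)])
    }, numeric(1))
    recorded <- pw$branches$n_cells > 0
    dims$phylodiversity <- list(vals = pw$branches$length[recorded],
                                yr = br_year[recorded])
    dims$phylo_endemism <- list(vals = pw$cells$pwe,
                                yr = cell_year[match(pw$cells$cell_id, grid$cells$cell_id)])
  }
  series <- dplyr::bind_rows(lapply(names(dims), function(d) {
    vals <- dims[[d]]$vals; yr <- dims[[d]]$yr
    final <- sum(vals[is.finite(yr)])
    cum <- vapply(years, function(t) sum(vals[yr <= t]), numeric(1))
    tibble::tibble(
      year = years, dimension = d, cumulative = cum,
      pct_of_final = if (final > 0) 100 * cum / final else 0
    )
  }))
  slopes <- dplyr::bind_rows(lapply(epochs, function(ep) {
    dplyr::bind_rows(lapply(names(dims), function(d) {
      s <- series[series$dimension == d &
                    series$year >= ep[1] & series$year <= ep[2], ]
      xx <- (s$year - ep[1]) / (ep[2] - ep[1])
      yy <- s$pct_of_final / 100
      beta <- unname(stats::coef(stats::lm(yy ~ xx))[2])
      tibble::tibble(epoch_start = ep[1], epoch_end = ep[2], dimension = d,
                     slope_degrees = atan(beta) * 180 / pi)
    }))
  }))
  list(series = series, slopes = slopes)
}

#' Run the full gap-analysis pipeline
#'
#' Generates (or accepts) a synthetic world, grids the occurrences, builds
#' effort-corrected endemism and phylogenetic indices, partitions protection
#' by category and biome, tests densities inside vs outside PAs, accumulates
#' protection through time, and (optionally) fits distribution models to
#' score range representativeness. Deterministic for a fixed configuration
#' seed; a species whose SDM fails does not affect the occurrence-based
#' accounting.
#'
#' @param config A [world_config()] or an already-generated `world`.
#' @param include_sdm Fit SDMs for species with enough records?
#' @param sdm_min_records Minimum records per modelled species.
#' @param out_dir Optional directory to write `report.json` and CSV tables.
#' @return A `gap_pipeline` list: `world`, `grid`, `endemism`, `report`
#'   ([protection_proportions()]), `pa_table`, `tests`, `accumulation`,
#'   `sdm` (batch results + summary or `NULL`), `report_json` (the exact
#'   serialized report text).
#' @export
run_pipeline <- function(config, include_sdm = TRUE, sdm_min_records = 15,
                         out_dir = NULL) {
  world <- if (inherits(config, "world")) config else generate_world(config)
  grid <- hex_grid(world$config$extent, world$config$hex_diameter)
  assigned <- assign_to_cells(world$occurrences, grid)
  effort <- sampling_effort(assigned)
  endem <- endemism_table(assigned, effort = effort)
  report <- protection_proportions(assigned, world$pas, grid, tree = world$tree,
                                   biomes = world$biomes, endemism = endem)
  pa_table <- pa_sampling_table(world$occurrences, world$pas)
  tests <- inside_outside_tests(report$cells)
  acc <- accumulation_curves(assigned, world$pas, grid, tree = world$tree,
                             endemism = endem)
  sdm <- NULL
  if (include_sdm) {
    axes <- pca_env(world$env)
    pa_mask <- env_pa_mask(axes, world$pas$geometry)
    batch <- sdm_batch(world$occurrences, axes, pa_mask,
                       min_records = sdm_min_records,
                       seed = world$config$seed)
    groups <- world$truth$species[, c("species_id", "group")]
    summ <- if (any(batch$kept)) sdm_summary(batch, groups = groups) else NULL
    sdm <- list(results = batch, summary = summ)
  }
  out <- structure(
    list(world = world, grid = grid, endemism = endem, report = report,
         pa_table = pa_table, tests = tests, accumulation = acc, sdm = sdm),
    class = "gap_pipeline"
  )
  out$report_json <- report_json(out)
  if (!is.null(out_dir)) write_gap_report(out, out_dir)
  out
}

#' @export
print.gap_pipeline <- function(x, ...) {
  cat("<gap_pipeline>\n")
  print(x$report$overall)
  invisible(x)
}

report_json <- function(pipeline) {
  rep_ <- pipeline$report
  payload <- list(
    seed = pipeline$world$config$seed,
    n_species = nrow(pipeline$world$truth$species),
    n_records = nrow(pipeline$world$occurrences),
    n_cells = nrow(pipeline$grid$cells),
    overall = rep_$overall,
    by_category = rep_$by_category,
    by_biome = rep_$by_biome,
    lineage = rep_$lineage,
    tests = pipeline$tests,
    slopes = pipeline$accumulation$slopes,
    sdm_summary = if (!is.null(pipeline$sdm$summary)) pipeline$sdm$summary$summary else NULL
  )
  jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                   digits = NA, na = "null")
}

#' Write pipeline outputs
#'
#' Writes `report.json` plus CSV tables (`endemism.csv`,
#' `cell_endemism.csv`, `pa_table.csv`, `accumulation.csv`,
#' `sdm_results.csv` when present).
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gap_report <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(pipeline$report_json, file.path(dir, "report.json"))
  readr::write_csv(pipeline$endemism, file.path(dir, "endemism.csv"))
  readr::write_csv(
    pipeline$report$cells[, c("cell_id", "label", "biome_id", "n_records",
                              "density", "we", "we_corrected", "pwe")],
    file.path(dir, "cell_endemism.csv")
  )
  readr::write_csv(pipeline$pa_table, file.path(dir, "pa_table.csv"))
  readr::write_csv(pipeline$accumulation$series, file.path(dir, "accumulation.csv"))
  if (!is.null(pipeline$sdm)) {
    readr::write_csv(pipeline$sdm$results, file.path(dir, "sdm_results.csv"))
  }
  invisible(dir)
}
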