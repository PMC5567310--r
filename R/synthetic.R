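#' Configuration of a synthetic landscape
#'
#' Defines the study conditions the generator emulates: a planar extent in
#' km; biome strips; three protected-area categories with designation years
#' spanning 1903-2016 (most designated after 2000); species with
#' heavy-tailed record counts (minimum 1, most species under 15 records,
#' a few above 150); spatially clustered sampling effort (Gaussian hotspots
#' over a uniform floor); and 21 spatially autocorrelated environmental
#' layers (19 "bioclimatic" plus 2 "topographic" surrogates).
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`, km.
#' @param n_biomes Number of biome strips (default 6).
#' @param n_pas_per_category Named integer vector: PAs per category
#'   (`strict`, `sustainable`, `indigenous`).
#' @param pa_year_range Designation-year range.
#' @param prop_recent_pas Share of PAs designated from 2001 on (only used
#'   when `pa_year_range` is the default 1903-2016).
#' @param n_species Number of species.
#' @param records_meanlog,records_sdlog Log-normal law of per-species record
#'   counts (rounded, clamped at 1).
#' @param range_radius_meanlog,range_radius_sdlog Log-normal law of range
#'   kernel radii, km (clamped to \[15, 250\]).
#' @param max_range_centers Max kernels per species range (1 to this many).
#' @param effort_hotspots Number of sampling-effort hotspots (0 = uniform
#'   effort).
#' @param hotspot_sd Hotspot Gaussian SD, km.
#' @param hotspot_floor Uniform effort floor relative to a hotspot peak.
#' @param pa_radius_range PA circumradius range, km.
#' @param hex_diameter Hexagon diameter used downstream, km.
#' @param env_nx,env_ny Environmental grid dimensions.
#' @param n_env Number of environmental layers.
#' @param seed RNG seed; fixed seed gives byte-identical worlds.
#' @return A `world_config` list.
#' @export
world_config <- function(extent = c(0, 1000, 0, 1000),
                         n_biomes = 6,
                         n_pas_per_category = c(strict = 8, sustainable = 8, indigenous = 8),
                         pa_year_range = c(1903, 2016),
                         prop_recent_pas = 0.8,
                         n_species = 150,
                         records_meanlog = log(8), records_sdlog = 1.3,
                         range_radius_meanlog = log(60), range_radius_sdlog = 0.5,
                         max_range_centers = 3,
                         effort_hotspots = 5, hotspot_sd = 80, hotspot_floor = 0.2,
                         pa_radius_range = c(30, 110),
                         hex_diameter = 55,
                         env_nx = 80, env_ny = 80, n_env = 21,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
    n_biomes >= 1, n_species >= 1, all(n_pas_per_category >= 1),
    max_range_centers >= 1, effort_hotspots >= 0,
    pa_year_range[2] >= pa_year_range[1], hex_diameter > 0, n_env >= 1
  )
  if (is.null(names(cfg$n_pas_per_category))) {
    names(cfg$n_pas_per_category) <- c("strict", "sustainable", "indigenous")
  }
  structure(cfg, class = "world_config")
}

world_area <- function(extent) (extent[2] - extent[1]) * (extent[4] - extent[3])

# vertical biome strips with jittered widths
gen_biomes <- function(config) {
  k <- config$n_biomes
  ext <- config$extent
  w <- stats::runif(k, 0.6, 1.4)
  breaks <- ext[1] + cumsum(c(0, w)) / sum(w) * (ext[2] - ext[1])
  tibble::tibble(
    biome_id = sprintf("biome_%d", seq_len(k)),
    geometry = lapply(seq_len(k), function(i) {
      cbind(c(breaks[i], breaks[i + 1], breaks[i + 1], breaks[i]),
            c(ext[3], ext[3], ext[4], ext[4]))
    })
  )
}

gen_pa_year <- function(n, config) {
  yr <- config$pa_year_range
  if (identical(as.numeric(yr), c(1903, 2016))) {
    recent <- stats::runif(n) < config$prop_recent_pas
    ifelse(recent,
           sample(2001:2016, n, replace = TRUE),
           sample(1903:2000, n, replace = TRUE))
  } else {
    sample(seq(yr[1], yr[2]), n, replace = TRUE)
  }
}

gen_pas <- function(config, biomes) {
  ext <- config$extent
  npa <- config$n_pas_per_category
  total <- sum(npa)
  # PAs may overlap, but refuse layouts whose combined footprint dwarfs the
  # extent (radii capped at the extent half-width: giant PAs just clip)
  r_eff <- min(min(config$pa_radius_range),
               (ext[2] - ext[1]) / 2, (ext[4] - ext[3]) / 2)
  if (total * pi * r_eff^2 > 5 * world_area(ext)) {
    stop("generate_world(): infeasible geometry - too many protected areas for the extent")
  }
  cats <- rep(names(npa), npa)
  n <- length(cats)
  geoms <- vector("list", n)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      r <- stats::runif(1, config$pa_radius_range[1], config$pa_radius_range[2])
      cx <- stats::runif(1, ext[1], ext[2])
      cy <- stats::runif(1, ext[3], ext[4])
      poly <- clip_poly_rect(
        regular_poly(cx, cy, r, n = 12L, rot = stats::runif(1, 0, pi / 6)), ext
      )
      if (nrow(poly) >= 3 &&
          poly_area(poly) > 0.2 * min(pi * r^2, world_area(ext))) break
    }
    geoms[[i]] <- poly
    centers[i, ] <- c(cx, cy)
  }
  biome_of <- function(pts) {
    lab <- rep(NA_character_, nrow(pts))
    for (b in seq_len(nrow(biomes))) {
      hit <- points_in_poly(pts, biomes$geometry[[b]])
      lab[is.na(lab) & hit] <- biomes$biome_id[b]
    }
    lab
  }
  tibble::tibble(
    id = sprintf("pa_%02d", seq_len(n)),
    category = cats,
    year = as.integer(gen_pa_year(n, config)),
    biome_id = biome_of(centers),
    geometry = geoms
  )
}

# analytic sampling-effort field: Gaussian hotspots over a uniform floor
effort_field <- function(config) {
  ext <- config$extent
  k <- config$effort_hotspots
  centers <- if (k > 0) {
    cbind(stats::runif(k, ext[1], ext[2]), stats::runif(k, ext[3], ext[4]))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  floor_ <- config$hotspot_floor
  sd_ <- config$hotspot_sd
  list(
    centers = centers,
    value = function(pts) {
      pts <- as_xy_matrix(pts)
      v <- rep(floor_, nrow(pts))
      if (nrow(centers) > 0) {
        for (i in seq_len(nrow(centers))) {
          d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2
          v <- v + exp(-d2 / (2 * sd_^2))
        }
      }
      v
    },
    max = floor_ + max(1L, nrow(centers)) * 1.0
  )
}

#' Per-species record-count law of the generator
#'
#' Rounded log-normal clamped at 1: most species get fewer than 15 records,
#' a small share more than 150. Exposed so tests can compare sampled counts
#' against the generating law directly.
#'
#' @param n Number of draws.
#' @param config A [world_config()].
#' @return Integer vector of record counts (>= 1).
#' @export
rrecord_counts <- function(n, config) {
  pmax(1L, as.integer(round(stats::rlnorm(n, config$records_meanlog,
                                          config$records_sdlog))))
}

# uniform draw from (union of discs) intersected with the extent
draw_in_range <- function(n, centers, radius, extent) {
  bb <- c(
    max(extent[1], min(centers[, 1]) - radius),
    min(extent[2], max(centers[, 1]) + radius),
    max(extent[3], min(centers[, 2]) - radius),
    min(extent[4], max(centers[, 2]) + radius)
  )
  out <- matrix(numeric(0), ncol = 2)
  guard <- 0L
  while (nrow(out) < n && guard < 200L) {
    guard <- guard + 1L
    m <- max(50L, 4L * (n - nrow(out)))
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    ok <- rep(FALSE, m)
    for (i in seq_len(nrow(centers))) {
      ok <- ok | ((cand[, 1] - centers[i, 1])^2 +
                    (cand[, 2] - centers[i, 2])^2 <= radius^2)
    }
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  if (nrow(out) < n) stop("draw_in_range(): range does not intersect the extent")
  out[seq_len(n), , drop = FALSE]
}

# effort-biased thinning: accept with probability effort/max_effort; if the
# budget of candidate draws is exhausted the remaining records are taken
# unthinned so every species keeps its configured count
sample_species_records <- function(n, centers, radius, extent, eff) {
  kept <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(kept) < n && tries < 60L) {
    tries <- tries + 1L
    cand <- draw_in_range(max(20L, 3L * (n - nrow(kept))), centers, radius, extent)
    acc <- stats::runif(nrow(cand)) < eff$value(cand) / eff$max
    kept <- rbind(kept, cand[acc, , drop = FALSE])
  }
  if (nrow(kept) < n) {
    kept <- rbind(kept, draw_in_range(n - nrow(kept), centers, radius, extent))
  }
  kept[seq_len(n), , drop = FALSE]
}

smooth_noise <- function(nx, ny, sigma_cells = 3) {
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  k <- stats::dnorm(seq(-3 * sigma_cells, 3 * sigma_cells), sd = sigma_cells)
  k <- k / sum(k)
  z <- t(apply(z, 1, function(row) stats::filter(c(rev(row), row, rev(row)), k,
                                                 sides = 2)[(nx + 1):(2 * nx)]))
  z <- apply(z, 2, function(col) stats::filter(c(rev(col), col, rev(col)), k,
                                               sides = 2)[(ny + 1):(2 * ny)])
  (z - mean(z)) / stats::sd(z)
}

gen_env <- function(config, eff) {
  ext <- config$extent
  nx <- config$env_nx; ny <- config$env_ny
  cellsize <- (ext[2] - ext[1]) / nx
  stk <- env_stack(matrix(0, nx * ny, config$n_env), nx, ny, ext[1], ext[3], cellsize)
  ctr <- env_cell_centers(stk)
  X <- (ctr[, 1] - ext[1]) / (ext[2] - ext[1])
  Y <- (ctr[, 2] - ext[3]) / (ext[4] - ext[3])
  vals <- sapply(seq_len(config$n_env), function(k) {
    w <- stats::rnorm(2)
    noise <- as.numeric(t(smooth_noise(nx, ny)))  # row-major from bottom
    w[1] * X + w[2] * Y + 0.8 * noise
  })
  colnames(vals) <- c(sprintf("bio_%02d", seq_len(min(19, config$n_env))),
                      sprintf("topo_%02d", seq_len(max(0, config$n_env - 19))))
  out <- env_stack(vals, nx, ny, ext[1], ext[3], cellsize)
  attr(out, "effort") <- matrix(eff$value(ctr), ny, nx, byrow = TRUE)
  out
}

species_truth <- function(sp_ids, centers_list, radii, pas, extent) {
  frac <- vapply(seq_along(sp_ids), function(i) {
    ctrs <- centers_list[[i]]; r <- radii[i]
    step <- r / 8
    bb <- c(max(extent[1], min(ctrs[, 1]) - r), min(extent[2], max(ctrs[, 1]) + r),
            max(extent[3], min(ctrs[, 2]) - r), min(extent[4], max(ctrs[, 2]) + r))
    gx <- seq(bb[1] + step / 2, bb[2], by = step)
    gy <- seq(bb[3] + step / 2, bb[4], by = step)
    pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    inr <- rep(FALSE, nrow(pts))
    for (j in seq_len(nrow(ctrs))) {
      inr <- inr | ((pts[, 1] - ctrs[j, 1])^2 + (pts[, 2] - ctrs[j, 2])^2 <= r^2)
    }
    pts <- pts[inr, , drop = FALSE]
    if (nrow(pts) == 0) return(0)
    mean(points_in_any(pts, pas$geometry))
  }, numeric(1))
  tibble::tibble(
    species_id = sp_ids,
    range_radius = radii,
    n_centers = vapply(centers_list, nrow, integer(1)),
    frac_inside_pa = frac
  )
}

#' Generate a synthetic landscape with known ground truth
#'
#' Draws biomes, protected areas, an effort field, environmental layers, a
#' species phylogeny and effort-thinned occurrence records, all reproducible
#' from the configuration seed. Every record lies inside its species' true
#' range (a union of discs clipped to the extent), and the returned truth
#' table carries each species' true fraction of range inside PAs.
#'
#' @param config A [world_config()].
#' @return A `world`: list with `config`, `occurrences`, `pas`, `biomes`,
#'   `env` ([env_stack()], with the effort raster as attribute `effort`),
#'   `tree` (unit-branch-length [ape::phylo]) and `truth` (list:
#'   `species` tibble, `range_centers`, `effort_centers`).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  ext <- config$extent
  biomes <- gen_biomes(config)
  pas <- gen_pas(config, biomes)
  eff <- effort_field(config)
  n_sp <- config$n_species
  sp_ids <- sprintf("sp_%03d", seq_len(n_sp))
  radii <- pmin(250, pmax(15, stats::rlnorm(n_sp, config$range_radius_meanlog,
                                            config$range_radius_sdlog)))
  centers_list <- lapply(seq_len(n_sp), function(i) {
    k <- sample.int(config$max_range_centers, 1)
    c1 <- c(stats::runif(1, ext[1], ext[2]), stats::runif(1, ext[3], ext[4]))
    ctrs <- matrix(rep(c1, k), ncol = 2, byrow = TRUE)
    if (k > 1) {
      ctrs[-1, 1] <- pmin(ext[2], pmax(ext[1], c1[1] + stats::rnorm(k - 1, sd = 0.8 * radii[i])))
      ctrs[-1, 2] <- pmin(ext[4], pmax(ext[3], c1[2] + stats::rnorm(k - 1, sd = 0.8 * radii[i])))
    }
    ctrs
  })
  counts <- rrecord_counts(n_sp, config)
  occ <- lapply(seq_len(n_sp), function(i) {
    xy <- sample_species_records(counts[i], centers_list[[i]], radii[i], ext, eff)
    tibble::tibble(species_id = sp_ids[i], x = xy[, 1], y = xy[, 2],
                   year = sample(1950:2014, counts[i], replace = TRUE))
  })
  occurrences <- dplyr::bind_rows(occ)
  tree <- unit_branch_lengths(ape::rtree(n_sp, tip.label = sp_ids))
  env <- gen_env(config, eff)
  truth_sp <- species_truth(sp_ids, centers_list, radii, pas, ext)
  truth_sp$n_records <- counts
  truth_sp$group <- sample(c("angiosperm", "arthropod", "vertebrate"),
                           n_sp, replace = TRUE)
  structure(
    list(config = config, occurrences = occurrences, pas = pas,
         biomes = biomes, env = env, tree = tree,
         truth = list(species = truth_sp, range_centers = centers_list,
                      effort_centers = eff$centers)),
    class = "world"
  )
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf(
    "<world> %d species, %d records, %d PAs, %d biomes, %d env layers (seed %d)\n",
    nrow(x$truth$species), nrow(x$occurrences), nrow(x$pas), nrow(x$biomes),
    ncol(x$env$values), x$config$seed
  ))
  invisible(x)
}

#' Synthetic world with a known fraction of species outside PAs
#'
#' Calibration scenario: a target share of species get ranges wholly
#' disjoint from every PA (their records can therefore never fall inside
#' one), while the remaining species have their range centre placed inside
#' a PA and their first record pinned at that centre, so record-based
#' protection accounting recovers the generator truth exactly up to the
#' rounding of `target * n_species`.
#'
#' @param config A [world_config()].
#' @param target_outside_fraction Target share of species with no PA overlap,
#'   strictly in (0, 1).
#' @return A `world` whose `truth$species` has an `outside` logical column;
#'   `truth$n_outside` gives the realized count.
#' @export
scenario_gap <- function(config, target_outside_fraction) {
  stopifnot(inherits(config, "world_config"),
            target_outside_fraction > 0, target_outside_fraction < 1)
  set.seed(config$seed)
  ext <- config$extent
  biomes <- gen_biomes(config)
  pas <- gen_pas(config, biomes)
  eff <- effort_field(config)
  n_sp <- config$n_species
  n_out <- round(target_outside_fraction * n_sp)
  sp_ids <- sprintf("sp_%03d", seq_len(n_sp))
  outside <- seq_len(n_sp) <= n_out
  radii <- pmin(120, pmax(15, stats::rlnorm(n_sp, config$range_radius_meanlog,
                                            config$range_radius_sdlog)))
  centers_list <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    if (outside[i]) {
      placed <- FALSE
      r <- radii[i]
      for (attempt in 1:4) {
        for (try in 1:300) {
          c1 <- c(stats::runif(1, ext[1], ext[2]), stats::runif(1, ext[3], ext[4]))
          dmin <- min(vapply(pas$geometry, function(p) {
            dist_to_poly(matrix(c1, ncol = 2), p)
          }, numeric(1)))
          if (dmin > r + 2) { placed <- TRUE; break }
        }
        if (placed) break
        r <- r / 2
      }
      if (!placed) {
        stop(sprintf(
          "scenario_gap(): could not place species %s outside all PAs; the PA layout leaves no room (target %.2f unreachable)",
          sp_ids[i], target_outside_fraction
        ))
      }
      radii[i] <- r
      centers_list[[i]] <- matrix(c1, ncol = 2)
    } else {
      pa <- pas$geometry[[1 + (i %% nrow(pas))]]
      bb <- c(range(pa[, 1]), range(pa[, 2]))
      repeat {
        c1 <- c(stats::runif(1, bb[1], bb[2]), stats::runif(1, bb[3], bb[4]))
        if (points_in_poly(matrix(c1, ncol = 2), pa)) break
      }
      centers_list[[i]] <- matrix(c1, ncol = 2)
    }
  }
  counts <- rrecord_counts(n_sp, config)
  occ <- lapply(seq_len(n_sp), function(i) {
    xy <- sample_species_records(counts[i], centers_list[[i]], radii[i], ext, eff)
    if (!outside[i]) xy[1, ] <- centers_list[[i]][1, ]  # anchor record inside the PA
    tibble::tibble(species_id = sp_ids[i], x = xy[, 1], y = xy[, 2],
                   year = sample(1950:2014, counts[i], replace = TRUE))
  })
  occurrences <- dplyr::bind_rows(occ)
  tree <- unit_branch_lengths(ape::rtree(n_sp, tip.label = sp_ids))
  env <- gen_env(config, eff)
  truth_sp <- species_truth(sp_ids, centers_list, radii, pas, ext)
  truth_sp$n_records <- counts
  truth_sp$outside <- outside
  truth_sp$group <- sample(c("angiosperm", "arthropod", "vertebrate"),
                           n_sp, replace = TRUE)
  structure(
    list(config = config, occurrences = occurrences, pas = pas,
         biomes = biomes, env = env, tree = tree,
         truth = list(species = truth_sp, range_centers = centers_list,
                      effort_centers = eff$centers, n_outside = n_out)),
    class = "world"
  )
}

#' Engineered world with a fixed PA share of every species range
#'
#' Builds a landscape whose environmental layers vary along x only (plus
#' independent cell noise), species ranges are x-bands, and the single PA is
#' a horizontal strip covering `pa_fraction` of the extent's height. Any
#' y-invariant predicted range then has exactly `pa_fraction` of its area
#' inside the PA, making the geometric truth of the representativeness
#' statistic known by construction.
#'
#' @param pa_fraction Share of every range inside the PA (default 0.3).
#' @param n_species,n_presences Species count and records per species.
#' @param env_nx,env_ny,n_env Environmental grid and layer counts.
#' @param noise_sd SD of the iid cell noise added to each layer.
#' @param seed RNG seed.
#' @return List with `occurrences`, `env`, `pas`, `truth` (tibble
#'   `species_id`, `pct_inside_pa`).
#' @export
scenario_representativeness <- function(pa_fraction = 0.3, n_species = 20,
                                        n_presences = 80, env_nx = 100,
                                        env_ny = 100, n_env = 21,
                                        noise_sd = 0.03, seed = 1) {
  stopifnot(pa_fraction > 0, pa_fraction < 1)
  set.seed(seed)
  ext <- c(0, 1000, 0, 1000)
  cellsize <- (ext[2] - ext[1]) / env_nx
  stk0 <- env_stack(matrix(0, env_nx * env_ny, 1), env_nx, env_ny,
                    ext[1], ext[3], cellsize)
  ctr <- env_cell_centers(stk0)
  X <- (ctr[, 1] - ext[1]) / (ext[2] - ext[1])
  vals <- sapply(seq_len(n_env), function(k) {
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    a * X + b * X^2 + noise_sd * stats::rnorm(length(X))
  })
  env <- env_stack(vals, env_nx, env_ny, ext[1], ext[3], cellsize)
  # PA strip aligned to whole cell rows so the covered share is exact
  strip_rows <- round(pa_fraction * env_ny)
  y_top <- ext[3] + strip_rows * cellsize
  pas <- tibble::tibble(
    id = "pa_01", category = "strict", year = 1990L, biome_id = "biome_1",
    geometry = list(cbind(c(ext[1], ext[2], ext[2], ext[1]),
                          c(ext[3], ext[3], y_top, y_top)))
  )
  x0 <- numeric(n_species); x1 <- numeric(n_species)
  occ <- lapply(seq_len(n_species), function(i) {
    width <- stats::runif(1, 0.25, 0.35) * (ext[2] - ext[1])
    lo <- stats::runif(1, ext[1], ext[2] - width)
    x0[i] <<- lo; x1[i] <<- lo + width
    tibble::tibble(
      species_id = sprintf("sp_%03d", i),
      x = stats::runif(n_presences, lo, lo + width),
      y = stats::runif(n_presences, ext[3], ext[4]),
      year = 2000L
    )
  })
  occ <- dplyr::bind_rows(occ)
  list(
    occurrences = occ,
    env = env,
    pas = pas,
    truth = tibble::tibble(
      species_id = sprintf("sp_%03d", seq_len(n_species)),
      x_min = x0, x_max = x1,
      pct_inside_pa = 100 * strip_rows / env_ny
    )
  )
}
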