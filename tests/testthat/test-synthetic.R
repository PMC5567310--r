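test_that("fixed seed reproduces a world byte for byte", {
  cfg <- small_config(seed = 7, n_species = 25)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- generate_world(small_config(seed = 8, n_species = 25))
  expect_false(identical(w1$occurrences, w3$occurrences))
})

test_that("every record lies inside its species' true range and the extent", {
  w <- generate_world(small_config(seed = 3, n_species = 40))
  ext <- w$config$extent
  expect_true(all(w$occurrences$x >= ext[1] & w$occurrences$x <= ext[2]))
  expect_true(all(w$occurrences$y >= ext[3] & w$occurrences$y <= ext[4]))
  tr <- w$truth
  by_sp <- split(w$occurrences, w$occurrences$species_id)
  for (sp in names(by_sp)) {
    i <- match(sp, tr$species$species_id)
    ctrs <- tr$range_centers[[i]]
    r <- tr$species$range_radius[i]
    pts <- by_sp[[sp]]
    dmin <- rep(Inf, nrow(pts))
    for (j in seq_len(nrow(ctrs))) {
      dmin <- pmin(dmin, sqrt((pts$x - ctrs[j, 1])^2 + (pts$y - ctrs[j, 2])^2))
    }
    expect_true(all(dmin <= r + 1e-9))
  }
  expect_true(all(tr$species$frac_inside_pa >= 0 & tr$species$frac_inside_pa <= 1))
})

test_that("PAs covering the whole extent give full range protection", {
  cfg <- world_config(extent = c(0, 200, 0, 200), n_species = 3,
                      n_pas_per_category = c(strict = 1, sustainable = 1, indigenous = 1),
                      pa_radius_range = c(3000, 3100),
                      env_nx = 20, env_ny = 20, seed = 5)
  w <- generate_world(cfg)
  expect_equal(w$truth$species$frac_inside_pa, rep(1, 3))
})

test_that("overcrowded PA layouts fail with an explicit geometry error", {
  cfg <- world_config(extent = c(0, 60, 0, 60),
                      n_pas_per_category = c(strict = 10, sustainable = 10, indigenous = 10),
                      seed = 1)
  expect_error(generate_world(cfg), "infeasible geometry")
})

test_that("uniform effort with no hotspots samples cells like a uniform multinomial", {
  # range disc centred on the extent and wide enough to cover it entirely,
  # so the only stochastic structure left is the effort thinning
  ext <- c(0, 300, 0, 300)
  ctrs <- matrix(c(150, 150), ncol = 2)
  cfg <- world_config(extent = ext, effort_hotspots = 0, seed = 1)
  eff <- gapscape:::effort_field(cfg)
  nbin <- 6
  rejections <- 0L
  for (s in 1:20) {
    set.seed(s)
    xy <- gapscape:::sample_species_records(2000, ctrs, 250, ext, eff)
    bx <- pmin(nbin, 1L + floor(nbin * (xy[, 1] - ext[1]) / 300))
    by <- pmin(nbin, 1L + floor(nbin * (xy[, 2] - ext[3]) / 300))
    counts <- tabulate((by - 1L) * nbin + bx, nbins = nbin^2)
    p <- stats::chisq.test(counts, p = rep(1 / nbin^2, nbin^2))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("hotspot effort concentrates sampling around the hotspots", {
  ext <- c(0, 300, 0, 300)
  cfg <- world_config(extent = ext, effort_hotspots = 1, hotspot_sd = 30,
                      hotspot_floor = 0.02, seed = 4)
  set.seed(4)
  eff <- gapscape:::effort_field(cfg)
  hx <- eff$centers[1, ]
  xy <- gapscape:::sample_species_records(1500, matrix(c(150, 150), ncol = 2),
                                          250, ext, eff)
  d <- sqrt((xy[, 1] - hx[1])^2 + (xy[, 2] - hx[2])^2)
  expect_gt(mean(d < 60), 0.3) # far above the uniform share of that disc
})

test_that("realized record counts follow the configured heavy-tailed law", {
  cfg <- small_config(n_species = 200)
  rejections <- 0L
  for (s in 1:20) {
    w <- generate_world(small_config(seed = 100 + s, n_species = 200, n_env = 3,
                                     env_nx = 20, env_ny = 20))
    realized <- dplyr::count(w$occurrences, species_id)$n
    set.seed(90000 + s)
    reference <- rrecord_counts(20000, cfg)
    p <- suppressWarnings(stats::ks.test(realized, reference)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("scenario_gap realizes the target outside fraction to one species", {
  cfg <- world_config(n_species = 40, env_nx = 20, env_ny = 20, n_env = 3, seed = 11)
  w <- scenario_gap(cfg, 0.5)
  expect_true(w$truth$n_outside >= 19 && w$truth$n_outside <= 21)
  # generator truth is consistent with the recomputed geometric truth
  expect_equal(sum(w$truth$species$frac_inside_pa == 0), w$truth$n_outside)
  expect_equal(w$truth$species$outside, w$truth$species$frac_inside_pa == 0)
  cfg100 <- world_config(n_species = 100, env_nx = 20, env_ny = 20, n_env = 3, seed = 12)
  w2 <- scenario_gap(cfg100, 0.56)
  expect_true(w2$truth$n_outside >= 55 && w2$truth$n_outside <= 57)
})

test_that("scenario_gap fails with a diagnostic when PAs leave no room", {
  cfg <- world_config(extent = c(0, 200, 0, 200), n_species = 10,
                      n_pas_per_category = c(strict = 1, sustainable = 1, indigenous = 1),
                      pa_radius_range = c(3000, 3100),
                      env_nx = 20, env_ny = 20, seed = 2)
  expect_error(scenario_gap(cfg, 0.5), "no room")
})

test_that("the engineered strip world pins the PA share of every range", {
  sc <- scenario_representativeness(pa_fraction = 0.3, n_species = 3,
                                    n_presences = 20, seed = 9)
  expect_equal(sc$truth$pct_inside_pa, rep(30, 3))
  mask <- env_pa_mask(sc$env, sc$pas$geometry)
  expect_equal(mean(mask), 0.3, tolerance = 1e-12)
})
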