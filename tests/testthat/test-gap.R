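square <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))

toy_pas <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3"),
    category = c("strict", "sustainable", "indigenous"),
    year = c(1950L, 1990L, 2010L),
    biome_id = "biome_1",
    geometry = list(square(0, 0, 50), square(40, 0, 50), square(200, 200, 50))
  )
}

test_that("protection labels follow category precedence and partition points", {
  pas <- toy_pas()
  pts <- tibble::tibble(x = c(10, 45, 220, 150), y = c(10, 10, 220, 150))
  lab <- classify_protection(pts, pas)
  expect_equal(as.character(lab), c("strict", "strict", "indigenous", "unprotected"))
  # the overlap zone (40-50) belongs to strict despite the sustainable PA
  expect_equal(as.character(classify_protection(tibble::tibble(x = 60, y = 10), pas)),
               "sustainable")
  expect_equal(length(lab), nrow(pts))
  expect_equal(sum(table(lab)), nrow(pts))
})

test_that("an all-covering PA set leaves nothing outside on any dimension", {
  set.seed(31)
  g <- hex_grid(c(0, 300, 0, 300), 55)
  occ <- tibble::tibble(
    species_id = sample(sprintf("s%d", 1:10), 200, replace = TRUE),
    x = runif(200, 0, 300), y = runif(200, 0, 300)
  )
  a <- assign_to_cells(occ, g)
  pas <- tibble::tibble(id = "big", category = "strict", year = 1950L,
                        biome_id = "biome_1",
                        geometry = list(square(-100, -100, 500)))
  tree <- unit_branch_lengths(ape::rtree(10, tip.label = sprintf("s%d", 1:10)))
  rep_ <- protection_proportions(a, pas, g, tree = tree)
  expect_equal(rep_$overall$pct_outside, rep(0, 5), tolerance = 1e-9)
  expect_equal(rep_$overall$pct_inside + rep_$overall$pct_outside,
               rep(100, 5), tolerance = 1e-9)
})

test_that("an empty PA set leaves everything outside", {
  set.seed(32)
  g <- hex_grid(c(0, 200, 0, 200), 55)
  occ <- tibble::tibble(species_id = sample(c("a", "b", "c"), 60, replace = TRUE),
                        x = runif(60, 0, 200), y = runif(60, 0, 200))
  a <- assign_to_cells(occ, g)
  pas <- toy_pas()[0, ]
  rep_ <- protection_proportions(a, pas, g)
  expect_equal(rep_$overall$pct_outside, rep(100, 3), tolerance = 1e-9)
})

test_that("WE and PWE partitions conserve their totals", {
  w <- generate_world(small_config(seed = 17, n_species = 40))
  g <- hex_grid(w$config$extent, w$config$hex_diameter)
  a <- assign_to_cells(w$occurrences, g)
  rep_ <- protection_proportions(a, w$pas, g, tree = w$tree, biomes = w$biomes)
  cells <- rep_$cells
  n_sp <- dplyr::n_distinct(w$occurrences$species_id)
  expect_equal(sum(cells$we), n_sp, tolerance = 1e-9)
  inside_we <- sum(cells$we[cells$label != "unprotected"])
  expect_equal(
    rep_$overall$pct_inside[rep_$overall$dimension == "endemism"],
    100 * inside_we / n_sp, tolerance = 1e-9
  )
  pw_total <- sum(cells$pwe)
  expect_equal(
    rep_$overall$pct_outside[rep_$overall$dimension == "phylo_endemism"],
    100 * sum(cells$pwe[cells$label == "unprotected"]) / pw_total,
    tolerance = 1e-9
  )
  # category shares partition the totals
  by_cat <- rep_$by_category
  for (d in c("species", "endemism", "phylo_endemism")) {
    expect_equal(sum(by_cat$pct_of_total[by_cat$dimension == d]), 100,
                 tolerance = 1e-9)
  }
})

test_that("per-PA sampling table reports density classes and sampled fractions", {
  set.seed(33)
  occ <- tibble::tibble(species_id = "s",
                        x = runif(300, 0, 60), y = runif(300, 0, 60))
  tab <- pa_sampling_table(occ, toy_pas())
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_records[3], 0)
  expect_equal(tab$sampled_fraction[3], 0)
  expect_true(all(tab$sampled_fraction >= 0 & tab$sampled_fraction <= 1))
  expect_equal(tab$density[1], tab$n_records[1] / poly_area(toy_pas()$geometry[[1]]))
  expect_equal(as.character(tab$density_class[3]), "[0]")
})

test_that("rank tests recognise identical and separated samples", {
  cells <- tibble::tibble(
    cell_id = 1:40,
    label = factor(rep(c("strict", "unprotected"), each = 20),
                   levels = c("strict", "sustainable", "indigenous", "unprotected")),
    density = rep(1, 40), we = rep(1, 40),
    biome_id = NA_character_
  )
  out <- inside_outside_tests(cells)
  h <- out$statistic[out$test == "density_kw" & out$scope == "all"]
  expect_equal(h, 0, tolerance = 1e-9)
  # complete separation gives the extreme U statistic
  expect_equal(unname(stats::wilcox.test(c(1, 2, 3), c(10, 11, 12))$statistic), 0)
  cells2 <- dplyr::mutate(cells, density = c(rnorm(20, 10), rnorm(20, 0.1)),
                          we = density)
  out2 <- inside_outside_tests(cells2)
  expect_lt(out2$p_value[out2$test == "density_kw"][1], 0.001)
})

test_that("accumulation curves are monotone and end at the static accounting", {
  w <- generate_world(small_config(seed = 23, n_species = 30))
  g <- hex_grid(w$config$extent, w$config$hex_diameter)
  a <- assign_to_cells(w$occurrences, g)
  acc <- accumulation_curves(a, w$pas, g, tree = w$tree)
  for (d in unique(acc$series$dimension)) {
    s <- acc$series[acc$series$dimension == d, ]
    expect_true(all(diff(s$cumulative) >= -1e-12))
    expect_equal(s$pct_of_final[nrow(s)], 100, tolerance = 1e-9)
  }
  # endpoint consistency with the static report
  rep_ <- protection_proportions(a, w$pas, g, tree = w$tree)
  sp_final <- max(acc$series$cumulative[acc$series$dimension == "species"])
  expect_equal(sp_final, sum(rep_$species$label != "unprotected"))
})

test_that("a single designation epoch owns all the slope", {
  w <- generate_world(small_config(seed = 29, n_species = 25))
  w$pas$year <- 1985L
  g <- hex_grid(w$config$extent, w$config$hex_diameter)
  a <- assign_to_cells(w$occurrences, g)
  acc <- accumulation_curves(a, w$pas, g)
  sl <- acc$slopes[acc$slopes$dimension == "species", ]
  expect_gt(sl$slope_degrees[sl$epoch_start == 1981], 0)
  expect_equal(sl$slope_degrees[sl$epoch_start != 1981], rep(0, 4),
               tolerance = 1e-9)
})

test_that("the pipeline isolates SDM failures from occurrence accounting", {
  w <- generate_world(small_config(seed = 37, n_species = 20))
  p_with <- run_pipeline(w, include_sdm = TRUE)
  p_without <- run_pipeline(w, include_sdm = FALSE)
  expect_equal(p_with$report$overall, p_without$report$overall)
  # skipped species are logged, not fatal
  skipped <- p_with$sdm$results[!is.na(p_with$sdm$results$note), ]
  expect_true(all(grepl("skipped|failed", skipped$note)))
})
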