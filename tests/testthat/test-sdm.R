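make_stack <- function(nx = 30, ny = 30, nlayer = 6, seed = 4, f = NULL) {
  set.seed(seed)
  n <- nx * ny
  vals <- sapply(seq_len(nlayer), function(k) rnorm(n))
  if (!is.null(f)) vals <- f(vals)
  env_stack(vals, nx, ny, 0, 0, 10)
}

test_that("environmental PCA yields orthogonal axes with decreasing variance", {
  stk <- make_stack()
  axes <- pca_env(stk, n_axes = 4)
  cors <- stats::cor(axes$values)
  expect_equal(cors[upper.tri(cors)], rep(0, 6), tolerance = 1e-8)
  ve <- attr(axes, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
})

test_that("perfectly correlated layers collapse onto one axis", {
  set.seed(6)
  base <- rnorm(400)
  stk <- env_stack(cbind(a = base, b = 2 * base + 3), 20, 20, 0, 0, 10)
  axes <- pca_env(stk, n_axes = 2)
  ve <- attr(axes, "var_explained")
  expect_equal(ve[1], 1, tolerance = 1e-10)
  expect_equal(ve[2], 0, tolerance = 1e-10)
  expect_error(pca_env(env_stack(cbind(base, rep(1, 400)), 20, 20, 0, 0, 10), 2),
               "constant")
})

test_that("suitability peaks near the training cloud for every algorithm", {
  set.seed(10)
  train <- matrix(rnorm(4 * 40), 40, 4)
  centroid <- colMeans(train)
  far <- centroid + 3 * apply(train, 2, sd) * c(1, 1, 1, 1)
  cells <- rbind(centroid, far)
  for (fun in list(gapscape:::suitability_bioclim,
                   gapscape:::suitability_domain,
                   gapscape:::suitability_mahalanobis)) {
    s <- fun(train, cells)
    expect_gte(s[1], s[2])
  }
  # bioclim: outside the envelope on any axis means zero suitability
  outside <- centroid
  outside[2] <- max(train[, 2]) + 1
  expect_equal(gapscape:::suitability_bioclim(train, rbind(outside)), 0)
})

test_that("the minimum-training threshold forces zero training omission", {
  stk <- make_stack(nx = 40, ny = 40, nlayer = 5, seed = 12)
  axes <- pca_env(stk, 4)
  set.seed(12)
  occ <- tibble::tibble(x = runif(25, 50, 250), y = runif(25, 50, 250))
  for (alg in c("bioclim", "domain", "mahalanobis", "glm")) {
    fit <- fit_sdm(occ, axes, algorithm = alg, seed = 3)
    expect_true(all(fit$binary[fit$presence_cells]))        # omission 0
    expect_equal(min(fit$suitability[fit$presence_cells]), fit$threshold)
    # raising the threshold by any epsilon drops a training point
    expect_gte(sum(fit$suitability[fit$presence_cells] <= fit$threshold), 1)
  }
  expect_error(fit_sdm(occ[1:5, ], axes, "bioclim"), "too few records")
})

test_that("rank AUC handles separation, exchangeability and the worked pairs", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.7, 0.1)), 1)
  expect_equal(auc_rank(6:10, 1:5), 1)
  expect_equal(auc_rank(c(1, 2), c(1, 2)), 0.5) # full ties credit half
  set.seed(2)
  aucs <- replicate(200, auc_rank(runif(20), runif(20)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("glm separable data is recognised with AUC near 1", {
  nx <- 40
  stk <- make_stack(nx = nx, ny = nx, nlayer = 4, seed = 7, f = function(v) {
    ctr <- env_cell_centers(env_stack(v, nx, nx, 0, 0, 10))
    v[, 1] <- ctr[, 1] / 100 # strong x gradient on layer 1
    v
  })
  axes <- pca_env(stk, 4)
  set.seed(7)
  occ <- tibble::tibble(x = runif(30, 320, 390), y = runif(30, 10, 390))
  # engineered absences strictly left of the presence band: separable
  ctr <- env_cell_centers(axes)
  absences <- sample(which(ctr[, 1] < 250), 200)
  fit <- fit_sdm(occ, axes, algorithm = "glm", pseudo_absence_cells = absences)
  expect_gt(fit$auc, 0.99)
  expect_true(fit$keep)
})

test_that("representativeness partitions the masked range", {
  binary <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(representativeness(binary, pa_mask = rep(TRUE, 5)), 100)
  expect_equal(representativeness(binary, pa_mask = rep(FALSE, 5)), 0)
  expect_equal(representativeness(binary, pa_mask = c(TRUE, FALSE, FALSE, FALSE, FALSE)), 25)
  veg <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(representativeness(binary, c(TRUE, FALSE, TRUE, TRUE, TRUE), veg), 50)
  expect_true(is.na(representativeness(rep(FALSE, 5), rep(TRUE, 5))))
})

test_that("group summaries and rank tests behave on constructed results", {
  res <- tibble::tibble(
    species_id = sprintf("s%02d", 1:60),
    algorithm = "bioclim",
    pct_inside_pa = c(rep(c(10, 20, 30), 10), rep(c(60, 70, 80), 10)),
    kept = TRUE,
    group = rep(c("g1", "g2"), each = 30)
  )
  s <- sdm_summary(res)
  expect_equal(s$summary$median, c(20, 70))
  expect_lt(s$tests$p_value, 0.01)
  flat <- dplyr::mutate(res, pct_inside_pa = 42)
  expect_equal(sdm_summary(flat)$tests$H, 0, tolerance = 1e-12)
  expect_equal(stats::median(c(10, 20, 30)), 20)
})

test_that("label-shuffled training data fails the AUC filter", {
  stk <- make_stack(nx = 40, ny = 40, nlayer = 5, seed = 19)
  axes <- pca_env(stk, 4)
  rejected <- 0L
  for (i in 1:20) {
    set.seed(100 + i)
    # presences drawn uniformly over the background: no signal to learn
    occ <- tibble::tibble(x = runif(20, 1, 399), y = runif(20, 1, 399))
    fit <- fit_sdm(occ, axes, algorithm = "glm", seed = 100 + i)
    if (!fit$keep) rejected <- rejected + 1L
  }
  expect_gte(rejected, 18L)
})
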