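test_that("average-male selection applies the inclusion criteria with closed height/weight intervals", {
  mk <- function(age, h, w) {
    rc <- thoraxvar:::unflatten_ribcage(
      thoraxvar:::template_ribcage_vector(6), 6,
      meta = list(age = age, height = h, weight = w))
    rc
  }
  pop <- list(mk(30, 1.75, 75),   # in
              mk(18, 1.75, 75),   # age boundary: excluded (strict >)
              mk(19, 1.72, 72),   # boundary heights/weights: included
              mk(19, 1.82, 82),   # included
              mk(19, 1.83, 75),   # height out
              mk(19, 1.75, 71.9)) # weight out
  sel <- select_average_males(pop)
  expect_length(sel, 3)
})

test_that("selection is idempotent, matches a brute-force filter, and warns on missing metadata", {
  pop <- generate_population(generator_config(seed = 7, n_subjects = 200,
                                              rib_points = 6))
  sel <- select_average_males(pop$subjects)
  meta <- pop$truth$meta
  want <- sum(meta$age > 18 & meta$height >= 1.72 & meta$height <= 1.82 &
                meta$weight >= 72 & meta$weight <= 82)
  expect_length(sel, want)
  expect_length(select_average_males(sel), length(sel))

  pop2 <- pop$subjects[1:3]
  pop2[[2]]$meta <- NULL
  expect_warning(sel2 <- select_average_males(pop2), "missing metadata")
})

test_that("PCA on identical ribcages gives zero score SDs and the common mean", {
  rc <- thoraxvar:::unflatten_ribcage(thoraxvar:::template_ribcage_vector(6), 6)
  model <- fit_shape_pca(rep(list(rc), 5), k = 2)
  expect_equal(model$sigma, c(0, 0), tolerance = 1e-10)
  expect_equal(model$mu, thoraxvar:::flatten_ribcage(rc))
})

test_that("PCA recovers a rank-2 generating basis up to sign", {
  pop <- make_rank2_population()
  model <- fit_shape_pca(pop$subjects, k = 2)
  expect_lt(max_principal_angle(pop$basis, model$components), 1e-6)
  expect_equal(sum(model$explained_variance), 1, tolerance = 1e-8)
  # components orthonormal
  G <- model$components %*% t(model$components)
  expect_equal(G, diag(2), tolerance = 1e-8)
  # score SDs use the n-1 convention
  scores <- t(vapply(pop$subjects, function(rc) shape_scores(model, rc),
                     numeric(2)))
  expect_equal(apply(scores, 2, sd), model$sigma, tolerance = 1e-8)
})

test_that("ribcage generation along a mode is Eq-style affine in s", {
  pop <- make_rank2_population()
  model <- fit_shape_pca(pop$subjects, k = 2)
  expect_equal(thoraxvar:::flatten_ribcage(generate_ribcage(model, 1, 0)),
               model$mu)
  out <- generate_ribcage(model, 2, 1.5)
  sc <- shape_scores(model, out)
  expect_equal(sc[2], 1.5 * model$sigma[2], tolerance = 1e-8)
  expect_equal(sc[1], 0, tolerance = 1e-8 * model$sigma[1])
  # symmetry about the mean and affinity in s
  lo <- thoraxvar:::flatten_ribcage(generate_ribcage(model, 1, -2))
  hi <- thoraxvar:::flatten_ribcage(generate_ribcage(model, 1, 2))
  expect_equal((lo + hi) / 2, model$mu, tolerance = 1e-10)
  mid <- thoraxvar:::flatten_ribcage(generate_ribcage(model, 1, 1))
  expect_equal(mid, (model$mu + hi) / 2, tolerance = 1e-10)
  expect_error(generate_ribcage(model, 3, 0), "index")
})

test_that("a full-rank training sample is reconstructed exactly from all components", {
  pop <- generate_population(generator_config(seed = 11, n_subjects = 8,
                                              rib_points = 6))
  model <- fit_shape_pca(pop$subjects, k = 7)
  for (rc in pop$subjects) {
    vec <- thoraxvar:::flatten_ribcage(rc)
    sc <- shape_scores(model, rc)
    recon <- model$mu + as.numeric(t(model$components) %*% sc)
    expect_equal(recon, vec, tolerance = 1e-8)
  }
})

test_that("log-normal thickness fitting recovers parameters and flags degeneracy", {
  expect_error(fit_thickness_lognormal(rep(1, 5)), "at least 10")
  expect_error(fit_thickness_lognormal(c(rep(1, 10), -1)), "non-positive")
  f0 <- fit_thickness_lognormal(rep(1, 100))
  expect_equal(f0$mu_log, 0)
  expect_equal(f0$sigma_log, 0)
  expect_true(f0$degenerate)

  draws <- thoraxvar:::with_preserved_seed(3, rlnorm(10000, 0, 0.3))
  fit <- fit_thickness_lognormal(thickness_map(draws))
  expect_equal(fit$mu_log, 0, tolerance = 0.01)
  expect_equal(fit$sigma_log, 0.3, tolerance = 0.01)
})

test_that("population SD of fitted log-means matches closed-form and spreadsheet oracles", {
  f1 <- fit_thickness_lognormal(rep(exp(0.0), 10))
  f2 <- fit_thickness_lognormal(rep(exp(0.44), 10))
  expect_equal(population_mu_sd(list(f1, f2)), sd(c(0, 0.44)))
  expect_equal(population_mu_sd(list(f1, f2)), 0.311127, tolerance = 1e-6)
  expect_equal(population_mu_sd(list(f1, f1, f1)), 0)
  expect_error(population_mu_sd(list(f1)), "at least 2")

  maps <- generate_thickness_maps(generator_config(seed = 5))$maps
  fits <- lapply(maps, fit_thickness_lognormal)
  mus <- vapply(fits, `[[`, numeric(1), "mu_log")
  manual <- sqrt(sum((mus - mean(mus))^2) / (length(mus) - 1))
  expect_equal(population_mu_sd(fits), manual, tolerance = 1e-12)
})

test_that("rib-curve and shape-model archives round-trip through CSV/JSON", {
  pop <- generate_population(generator_config(seed = 2, n_subjects = 5,
                                              rib_points = 6))
  curve_csv <- withr::local_tempfile(fileext = ".csv")
  meta_csv <- withr::local_tempfile(fileext = ".csv")
  write_rib_curves_csv(pop$subjects, curve_csv, meta_csv)
  back <- read_rib_curves_csv(curve_csv, meta_csv)
  expect_length(back, 5)
  expect_equal(thoraxvar:::flatten_ribcage(back[[1]]),
               thoraxvar:::flatten_ribcage(pop$subjects[[1]]),
               tolerance = 1e-10)
  expect_equal(back[[3]]$meta$age, pop$subjects[[3]]$meta$age,
               tolerance = 1e-10)

  model <- fit_shape_pca(pop$subjects, k = 3)
  dir <- withr::local_tempdir()
  write_shape_model(model, dir)
  restored <- read_shape_model(dir)
  expect_equal(restored$mu, model$mu, tolerance = 1e-12)
  expect_equal(restored$components, model$components, tolerance = 1e-12)
  expect_equal(restored$sigma, model$sigma, tolerance = 1e-12)

  target_csv <- withr::local_tempfile(fileext = ".csv")
  export_morph_target(model, 1, 2, target_csv)
  tgt <- read_rib_curves_csv(target_csv)
  expect_equal(thoraxvar:::flatten_ribcage(tgt[[1]]),
               thoraxvar:::flatten_ribcage(generate_ribcage(model, 1, 2)),
               tolerance = 1e-10)
})
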