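test_that("default parameter space enumerates the 15 coordinates with their distributions", {
  space <- default_parameter_space()
  expect_length(space, 15)
  expect_s3_class(space, "parameter_space")
  expect_identical(space$adipose$distribution, "uniform")
  expect_identical(space$skeletal_muscle$distribution, "uniform")
  expect_identical(space$intercostal_muscle$distribution, "uniform")
  expect_identical(space$cartilage$distribution, "cartilage_percentile")
  normals <- c(paste0("shape_pc", 1:6), "cort_thickness", "rib_width",
               "rib_height", "cort_material", "trab_material")
  for (nm in normals) {
    expect_identical(space[[nm]]$distribution, "standard_normal_truncated")
  }
  for (sp in space) expect_equal(sp$s_range, c(-2, 2))
})

test_that("cortical, trabecular and cartilage scalings evaluate the printed expressions", {
  cm <- scale_cortical(0)
  expect_equal(cm$E, 14.7)
  expect_equal(cm$sigma_Y, 100.7)
  expect_equal(cm$P, 1.94)
  expect_equal(scale_cortical(2)$E, 18.7)
  expect_equal(scale_cortical(-2)$sigma_Y, 74.9)

  tm <- scale_trabecular(0)
  expect_equal(tm$E, 25.7)
  expect_equal(tm$sigma_Y, 0.42)
  expect_equal(tm$P, 5.66)
  t2 <- scale_trabecular(2)
  expect_equal(t2$g, 0.475)
  expect_equal(t2$E, 25.7 + 46.7 * 0.475)
  tm2 <- scale_trabecular(-2)
  expect_equal(tm2$P, 5.66 - 11.9 * 0.475)
  expect_gt(tm2$P, 0)

  expect_equal(scale_cartilage(0)$E_eff, 21.4)
  expect_equal(scale_cartilage(2)$E_eff, 44.1, tolerance = 1e-12)
  expect_equal(scale_cartilage(-2)$E_eff, 7.9, tolerance = 1e-12)
})

test_that("soft-tissue scalings reproduce the material table rows", {
  ad2 <- scale_soft_tissue("adipose", 2)
  expect_equal(ad2$mu, 41)
  expect_equal(ad2$prony$G, c(1.04, 2.34, 2.90))
  expect_equal(ad2$nu, 0.499995, tolerance = 1e-6)
  adm <- scale_soft_tissue("adipose", -2)
  expect_equal(adm$mu, 29)
  expect_equal(adm$nu, 0.49978, tolerance = 1e-5)
  expect_equal(adm$prony$G, c(0.56, 1.26, 1.54))
  ad0 <- scale_soft_tissue("adipose", 0)
  expect_equal(ad0$mu, 35)
  expect_equal(ad0$alpha, 20)
  expect_equal(ad0$nu, 0.49998, tolerance = 1e-6)

  mus <- scale_soft_tissue("muscle", 2)
  expect_equal(mus$mu, 153)
  expect_equal(mus$alpha, 13.2)
  expect_equal(mus$nu, 0.495)
  expect_identical(nrow(mus$prony), 0L)
  expect_equal(scale_soft_tissue("muscle", -2)$mu, 63)
})

test_that("geometry scaling is the identity at the cut-point and matches the 2-SD offsets", {
  g0 <- scale_geometry(0, 0, 0)
  expect_equal(g0$T_scale, 1)
  expect_equal(g0$dW, 0)
  expect_equal(g0$dH, 0)
  expect_equal(scale_geometry(2, 0, 0)$T_scale, exp(0.44))
  g2 <- scale_geometry(0, 2, 2)
  expect_equal(g2$dW, 2.72)
  expect_equal(g2$dH, 3.92)
  # alternative published-coefficient convention remains selectable
  expect_equal(scale_geometry(0, 1, 0, width_per_sd = 2.72)$dW, 2.72)
})

test_that("scaling expressions are monotone in s over the scaling range", {
  grid <- seq(-2, 2, by = 0.25)
  series <- list(
    function(s) scale_cortical(s)$E,
    function(s) scale_cortical(s)$sigma_Y,
    function(s) scale_cortical(s)$P,
    function(s) scale_trabecular(s)$E,
    function(s) scale_trabecular(s)$sigma_Y,
    function(s) scale_trabecular(s)$P,
    function(s) scale_cartilage(s)$E_eff,
    function(s) scale_soft_tissue("adipose", s)$mu,
    function(s) scale_soft_tissue("muscle", s)$mu,
    function(s) scale_geometry(s, 0, 0)$T_scale,
    function(s) scale_geometry(0, s, 0)$dW,
    function(s) scale_geometry(0, 0, s)$dH
  )
  for (f in series) {
    expect_true(all(diff(vapply(grid, f, numeric(1))) > 0))
  }
})

test_that("scaling coordinates outside [-2, 2] are rejected", {
  expect_error(scale_cortical(2.5), "range")
  expect_error(scale_cartilage(-2.01), "range")
  expect_error(scale_soft_tissue("adipose", 3), "range")
  expect_error(scale_geometry(0, 5, 0), "range")
})

test_that("bi-linear stress is continuous at yield and ordered in s", {
  cm <- scale_cortical(0)
  expect_equal(bilinear_stress(cm, 0), 0)
  eps_y <- 100.7 / 14700
  expect_equal(bilinear_stress(cm, eps_y), 100.7, tolerance = 1e-12)
  # continuity: approach yield from both sides
  expect_equal(bilinear_stress(cm, eps_y - 1e-12),
               bilinear_stress(cm, eps_y + 1e-12), tolerance = 1e-6)
  grid <- seq(1e-4, 0.05, length.out = 50)
  expect_true(all(bilinear_stress(scale_cortical(1), grid) >=
                    bilinear_stress(scale_cortical(-1), grid)))
  expect_true(all(bilinear_stress(scale_trabecular(1), grid) >=
                    bilinear_stress(scale_trabecular(-1), grid)))
  expect_error(bilinear_stress(cm, -0.01), "negative")
})

test_that("scaling-coordinate densities have the stated values and renormalize to 1", {
  space <- default_parameter_space()
  expect_equal(density_for(1.5, space$adipose), 0.25)
  expect_equal(density_for(0, space$cort_thickness),
               dnorm(0) / (pnorm(2) - pnorm(-2)), tolerance = 1e-12)
  # cartilage coordinate preserves the percentile correspondence:
  # P(s <= -2) = 0.05 before truncation
  sd0 <- 2 / qnorm(0.95)
  expect_equal(pnorm(-2, sd = sd0), 0.05, tolerance = 1e-12)
  for (sp in space) {
    total <- integrate(function(s) density_for(s, sp),
                       sp$s_range[1], sp$s_range[2], rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("parameter-space YAML definition round-trips", {
  space <- default_parameter_space()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_space(space, path)
  back <- read_parameter_space(path)
  expect_identical(names(back), names(space))
  for (nm in names(space)) {
    expect_identical(back[[nm]]$distribution, space[[nm]]$distribution)
    expect_equal(back[[nm]]$s_range, space[[nm]]$s_range)
  }
})

test_that("parameter vectors are validated against the space", {
  space <- default_parameter_space()
  pv <- cut_point(space)
  expect_silent(validate_parameter_vector(pv, space))
  pv_bad <- pv
  pv_bad[["rib_width"]] <- 3
  expect_error(validate_parameter_vector(pv_bad, space), "range")
  expect_error(validate_parameter_vector(pv[-1], space), "missing")
})

test_that("the material table exports every parametric field in long format", {
  tab <- material_table(c(-2, 0, 2))
  expect_named(tab, c("parameter", "s", "field", "value", "unit"))
  row <- tab[tab$parameter == "adipose" & tab$s == 2 & tab$field == "G1", ]
  expect_equal(row$value, 1.04)
  expect_identical(row$unit, "kPa")
  expect_equal(tab[tab$parameter == "cort_material" & tab$s == 0 &
                     tab$field == "E", "value"], 14.7)
})
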