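test_that("Gauss-Legendre rules have exact low-order behaviour", {
  gl1 <- gauss_legendre_nodes(1, -1, 1)
  expect_equal(gl1$nodes, 0)
  expect_equal(gl1$weights, 2)
  gl5 <- gauss_legendre_nodes(5, -2, 2)
  expect_equal(sum(gl5$weights), 4, tolerance = 1e-12)
  gl <- gauss_legendre_nodes(5, -1, 1)
  expect_equal(sum(gl$weights * gl$nodes^9), 0, tolerance = 1e-14)
  expect_equal(sum(gl$weights * gl$nodes^8), 2 / 9, tolerance = 1e-14)
  expect_error(gauss_legendre_nodes(5, 1, -1), "interval")
  expect_error(gauss_legendre_nodes(0), "N")
})

test_that("the quadrature design uses n * N_GP + 1 evaluations with unit weight sums", {
  space <- default_parameter_space()
  counter <- 0L
  model <- function(pv) {
    counter <<- counter + 1L
    1 + sum(as.numeric(pv)^2)
  }
  design <- build_design(space, model, N_GP = 5)
  expect_identical(counter, 76L)
  expect_identical(design$n_evaluations, 76L)
  expect_equal(unname(rowSums(design$weights)), rep(1, 15), tolerance = 1e-12)
  expect_equal(dim(design$h), c(15L, 5L))

  # constant model: all node outputs equal the cut-point output
  dsgn0 <- build_design(space, function(pv) 2.5, N_GP = 3)
  expect_true(all(dsgn0$h == dsgn0$h0))
  res0 <- mdrm_indices(dsgn0)
  expect_true(res0$constant_model)
  expect_true(all(res0$S_i == 0) && all(res0$S_Ti == 0))
  expect_equal(res0$V_Y, 0)
})

test_that("design tables serialize and re-load without re-evaluating the model", {
  tf <- make_test_functions()$multiplicative
  design <- build_design(tf$space, tf$f, N_GP = 5, cut = tf$cut)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(design, path)
  back <- read_design_csv(path)
  expect_equal(back$h, design$h, tolerance = 1e-12)
  expect_equal(back$h0, design$h0, tolerance = 1e-12)
  r1 <- mdrm_indices(design)
  r2 <- mdrm_indices(back)
  expect_equal(r2$S_i, r1$S_i, tolerance = 1e-12)
  expect_equal(r2$S_Ti, r1$S_Ti, tolerance = 1e-12)
})

test_that("M-DRM is exact for multiplicative models, including second-order indices", {
  tf <- make_test_functions()$multiplicative
  res <- mdrm_indices(build_design(tf$space, tf$f, N_GP = 5, cut = tf$cut))
  expect_equal(unname(res$S_i), tf$analytic$S, tolerance = 1e-10)
  expect_equal(unname(res$S_Ti), tf$analytic$ST, tolerance = 1e-10)
  # analytic second-order indices derived from the Sobol decomposition of
  # prod(1 + a_i x_i): V_ij = (a_i^2/3)(a_j^2/3), V = prod(1 + a_k^2/3) - 1
  a <- c(0.5, 0.3, 0.2)
  V <- prod(1 + a^2 / 3) - 1
  for (row in seq_len(nrow(res$S_ij))) {
    i <- match(res$S_ij$parameter_i[row], tf$space |> names())
    j <- match(res$S_ij$parameter_j[row], tf$space |> names())
    expect_equal(res$S_ij$S_ij[row], (a[i]^2 / 3) * (a[j]^2 / 3) / V,
                 tolerance = 1e-10)
  }
  # full index algebra is consistent: sum of all orders is 1 for a
  # three-factor multiplicative model up to the third-order remainder
  expect_lte(sum(res$S_i), 1 + 1e-9)
  expect_true(all(res$S_Ti >= res$S_i - 1e-9))
})

test_that("a model depending on one parameter concentrates all variance there", {
  space <- uniform_space(3, c(-1, 1))
  model <- function(x) 2 + 0.5 * x[["x1"]] + 0.1 * x[["x1"]]^2
  res <- mdrm_indices(build_design(space, model, N_GP = 5))
  expect_equal(unname(res$S_i["x1"]), 1, tolerance = 1e-10)
  expect_equal(unname(res$S_Ti["x1"]), 1, tolerance = 1e-10)
  expect_equal(unname(res$S_i[c("x2", "x3")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(res$S_Ti[c("x2", "x3")]), c(0, 0), tolerance = 1e-12)
})

test_that("Monte Carlo Sobol oracle recovers additive-model indices and is seed-stable", {
  tf <- make_test_functions()$additive
  res <- sobol_oracle(tf$f, tf$space, n_samples = 4096, seed = 101)
  for (i in 1:3) {
    expect_lt(abs(res$S_i[i] - tf$analytic$S[i]),
              max(3 * res$se_S[i], 0.02))
    expect_lt(abs(res$S_Ti[i] - tf$analytic$ST[i]),
              max(3 * res$se_ST[i], 0.02))
  }
  res2 <- sobol_oracle(tf$f, tf$space, n_samples = 4096, seed = 101)
  expect_identical(res$S_i, res2$S_i)
  resc <- sobol_oracle(function(x) 3, uniform_space(3), n_samples = 1024,
                       seed = 5)
  expect_true(resc$constant_model)
  expect_error(sobol_oracle(tf$f, tf$space, n_samples = 100), "1024")
})

test_that("M-DRM agrees with the Monte Carlo oracle where its product form holds", {
  for (nm in c("multiplicative", "additive")) {
    tf <- make_test_functions()[[nm]]
    mdrm <- mdrm_indices(build_design(tf$space, tf$f, N_GP = 10,
                                      cut = tf$cut))
    mc <- sobol_oracle(tf$f, tf$space, n_samples = 8192, seed = 7)
    for (i in 1:3) {
      expect_lt(abs(mdrm$S_i[i] - mc$S_i[i]), max(0.05, 3 * mc$se_S[i]))
      expect_lt(abs(mdrm$S_Ti[i] - mc$S_Ti[i]), max(0.05, 3 * mc$se_ST[i]))
    }
  }
})

test_that("index invariants hold on the surrogate study designs", {
  report <- run_study(N_GP = 3)
  for (case in report$study$cases) {
    res <- case$result
    expect_lte(sum(res$S_i), 1 + 1e-9)
    expect_true(all(res$S_Ti >= res$S_i - 1e-9))
    expect_true(all(res$S_i >= -1e-12))
    expect_true(all(res$S_ij$S_ij >= -1e-12))
    expect_gt(res$V_Y, 0)
  }
})

test_that("ranking orders by total index with documented tie-breaks", {
  res <- structure(list(parameters = c("b", "a", "c"),
                        S_i = c(b = 0.2, a = 0.3, c = 0.2),
                        S_Ti = c(b = 0.5, a = 0.5, c = 0.1),
                        method = "mdrm", constant_model = FALSE),
                   class = "sensitivity_result")
  rk <- rank_indices(res)
  expect_identical(rk$parameter, c("a", "b", "c"))
  expect_identical(rk$rank, 1:3)
})

test_that("degenerate one-dimensional means are reported as errors", {
  space <- uniform_space(2, c(-pi, pi))
  model <- function(x) sin(x[["x1"]]) + 2  # fine
  expect_silent(mdrm_indices(build_design(space, model, N_GP = 5)))
  bad <- function(x) sin(x[["x1"]])        # E[h_1] = 0 at the cut-point
  expect_error(mdrm_indices(build_design(space, bad, N_GP = 5)),
               "degenerate")
})

test_that("near-saturated risk outputs trigger the bounds warning", {
  space <- uniform_space(2, c(-1, 1))
  model <- function(x) min(1, max(0, 0.5 + x[["x1"]]))
  expect_warning(build_design(space, model, N_GP = 5,
                              output_bounds = c(0, 1)), "bounds")
})
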