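# Synthetic-data generators: every input the pipeline consumes, produced
# with the statistical structure the analysis assumes (known ground truth
# emitted alongside the data so recovery tests never go through the pipeline
# under test). Curves are statistical stand-ins for CT-derived centroidal
# paths, not anatomical reconstructions.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study conditions the pipeline is designed around: 89
#' average-male subjects for the shape sample, 33 individuals for the
#' thickness maps with a between-subject log-mean SD of 0.22, six generating
#' shape modes dominating more than 90% of coordinate variance.
#'
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @param n_subjects Number of subjects in the shape population.
#' @param rib_points Points per rib curve.
#' @param mode_sds SDs (mm) of the generating shape-mode scores.
#' @param noise_sd Per-coordinate residual noise SD, mm.
#' @param thickness List: `n_subjects`, `n_nodes`, `pop_log_mean`
#'   (population log-mean of thickness in log-mm), `mu_sd` (between-subject
#'   SD of the log-mean, default 0.22), `within_sd` (within-subject log-SD).
#' @param age_range,height_range,weight_range Metadata sampling windows
#'   (years, m, kg); the defaults straddle the average-male inclusion
#'   criteria so filtering is exercised.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1, n_subjects = 89, rib_points = 20,
                             mode_sds = c(12, 8, 6, 4, 3, 2.5),
                             noise_sd = 0.04,
                             thickness = list(n_subjects = 33,
                                              n_nodes = 2000,
                                              pop_log_mean = log(0.7),
                                              mu_sd = 0.22,
                                              within_sd = 0.35),
                             age_range = c(16, 80),
                             height_range = c(1.60, 1.95),
                             weight_range = c(60, 95)) {
  stopifnot(n_subjects >= 2, rib_points >= 2, all(mode_sds >= 0),
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 rib_points = rib_points, mode_sds = mode_sds,
                 noise_sd = noise_sd, thickness = thickness,
                 age_range = age_range, height_range = height_range,
                 weight_range = weight_range),
            class = "generator_config")
}

# arc-length-uniform resampling of a polyline to n points
resample_arclength <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  target <- seq(0, cum[length(cum)], length.out = n)
  out <- sapply(seq_len(3), function(j) approx(cum, pts[, j], target)$y)
  out
}

#' Generate one synthetic rib centroidal curve
#'
#' A smooth, planar-ish semi-elliptical arc whose span and depth grow from
#' rib 1 to rib 7 and shrink thereafter, with a level-dependent
#' pump-handle droop and a small out-of-plane twist. Vertebral end first;
#' arc-length-uniform point spacing; deterministic given its inputs; left
#' and right curves are mirror images about the sagittal plane.
#'
#' @param level Rib level 1-12.
#' @param side `"left"` or `"right"`.
#' @param rib_points Number of points on the curve.
#' @param scale Overall size factor (subject-level).
#' @return A [rib_curve()].
#' @export
generate_rib_curve <- function(level, side = c("left", "right"),
                               rib_points = 20, scale = 1) {
  side <- match.arg(side)
  stopifnot(level %in% 1:12)
  a <- (80 + 55 * sin(pi * level / 14.5)) * scale   # half-span, mm
  b <- (55 + 50 * sin(pi * level / 14.5)) * scale   # depth, mm
  z0 <- 250 - 18 * level
  droop <- 0.35 * (level + 2) / 14                  # pump-handle tilt
  th <- seq(0, 0.85 * pi, length.out = 12 * rib_points)
  x <- a * sin(th)
  y <- -b * (1 - cos(th))
  z <- z0 + droop * y + 1.5 * sin(2 * th)           # mild twist
  if (side == "left") x <- -x
  pts <- resample_arclength(cbind(x, y, z), rib_points)
  rib_curve(level, side, pts)
}

# template ribcage as a flat coordinate vector
template_ribcage_vector <- function(rib_points) {
  curves <- list()
  k <- 1L
  for (level in 1:12) {
    for (side in RIB_SIDES) {
      curves[[k]] <- generate_rib_curve(level, side, rib_points)
      k <- k + 1L
    }
  }
  flatten_ribcage(ribcage_geometry(curves))
}

#' Generate a synthetic ribcage population with known shape structure
#'
#' Subjects are the template ribcage plus known orthonormal shape modes with
#' independent normal scores (SDs `mode_sds`) and small iid coordinate
#' noise; metadata is drawn from the configured windows so that both
#' in-window and out-of-window subjects occur. Ground truth (template, mode
#' matrix, scores, metadata) is returned alongside the data.
#'
#' @param config A [generator_config()].
#' @return List with `subjects` (list of [ribcage_geometry()]) and `truth`
#'   (template vector, `modes` p x K orthonormal matrix, `mode_sds`,
#'   `scores`, `meta` data frame).
#' @export
generate_population <- function(config = generator_config()) {
  npts <- config$rib_points
  template <- template_ribcage_vector(npts)
  p <- length(template)
  K <- length(config$mode_sds)
  with_preserved_seed(config$seed, {
    raw <- matrix(rnorm(p * K), p, K)
    Q <- qr.Q(qr(raw))
    for (k in seq_len(K)) {
      j <- which.max(abs(Q[, k]))
      if (Q[j, k] < 0) Q[, k] <- -Q[, k]
    }
    n <- config$n_subjects
    scores <- matrix(rnorm(n * K), n, K) %*% diag(config$mode_sds, K)
    noise <- matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    X <- matrix(template, n, p, byrow = TRUE) + scores %*% t(Q) + noise
    meta <- data.frame(
      age = runif(n, config$age_range[1], config$age_range[2]),
      height = runif(n, config$height_range[1], config$height_range[2]),
      weight = runif(n, config$weight_range[1], config$weight_range[2])
    )
    subjects <- lapply(seq_len(n), function(i) {
      unflatten_ribcage(X[i, ], npts,
                        meta = list(age = meta$age[i], height = meta$height[i],
                                    weight = meta$weight[i]))
    })
    list(subjects = subjects,
         truth = list(template = template, modes = Q,
                      mode_sds = config$mode_sds, scores = scores,
                      noise_sd = config$noise_sd, meta = meta,
                      seed = config$seed))
  })
}

#' Generate synthetic per-subject cortical thickness maps
#'
#' Each subject's nodal thicknesses are log-normal with a subject-specific
#' log-mean drawn from a normal distribution (SD `mu_sd`, default 0.22)
#' around the population log-mean. Ground truth per-subject log-means are
#' returned for recovery tests.
#'
#' @param config A [generator_config()] (its `thickness` entry is used).
#' @return List with `maps` (list of [thickness_map()]) and `truth`.
#' @export
generate_thickness_maps <- function(config = generator_config()) {
  th <- config$thickness
  stopifnot(th$n_subjects >= 2)
  with_preserved_seed(config$seed, {
    mu <- rnorm(th$n_subjects, th$pop_log_mean, th$mu_sd)
    maps <- lapply(seq_len(th$n_subjects), function(j) {
      if (th$within_sd == 0) {
        thickness_map(rep(exp(mu[j]), th$n_nodes))
      } else {
        thickness_map(rlnorm(th$n_nodes, mu[j], th$within_sd))
      }
    })
    list(maps = maps,
         truth = list(mu_log = mu, pop_log_mean = th$pop_log_mean,
                      mu_sd = th$mu_sd, within_sd = th$within_sd,
                      seed = config$seed))
  })
}

#' Write a generator ground-truth sidecar (JSON)
#'
#' @param truth A `truth` list from a generator.
#' @param path Output path (conventionally `*.truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analytic test-function battery for the sensitivity estimators
#'
#' Named black-box functions with their parameter spaces, recommended
#' cut-points and closed-form Sobol indices:
#' * `multiplicative`: `prod(1 + a_i x_i)` on uniform \[-1, 1\]^3 — the
#'   M-DRM product form is exact here; indices follow from
#'   `r_i = 1 + a_i^2 / 3`.
#' * `additive`: `10 + sum(a_i x_i)` on uniform \[-1, 1\]^3;
#'   `S_i = S_Ti = a_i^2 / sum(a_k^2)`.
#' * `ishigami`: `sin x1 + 7 sin^2 x2 + 0.1 x3^4 sin x1` on uniform
#'   \[-pi, pi\]^3; the standard closed forms give
#'   `V1 = (1 + b pi^4 / 5)^2 / 2`, `V2 = a^2 / 8`,
#'   `V13 = 8 b^2 pi^8 / 225`. Strong pure-interaction structure; a hard
#'   case for the multiplicative approximation.
#' * `constant`: all indices zero.
#'
#' @return Named list; each entry has `f`, `space`, `cut`, and
#'   `analytic = list(S, ST)`.
#' @export
make_test_functions <- function() {
  out <- list()

  a_m <- c(0.5, 0.3, 0.2)
  r_m <- 1 + a_m^2 / 3                     # E[(1+ax)^2], x ~ U(-1,1)
  denom_m <- prod(r_m) - 1
  ST_m <- vapply(1:3, function(i) {
    1 - (prod(r_m[-i]) - 1) / denom_m
  }, numeric(1))
  out$multiplicative <- list(
    f = function(x) prod(1 + a_m * as.numeric(x)),
    space = uniform_space(3, c(-1, 1)),
    cut = setNames(numeric(3), paste0("x", 1:3)),
    analytic = list(S = (r_m - 1) / denom_m, ST = ST_m)
  )

  a_a <- c(1, 2, 3)
  out$additive <- list(
    f = function(x) 10 + sum(a_a * as.numeric(x)),
    space = uniform_space(3, c(-1, 1)),
    cut = setNames(numeric(3), paste0("x", 1:3)),
    analytic = list(S = a_a^2 / sum(a_a^2), ST = a_a^2 / sum(a_a^2))
  )

  a_i <- 7; b_i <- 0.1
  V1 <- (1 + b_i * pi^4 / 5)^2 / 2
  V2 <- a_i^2 / 8
  V13 <- 8 * b_i^2 * pi^8 / 225
  V <- V1 + V2 + V13
  out$ishigami <- list(
    f = function(x) {
      x <- as.numeric(x)
      sin(x[1]) + a_i * sin(x[2])^2 + b_i * x[3]^4 * sin(x[1])
    },
    space = uniform_space(3, c(-pi, pi)),
    cut = setNames(rep(1, 3), paste0("x", 1:3)),
    analytic = list(S = c(V1, V2, 0) / V,
                    ST = c(V1 + V13, V2, V13) / V)
  )

  out$constant <- list(
    f = function(x) 3,
    space = uniform_space(3, c(-1, 1)),
    cut = setNames(numeric(3), paste0("x", 1:3)),
    analytic = list(S = rep(0, 3), ST = rep(0, 3))
  )

  out
}
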