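# Statistical shape model of rib centroidal curves and log-normal fitting of
# cortical thickness maps.
#
# A ribcage is represented by 24 rib centroidal curves (12 levels x 2 sides)
# with a fixed number of points per curve; curves are stacked, in canonical
# order (level 1..12, left then right, vertebral end first), into one
# coordinate vector for PCA.

RIB_SIDES <- c("left", "right")

#' A single rib centroidal curve
#'
#' @param rib_level Integer 1-12.
#' @param side `"left"` or `"right"`.
#' @param points Numeric matrix (n x 3) of xyz coordinates in mm, vertebral
#'   end first, with at least 2 points and consecutive points distinct.
#' @return Object of class `"rib_curve"`.
#' @export
rib_curve <- function(rib_level, side = c("left", "right"), points) {
  side <- match.arg(side)
  stopifnot(rib_level %in% 1:12)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 2L) {
    stop("'points' must be a numeric n x 3 matrix with n >= 2", call. = FALSE)
  }
  steps <- diff(points)
  if (any(rowSums(steps^2) == 0)) {
    stop("consecutive curve points must be distinct", call. = FALSE)
  }
  structure(list(rib_level = as.integer(rib_level), side = side,
                 points = unname(points)),
            class = "rib_curve")
}

#' A whole-ribcage geometry: 24 rib curves plus subject metadata
#'
#' @param curves List of 24 [rib_curve()] objects covering levels 1-12 on
#'   both sides, all with the same point count.
#' @param meta Optional list with `age` (years), `height` (m), `weight` (kg).
#' @return Object of class `"ribcage_geometry"`, with curves stored in
#'   canonical order.
#' @export
ribcage_geometry <- function(curves, meta = NULL) {
  if (length(curves) != 24L) {
    stop("a ribcage needs exactly 24 rib curves", call. = FALSE)
  }
  key <- vapply(curves, function(cv) {
    paste(cv$rib_level, cv$side)
  }, character(1))
  want <- as.vector(t(outer(1:12, RIB_SIDES, paste)))
  if (!setequal(key, want)) {
    stop("curves must cover rib levels 1-12 on both sides", call. = FALSE)
  }
  curves <- curves[match(want, key)]
  npts <- vapply(curves, function(cv) nrow(cv$points), integer(1))
  if (length(unique(npts)) != 1L) {
    stop("all rib curves must have the same point count", call. = FALSE)
  }
  structure(list(curves = curves, meta = meta, npts = npts[1]),
            class = "ribcage_geometry")
}

# stack a ribcage into one coordinate vector (canonical order, xyz by point)
flatten_ribcage <- function(rc) {
  as.numeric(t(do.call(rbind, lapply(rc$curves, `[[`, "points"))))
}

# rebuild a ribcage from a coordinate vector
unflatten_ribcage <- function(vec, npts, meta = NULL) {
  coords <- matrix(vec, ncol = 3, byrow = TRUE)
  idx <- 0L
  curves <- vector("list", 24L)
  k <- 1L
  for (level in 1:12) {
    for (side in RIB_SIDES) {
      pts <- coords[idx + seq_len(npts), , drop = FALSE]
      curves[[k]] <- rib_curve(level, side, pts)
      idx <- idx + npts
      k <- k + 1L
    }
  }
  ribcage_geometry(curves, meta)
}

#' Select average-stature male subjects from a population
#'
#' Inclusion criteria: age strictly greater than 18 years, height in the
#' closed interval 1.72-1.82 m, weight in 72-82 kg. Subjects with missing
#' metadata are excluded with a warning.
#'
#' @param population List of [ribcage_geometry()] objects with `meta`.
#' @return The subset (a list) of subjects satisfying all three criteria.
#' @export
select_average_males <- function(population) {
  ok <- vapply(population, function(rc) {
    m <- rc$meta
    if (is.null(m) || is.null(m$age) || is.null(m$height) ||
        is.null(m$weight) || anyNA(c(m$age, m$height, m$weight))) {
      return(NA)
    }
    m$age > 18 && m$height >= 1.72 && m$height <= 1.82 &&
      m$weight >= 72 && m$weight <= 82
  }, logical(1))
  if (anyNA(ok)) {
    warning(sum(is.na(ok)), " subject(s) excluded for missing metadata",
            call. = FALSE)
    ok[is.na(ok)] <- FALSE
  }
  population[ok]
}

#' Fit a PCA shape model of rib centroidal curves
#'
#' Mean-centered PCA of stacked whole-ribcage coordinate vectors. Score SDs
#' use the n-1 denominator; components are ordered by decreasing variance
#' and oriented so that each component's largest-magnitude loading is
#' positive.
#'
#' @param sample List of [ribcage_geometry()] objects with consistent point
#'   counts; at least `k + 1` subjects.
#' @param k Number of components to retain.
#' @return Object of class `"shape_model"` with fields `mu` (mean coordinate
#'   vector, mm), `components` (k x p matrix of unit-norm rows), `sigma`
#'   (score SDs, mm), `explained_variance` (fraction of total variance per
#'   retained component), `npts`.
#' @export
fit_shape_pca <- function(sample, k) {
  n <- length(sample)
  if (n < k + 1) stop("need at least k + 1 subjects", call. = FALSE)
  npts <- vapply(sample, `[[`, numeric(1), "npts")
  if (length(unique(npts)) != 1L) {
    stop("inconsistent point counts across subjects", call. = FALSE)
  }
  X <- do.call(rbind, lapply(sample, flatten_ribcage))
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  k_avail <- sum(pr$sdev > 0)
  if (k > length(pr$sdev)) stop("k exceeds the number of components",
                                call. = FALSE)
  comps <- t(pr$rotation[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  total_var <- sum(pr$sdev^2)
  ev <- if (total_var > 0) pr$sdev[seq_len(k)]^2 / total_var else
    rep(0, k)
  structure(list(mu = as.numeric(pr$center),
                 components = unname(comps),
                 sigma = pr$sdev[seq_len(k)],
                 explained_variance = ev,
                 npts = npts[1],
                 k = k,
                 n_train = n,
                 rank = k_avail),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("Shape model: %d components, %d training subjects, %d points/rib\n",
              x$k, x$n_train, x$npts))
  cat("  score SDs (mm):", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat(sprintf("  variance explained by retained components: %.1f%%\n",
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Generate a ribcage geometry along one shape mode
#'
#' Morph-target generation: mean shape plus `s` score SDs of component `i`,
#' `mu + P_i * sigma_i * s`.
#'
#' @param model A `"shape_model"`.
#' @param i Component index, 1..k.
#' @param s Scaling coordinate in \[-2, 2\].
#' @return A [ribcage_geometry()].
#' @export
generate_ribcage <- function(model, i, s) {
  if (!(i %in% seq_len(model$k))) stop("component index out of range",
                                       call. = FALSE)
  check_s_range(s)
  vec <- model$mu + model$components[i, ] * model$sigma[i] * s
  unflatten_ribcage(vec, model$npts)
}

#' Project a ribcage onto the shape-model components
#'
#' @param model A `"shape_model"`.
#' @param rc A [ribcage_geometry()] (or a raw coordinate vector).
#' @return Numeric vector of k scores (mm).
#' @export
shape_scores <- function(model, rc) {
  vec <- if (inherits(rc, "ribcage_geometry")) flatten_ribcage(rc) else
    as.numeric(rc)
  as.numeric(model$components %*% (vec - model$mu))
}

#' A nodal cortical-thickness map
#'
#' @param T_nom Positive nodal thickness values, mm.
#' @param node_ids Optional node identifiers.
#' @return Object of class `"thickness_map"`.
#' @export
thickness_map <- function(T_nom, node_ids = seq_along(T_nom)) {
  if (any(T_nom <= 0)) stop("all thickness values must be positive",
                            call. = FALSE)
  structure(list(node_ids = node_ids, T_nom = as.numeric(T_nom)),
            class = "thickness_map")
}

#' Maximum-likelihood log-normal fit of a thickness map
#'
#' Closed-form log-moment estimators (the exact MLE for the log-normal):
#' `mu_log` is the mean of log thickness, `sigma_log` the ML (1/n) SD of log
#' thickness. A degenerate constant map yields `sigma_log = 0` and is
#' flagged.
#'
#' @param map A [thickness_map()] or a positive numeric vector (>= 10
#'   values).
#' @return Object of class `"lognormal_fit"` with fields `mu_log`,
#'   `sigma_log`, `n`, `degenerate`.
#' @export
fit_thickness_lognormal <- function(map) {
  x <- if (inherits(map, "thickness_map")) map$T_nom else as.numeric(map)
  if (length(x) < 10) stop("need at least 10 nodes", call. = FALSE)
  if (any(x <= 0)) stop("non-positive thickness", call. = FALSE)
  lx <- log(x)
  mu <- mean(lx)
  sig <- sqrt(mean((lx - mu)^2))
  structure(list(mu_log = mu, sigma_log = sig, n = length(x),
                 degenerate = sig == 0),
            class = "lognormal_fit")
}

#' Population SD of fitted log-normal location parameters
#'
#' Sample SD (n-1 denominator) of `mu_log` across individual fits; the
#' population-level thickness variability used for the cortical-thickness
#' scaling coordinate.
#'
#' @param fits List of `"lognormal_fit"` objects (>= 2).
#' @return Unitless (log-mm) SD.
#' @export
population_mu_sd <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  sd(vapply(fits, `[[`, numeric(1), "mu_log"))
}
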