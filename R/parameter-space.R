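# Parameter space: the 15 scaling coordinates driving thorax variability.
#
# Each parameter is driven by a unitless scaling coordinate s, interpreted as
# a number of standard deviations (geometry and rib material parameters), a
# percentile-interpolation coordinate (costal cartilage), or a position in a
# bounded range of experimental behaviours (soft tissues).

# names of the 15 parameters, in canonical order
PARAMETER_NAMES <- c(
  paste0("shape_pc", 1:6),
  "cort_thickness", "rib_width", "rib_height",
  "cort_material", "trab_material", "cartilage",
  "adipose", "skeletal_muscle", "intercostal_muscle"
)

PARAM_DISTRIBUTIONS <- c("standard_normal_truncated", "uniform",
                         "cartilage_percentile")

# the cartilage scaling coordinate maps s = +/-2 to the 5th/95th percentiles
# of the underlying modulus distribution, so its density in s is a normal
# with sd chosen so that P(s <= -2) = 0.05 before truncation
cartilage_s_sd <- function() 2 / qnorm(0.95)

#' Define one scaling-coordinate parameter
#'
#' @param name Parameter identifier.
#' @param distribution One of `"standard_normal_truncated"`, `"uniform"`,
#'   `"cartilage_percentile"`.
#' @param s_range Closed interval for the scaling coordinate, default
#'   `c(-2, 2)`.
#' @return An object of class `"param_spec"`.
#' @export
param_spec <- function(name,
                       distribution = c("standard_normal_truncated",
                                        "uniform", "cartilage_percentile"),
                       s_range = c(-2, 2)) {
  distribution <- match.arg(distribution)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(s_range) || length(s_range) != 2L ||
      s_range[1] >= s_range[2]) {
    stop("'s_range' must be a length-2 interval with lower < upper",
         call. = FALSE)
  }
  structure(list(name = name, distribution = distribution,
                 s_range = as.numeric(s_range)),
            class = "param_spec")
}

#' The default 15-parameter thorax variability space
#'
#' Six ribcage shape modes, cortical thickness, rib cross-sectional width and
#' height, cortical and trabecular bone material, costal cartilage modulus,
#' and three soft-tissue materials. Geometry and rib material coordinates are
#' truncated standard normal on \[-2, 2\]; the cartilage coordinate carries
#' the density induced by its percentile interpolation; soft-tissue
#' coordinates are uniform (equal weighting of material representations).
#'
#' @return An object of class `"parameter_space"`: a named list of
#'   [param_spec()] objects.
#' @examples
#' space <- default_parameter_space()
#' length(space)        # 15
#' space$adipose$distribution
#' @export
default_parameter_space <- function() {
  dists <- c(rep("standard_normal_truncated", 6),   # shape PCs
             rep("standard_normal_truncated", 5),   # geometry + rib materials
             "cartilage_percentile",
             rep("uniform", 3))                     # soft tissues
  specs <- Map(param_spec, PARAMETER_NAMES, dists)
  structure(specs, class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("Parameter space with %d scaling coordinates:\n", length(x)))
  for (sp in x) {
    cat(sprintf("  %-20s %-28s [%g, %g]\n", sp$name, sp$distribution,
                sp$s_range[1], sp$s_range[2]))
  }
  invisible(x)
}

#' The cut-point parameter vector (all s = 0)
#'
#' The baseline about which all one-dimensional variations are taken.
#'
#' @param space A `"parameter_space"`.
#' @return Named numeric vector of zeros.
#' @export
cut_point <- function(space = default_parameter_space()) {
  setNames(numeric(length(space)), names(space))
}

#' Validate a parameter vector against a space
#'
#' Checks that every parameter of `space` has a value and that each value
#' lies within its spec's scaling range.
#'
#' @param x Named numeric vector of scaling coordinates.
#' @param space A `"parameter_space"`.
#' @return `x`, invisibly, with names ordered as in `space`.
#' @export
validate_parameter_vector <- function(x, space = default_parameter_space()) {
  if (is.null(names(x)) || !all(names(space) %in% names(x))) {
    missing <- setdiff(names(space), names(x))
    stop("parameter vector is missing values for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[names(space)]
  for (sp in space) {
    check_s_range(x[[sp$name]], sp$s_range, sp$name)
  }
  invisible(x)
}

#' Probability density of a scaling coordinate
#'
#' Density of s under the parameter's population distribution, renormalized
#' over the (truncated) scaling range so it integrates to 1.
#'
#' @param s Numeric vector of scaling-coordinate values, inside the spec's
#'   range.
#' @param spec A [param_spec()].
#' @return Density values, same length as `s`.
#' @export
density_for <- function(s, spec) {
  check_s_range(s, spec$s_range, spec$name)
  a <- spec$s_range[1]; b <- spec$s_range[2]
  switch(spec$distribution,
    uniform = rep(1 / (b - a), length(s)),
    standard_normal_truncated =
      dnorm(s) / (pnorm(b) - pnorm(a)),
    cartilage_percentile = {
      sd0 <- cartilage_s_sd()
      dnorm(s, sd = sd0) / (pnorm(b, sd = sd0) - pnorm(a, sd = sd0))
    },
    stop("unknown distribution: ", spec$distribution)
  )
}

#' Draw random scaling-coordinate values for one parameter
#'
#' Inverse-CDF sampling from the (truncated) population distribution; used by
#' the Monte Carlo Sobol oracle.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n) {
  a <- spec$s_range[1]; b <- spec$s_range[2]
  u <- runif(n)
  switch(spec$distribution,
    uniform = a + u * (b - a),
    standard_normal_truncated = {
      lo <- pnorm(a); hi <- pnorm(b)
      qnorm(lo + u * (hi - lo))
    },
    cartilage_percentile = {
      sd0 <- cartilage_s_sd()
      lo <- pnorm(a, sd = sd0); hi <- pnorm(b, sd = sd0)
      qnorm(lo + u * (hi - lo), sd = sd0)
    },
    stop("unknown distribution: ", spec$distribution)
  )
}

#' Write / read a parameter-space definition file
#'
#' YAML with one entry per parameter (`name`, `distribution`, `s_range`).
#' The two functions round-trip.
#'
#' @param space A `"parameter_space"`.
#' @param path File path.
#' @return `read_parameter_space()` returns a `"parameter_space"`;
#'   `write_parameter_space()` returns `path` invisibly.
#' @export
write_parameter_space <- function(space, path) {
  entries <- lapply(unname(space), function(sp) {
    list(name = sp$name, distribution = sp$distribution,
         s_range = as.numeric(sp$s_range))
  })
  yaml::write_yaml(list(parameters = entries), path)
  invisible(path)
}

#' @rdname write_parameter_space
#' @export
read_parameter_space <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$parameters, function(e) {
    param_spec(e$name, e$distribution, as.numeric(e$s_range))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  structure(specs, class = "parameter_space")
}

# helper used by the sensitivity test battery: a space of d uniform
# coordinates on a common range
uniform_space <- function(d, range = c(-1, 1), prefix = "x") {
  specs <- lapply(seq_len(d), function(i) {
    param_spec(paste0(prefix, i), "uniform", range)
  })
  names(specs) <- paste0(prefix, seq_len(d))
  structure(specs, class = "parameter_space")
}
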