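# Surrogate thorax: a documented, deterministic stand-in for finite-element
# crash simulation. Each rib is treated as a beam with an elliptical-annulus
# cross-section loaded by a calibrated bending moment; peak cortical strain
# follows the flexural-rigidity law epsilon = M c / (E I). The surrogate is
# NOT a fidelity claim about any particular human body model; it preserves
# the physics that drives the sensitivity structure (flexural rigidity =
# Young's modulus times area moment of inertia) so that the statistical
# pipeline can be exercised end to end.

#' Canonical rib ordering used for 24-entry vectors
#'
#' Levels 1-12, left then right within each level.
#'
#' @return Data frame with columns `index`, `level`, `side`.
#' @export
rib_index_table <- function() {
  data.frame(index = 1:24,
             level = rep(1:12, each = 2),
             side = rep(c("left", "right"), 12))
}

#' Elliptical-annulus rib cross-section properties
#'
#' Outer ellipse semi-axes (W/2, H/2), inner (W/2 - t, H/2 - t). Area and
#' second area moments follow the standard closed forms
#' `I = pi/4 (a b^3 - a' b'^3)` about each principal axis; `I_max` / `I_min`
#' are assigned by magnitude.
#'
#' @param W Outer width (minor axis), mm.
#' @param H Outer height (major axis), mm.
#' @param t Cortical thickness, mm; requires `2 t < min(W, H)`.
#' @return Object of class `"rib_section"` with fields `W`, `H`, `t`,
#'   `area` (mm^2), `I_max`, `I_min` (mm^4).
#' @export
elliptical_annulus <- function(W, H, t) {
  if (W <= 0 || H <= 0 || t <= 0) {
    stop("section dimensions must be positive", call. = FALSE)
  }
  if (2 * t >= min(W, H)) {
    stop("degenerate section: cortical thickness too large (2t >= min(W, H))",
         call. = FALSE)
  }
  a <- W / 2; b <- H / 2
  ai <- a - t; bi <- b - t
  area <- pi * (a * b - ai * bi)
  I_width_axis <- pi / 4 * (a * b^3 - ai * bi^3)   # bending about width axis
  I_height_axis <- pi / 4 * (b * a^3 - bi * ai^3)  # bending about height axis
  structure(list(W = W, H = H, t = t, area = area,
                 I_max = max(I_width_axis, I_height_axis),
                 I_min = min(I_width_axis, I_height_axis),
                 I_width_axis = I_width_axis,
                 I_height_axis = I_height_axis),
            class = "rib_section")
}

#' Nominal rib cross-section dimensions per rib level
#'
#' Plausible average-male outer width (minor axis), outer height (major
#' axis) and cortical thickness for rib levels 1-12; surrogate configuration
#' data, applied to both sides.
#'
#' @return Data frame with columns `level`, `W_nom`, `H_nom`, `t_nom` (mm).
#' @export
rib_nominal_sections <- function() {
  data.frame(
    level = 1:12,
    W_nom = c(7.6, 8.0, 8.4, 8.8, 9.0, 9.2, 9.2, 9.0, 8.8, 8.4, 8.0, 7.6),
    H_nom = c(12.0, 13.0, 14.0, 15.0, 15.5, 16.0, 16.0, 15.5, 15.0, 14.0,
              13.0, 12.0),
    t_nom = c(0.55, 0.60, 0.60, 0.60, 0.60, 0.60, 0.60, 0.60, 0.55, 0.55,
              0.50, 0.50)
  )
}

# per-rib-level relative load weights (before normalization over 24 ribs)
frontal_level_weights <- c(0, 0.5, 1.0, 1.6, 1.7, 1.6, 1.0, 0.5, 0, 0, 0, 0)
near_side_level_weights <- c(0, 0, 0.5, 1.0, 1.6, 1.7, 1.6, 1.0, 0.5, 0, 0, 0)

#' Define a crash load case
#'
#' `"frontal"`: 45 km/h delta velocity, belt/airbag loading shared
#' bilaterally over ribs 2-8 and peaking at ribs 4-6; tensile strain is
#' evaluated at the cutaneous-side fiber. `"near_side"`: 24 km/h lateral
#' delta velocity, struck-side (left) ribs 3-9 loaded, peaking laterally at
#' ribs 5-7; tensile strain at the pleural-side fiber. The fiber convention
#' selects which extreme-fiber distance is used; for the symmetric
#' elliptical-annulus section the two distances coincide.
#'
#' @param name `"frontal"` or `"near_side"`.
#' @param delta_v Crash delta velocity, km/h (defaults per case).
#' @param load_share Per-rib load fractions (24, canonical rib order,
#'   non-negative, summing to 1). Defaults per case.
#' @param load_magnitude Bending-moment scale, N mm; `NA` until calibrated
#'   with [calibrate_load()].
#' @return Object of class `"load_case"`.
#' @export
load_case <- function(name = c("frontal", "near_side"), delta_v = NULL,
                      load_share = NULL, load_magnitude = NA_real_) {
  name <- match.arg(name)
  if (is.null(delta_v)) delta_v <- if (name == "frontal") 45 else 24
  if (delta_v <= 0) stop("delta_v must be positive", call. = FALSE)
  if (is.null(load_share)) {
    idx <- rib_index_table()
    lw <- if (name == "frontal") frontal_level_weights else
      near_side_level_weights
    share <- lw[idx$level]
    if (name == "near_side") share[idx$side != "left"] <- 0
    load_share <- share / sum(share)
  }
  if (length(load_share) != 24L || any(load_share < 0) ||
      abs(sum(load_share) - 1) > 1e-10) {
    stop("'load_share' must be 24 non-negative fractions summing to 1",
         call. = FALSE)
  }
  structure(list(name = name, delta_v = delta_v,
                 load_share = as.numeric(load_share),
                 load_magnitude = load_magnitude,
                 strain_fiber = if (name == "frontal") "cutaneous" else
                   "pleural"),
            class = "load_case")
}

#' Surrogate modelling constants
#'
#' Documented configuration of the surrogate response: how the six ribcage
#' shape modes redistribute load among ribs, and the (deliberately weak,
#' a few percent across the scaling range) strain modulation applied for
#' soft-tissue and cartilage/trabecular coordinates. These are modelling
#' choices, not discovered results.
#'
#' @param shape_gamma Per-mode log-load-share sensitivities (length 6).
#' @param soft_coef Log-strain attenuation per unit s for the three
#'   soft-tissue coordinates.
#' @param redist_coef Log-strain load-redistribution coefficients for the
#'   cartilage and trabecular coordinates.
#' @return List of class `"surrogate_config"`.
#' @export
surrogate_config <- function(shape_gamma = c(0.060, 0.050, 0.030, 0.020,
                                             0.015, 0.010),
                             soft_coef = c(adipose = 0.008,
                                           skeletal_muscle = 0.010,
                                           intercostal_muscle = 0.006),
                             redist_coef = c(cartilage = 0.006,
                                             trab_material = 0.004)) {
  structure(list(shape_gamma = shape_gamma, soft_coef = soft_coef,
                 redist_coef = redist_coef),
            class = "surrogate_config")
}

# deterministic per-rib pattern through which shape modes perturb the load
# distribution (same for both sides; level-dependent)
shape_load_pattern <- function() {
  idx <- rib_index_table()
  sapply(1:6, function(i) cos(pi * i * (idx$level - 1) / 11))
}

#' Per-rib peak cortical strain under a load case (surrogate model)
#'
#' For each rib r: `epsilon_r = M_r c_r / (E I_r) * A_soft * A_cart`, where
#' `M_r` is the calibrated moment scale times the (shape-mode-perturbed,
#' renormalized) load share, `c_r = W_r / 2` is the extreme-fiber distance
#' for in-plane bending about the section's major (height) axis,
#' `I_r = I_min` from [elliptical_annulus()] after geometry scaling, and `E`
#' is the cortical Young's modulus. `A_soft` and `A_cart` are the mild
#' soft-tissue attenuation and cartilage/trabecular load-redistribution
#' factors from [surrogate_config()]. Deterministic; strictly decreasing in
#' the thickness, width and cortical-material coordinates.
#'
#' @param params Named parameter vector over [default_parameter_space()].
#' @param case A calibrated [load_case()].
#' @param sections Nominal sections, see [rib_nominal_sections()].
#' @param config A [surrogate_config()].
#' @return Object of class `"strain_result"`: list with `epsilon`
#'   (24 non-negative strains, canonical rib order) and `load_case`.
#' @export
peak_rib_strain <- function(params, case,
                            sections = rib_nominal_sections(),
                            config = surrogate_config()) {
  if (!inherits(case, "load_case")) stop("'case' must be a load_case",
                                         call. = FALSE)
  if (is.na(case$load_magnitude)) {
    stop("uncalibrated load case: run calibrate_load() first", call. = FALSE)
  }
  params <- validate_parameter_vector(params)
  idx <- rib_index_table()

  gs <- scale_geometry(params[["cort_thickness"]], params[["rib_width"]],
                       params[["rib_height"]])
  E_mpa <- scale_cortical(params[["cort_material"]])$E * 1000

  # shape-mode perturbation of the load distribution, renormalized so the
  # total transmitted load is preserved
  s_pc <- params[paste0("shape_pc", 1:6)]
  f <- exp(as.numeric(shape_load_pattern() %*% (config$shape_gamma * s_pc)))
  w <- case$load_share * f
  w <- w / sum(w)

  A_soft <- exp(-sum(config$soft_coef *
                       params[c("adipose", "skeletal_muscle",
                                "intercostal_muscle")]))
  A_cart <- exp(-sum(config$redist_coef *
                       params[c("cartilage", "trab_material")]))

  eps <- numeric(24)
  for (r in 1:24) {
    lv <- idx$level[r]
    sec <- elliptical_annulus(sections$W_nom[lv] + gs$dW,
                              sections$H_nom[lv] + gs$dH,
                              sections$t_nom[lv] * gs$T_scale)
    c_r <- sec$W / 2
    eps[r] <- case$load_magnitude * w[r] * c_r / (E_mpa * sec$I_min) *
      A_soft * A_cart
  }
  structure(list(epsilon = eps, load_case = case$name),
            class = "strain_result")
}

#' Calibrate a load case to a target baseline risk
#'
#' Sets the bending-moment scale by monotone root finding so that the
#' cut-point (all s = 0) strains produce the target NFR2+ risk, emulating
#' the selection of crash severity such that the baseline model predicts a
#' given risk. Baseline risk is thereby a calibration anchor, not a
#' prediction.
#'
#' @param case A [load_case()].
#' @param target_risk Target NFR2+ in (0, 1); default 0.51.
#' @param age Occupant age, years (risk-model input); default 45.
#' @param rf A [risk_function()].
#' @param sections,config Surrogate settings, as in [peak_rib_strain()].
#' @param tol Absolute tolerance on the achieved risk, default 1e-4.
#' @return The load case with `load_magnitude` set.
#' @export
calibrate_load <- function(case, target_risk = 0.51, age = 45,
                           rf = risk_function(),
                           sections = rib_nominal_sections(),
                           config = surrogate_config(), tol = 1e-4) {
  if (!(target_risk > 0 && target_risk < 1)) {
    stop("'target_risk' must be strictly inside (0, 1)", call. = FALSE)
  }
  pv <- cut_point()
  risk_at <- function(m) {
    trial <- case
    trial$load_magnitude <- m
    st <- peak_rib_strain(pv, trial, sections, config)
    nfr2plus(rib_fracture_probability(st$epsilon, age, rf))
  }
  lo <- 1; hi <- 1e4
  it <- 0
  while (risk_at(lo) > target_risk && it < 60) { lo <- lo / 10; it <- it + 1 }
  it <- 0
  while (risk_at(hi) < target_risk && it < 60) { hi <- hi * 10; it <- it + 1 }
  if (risk_at(lo) > target_risk || risk_at(hi) < target_risk) {
    stop("calibration error: target risk not bracketable (risk saturates)",
         call. = FALSE)
  }
  root <- uniroot(function(m) risk_at(m) - target_risk, c(lo, hi),
                  tol = .Machine$double.eps^0.5 * hi)
  achieved <- risk_at(root$root)
  if (abs(achieved - target_risk) > tol) {
    stop(sprintf("calibration did not converge: achieved %.6f vs target %.6f",
                 achieved, target_risk), call. = FALSE)
  }
  case$load_magnitude <- root$root
  case
}

#' Soft-tissue density factor preserving total mass
#'
#' When a geometry change alters soft-tissue volume by a fraction `v`, the
#' density is scaled by `1 / (1 + v)` so that mass is retained.
#'
#' @param volume_change Fractional volume change, > -1.
#' @return Density scale factor.
#' @export
conserve_mass <- function(volume_change) {
  if (any(volume_change <= -1)) {
    stop("volume_change must be greater than -1", call. = FALSE)
  }
  1 / (1 + volume_change)
}

#' Black-box adapter: per-rib strains from a precomputed table
#'
#' Lets externally computed (e.g. finite-element) responses stand in for the
#' surrogate: the table maps parameter vectors to per-rib strains through
#' one column per parameter name plus `eps_1` ... `eps_24`. The returned
#' function has the same contract as [peak_rib_strain()].
#'
#' @param table Data frame, or path to a CSV with that layout.
#' @param case_name Load-case label attached to results.
#' @param tol Match tolerance on parameter values.
#' @return A function `(params) -> "strain_result"`.
#' @export
tabulated_strain_model <- function(table, case_name = "tabulated",
                                   tol = 1e-8) {
  if (is.character(table)) table <- read.csv(table)
  eps_cols <- paste0("eps_", 1:24)
  par_cols <- setdiff(names(table), eps_cols)
  if (!all(eps_cols %in% names(table))) {
    stop("table must contain columns eps_1 ... eps_24", call. = FALSE)
  }
  function(params) {
    pv <- params[par_cols]
    hit <- which(vapply(seq_len(nrow(table)), function(i) {
      all(abs(as.numeric(table[i, par_cols]) - as.numeric(pv)) <= tol)
    }, logical(1)))
    if (length(hit) == 0) {
      stop("no tabulated response for the requested parameter vector",
           call. = FALSE)
    }
    structure(list(epsilon = as.numeric(table[hit[1], eps_cols]),
                   load_case = case_name),
              class = "strain_result")
  }
}

#' Write per-rib strains as CSV
#'
#' @param strain A `"strain_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(strain, path) {
  write.csv(data.frame(case = strain$load_case, rib_index = 1:24,
                       epsilon = strain$epsilon),
            path, row.names = FALSE)
  invisible(path)
}
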