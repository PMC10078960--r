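# Parametric scaling expressions mapping a scaling coordinate s to concrete
# geometry and material values. Units are kept exactly as in the source
# material models (GPa / MPa / Pa / kPa mixed) and tagged on each object;
# conversions happen only at module boundaries.

#' Rib cortical bone bi-linear material at scaling coordinate s
#'
#' Young's modulus, yield stress and plastic modulus are co-varied to
#' represent stiffer (s > 0) or softer (s < 0) cortical bone:
#' E = 14.7 + 2.0 s GPa, sigma_Y = 100.7 + 12.9 s MPa, P = 1.94 + 0.5 s GPa.
#'
#' @param s Scaling coordinate in \[-2, 2\] (SD units).
#' @return Object of class `"cortical_material"` with fields `E` (GPa),
#'   `sigma_Y` (MPa), `P` (GPa).
#' @examples
#' scale_cortical(0)$E  # 14.7 GPa
#' @export
scale_cortical <- function(s) {
  stop_if_not_scalar(s, "s")
  check_s_range(s)
  out <- list(E = 14.7 + 2.0 * s,
              sigma_Y = 100.7 + 12.9 * s,
              P = 1.94 + 0.5 * s,
              units = c(E = "GPa", sigma_Y = "MPa", P = "GPa"))
  structure(out, class = c("cortical_material", "bilinear_material"))
}

#' Rib trabecular bone bi-linear material at scaling coordinate s
#'
#' All three parameters share a scaling term g(s) chosen to cover 95% of the
#' range of reported material parameters over s in \[-2, 2\]:
#' E = 25.7 + 46.7 g(s) MPa, sigma_Y = 0.42 + 0.65 g(s) MPa,
#' P = 5.66 + 11.9 g(s) MPa, with g(s) = 0.95 s / 4 by default.
#'
#' @param s Scaling coordinate in \[-2, 2\].
#' @param g Scaling-term function of s; default `function(s) 0.95 * s / 4`.
#' @return Object of class `"trabecular_material"` with fields `E`,
#'   `sigma_Y`, `P` (all MPa) and `g` (the evaluated scaling term).
#' @export
scale_trabecular <- function(s, g = function(s) 0.95 * s / 4) {
  stop_if_not_scalar(s, "s")
  check_s_range(s)
  gs <- g(s)
  out <- list(E = 25.7 + 46.7 * gs,
              sigma_Y = 0.42 + 0.65 * gs,
              P = 5.66 + 11.9 * gs,
              g = gs,
              units = c(E = "MPa", sigma_Y = "MPa", P = "MPa"))
  if (out$E <= 0 || out$sigma_Y <= 0 || out$P <= 0) {
    stop("trabecular scaling term yields a non-positive material parameter",
         call. = FALSE)
  }
  structure(out, class = c("trabecular_material", "bilinear_material"))
}

#' Costal cartilage effective modulus at scaling coordinate s
#'
#' Quadratic interpolation of the 5th to 95th percentiles of the log-normal
#' modulus distribution (sample mean and SD 21.4 +/- 12.0 MPa):
#' E_eff = 21.4 + 1.15 s^2 + 9.05 s MPa.
#'
#' @param s Scaling coordinate in \[-2, 2\].
#' @return Object of class `"cartilage_material"` with field `E_eff` (MPa).
#' @export
scale_cartilage <- function(s) {
  stop_if_not_scalar(s, "s")
  check_s_range(s)
  structure(list(E_eff = 21.4 + 1.15 * s^2 + 9.05 * s,
                 units = c(E_eff = "MPa")),
            class = "cartilage_material")
}

#' Soft-tissue visco-hyperelastic material at scaling coordinate s
#'
#' Ogden-form material with a viscoelastic Prony series for adipose tissue.
#' Adipose: nu = 0.499996 - 1.6216 exp(-1.2951 s) 1e-5, mu = 35 + 3 s Pa,
#' alpha = 20, three Prony terms (beta_i in 1/ms, G_i in kPa). Muscle (used
#' for both skeletal and intercostal muscle): nu = 0.495,
#' mu = 108 + 22.5 s Pa, alpha = 13.2, no Prony terms.
#'
#' @param tissue `"adipose"` or `"muscle"`.
#' @param s Scaling coordinate in \[-2, 2\].
#' @return Object of class `"soft_tissue_material"` with fields `tissue`,
#'   `nu`, `mu` (Pa), `alpha`, and `prony` (data frame with columns `beta`
#'   in 1/ms and `G` in kPa; zero rows for muscle).
#' @export
scale_soft_tissue <- function(tissue = c("adipose", "muscle"), s) {
  tissue <- match.arg(tissue)
  stop_if_not_scalar(s, "s")
  check_s_range(s)
  if (tissue == "adipose") {
    out <- list(
      tissue = "adipose",
      nu = 0.499996 - 1.6216 * exp(-1.2951 * s) * 1e-5,
      mu = 35 + 3 * s,
      alpha = 20,
      prony = data.frame(beta = c(0.006, 0.05, 0.6),
                         G = c(0.80 + 0.12 * s,
                               1.80 + 0.27 * s,
                               2.22 + 0.34 * s))
    )
  } else {
    out <- list(
      tissue = "muscle",
      nu = 0.495,
      mu = 108 + 22.5 * s,
      alpha = 13.2,
      prony = data.frame(beta = numeric(0), G = numeric(0))
    )
  }
  out$units <- c(nu = "-", mu = "Pa", alpha = "-", beta = "1/ms", G = "kPa")
  structure(out, class = "soft_tissue_material")
}

#' Geometry scaling factors for thickness, width and height coordinates
#'
#' Cortical thickness is scaled multiplicatively and identically at every
#' node of all 24 ribs, `T_scale = exp(sigma_mu * s_thickness)` with
#' sigma_mu = 0.22 (the SD of fitted log-normal location parameters across
#' individuals). Cross-sectional width and height receive additive offsets
#' with per-SD coefficients 1.36 mm and 1.96 mm, so s = +/-2 produces the
#' +/-2.7 mm and +/-3.9 mm offsets corresponding to +/-2 SD of the minimum
#' and maximum area moments of inertia. The alternative convention in which
#' the published coefficients (2.72, 3.92) apply per unit s is selectable
#' through `width_per_sd` / `height_per_sd`.
#'
#' @param s_thickness,s_width,s_height Scaling coordinates in \[-2, 2\].
#' @param sigma_mu Log-space SD for the thickness scaling, default 0.22.
#' @param width_per_sd Width offset per unit s, mm; default 1.36.
#' @param height_per_sd Height offset per unit s, mm; default 1.96.
#' @return Object of class `"geometry_scaling"` with fields `T_scale`
#'   (unitless, > 0), `dW` (mm), `dH` (mm).
#' @examples
#' scale_geometry(0, 2, 2)  # T_scale 1, dW 2.72 mm, dH 3.92 mm
#' @export
scale_geometry <- function(s_thickness = 0, s_width = 0, s_height = 0,
                           sigma_mu = 0.22,
                           width_per_sd = 1.36, height_per_sd = 1.96) {
  for (v in list(s_thickness, s_width, s_height)) check_s_range(v)
  structure(list(T_scale = exp(sigma_mu * s_thickness),
                 dW = width_per_sd * s_width,
                 dH = height_per_sd * s_height,
                 units = c(T_scale = "-", dW = "mm", dH = "mm")),
            class = "geometry_scaling")
}

#' Bi-linear tension stress-strain response
#'
#' Elastic up to the yield strain sigma_Y / E, then hardening with the
#' plastic modulus; continuous at yield. Moduli are converted internally to
#' MPa so mixed GPa/MPa parameter sets evaluate consistently.
#'
#' @param material A `"cortical_material"` or `"trabecular_material"`.
#' @param strain Non-negative engineering strain (vectorized).
#' @return Stress in MPa, same length as `strain`.
#' @export
bilinear_stress <- function(material, strain) {
  if (!inherits(material, "bilinear_material")) {
    stop("'material' must be a cortical or trabecular material", call. = FALSE)
  }
  if (any(strain < 0)) {
    stop("negative strain: the tension-side curve only is modelled",
         call. = FALSE)
  }
  to_mpa <- function(value, unit) if (unit == "GPa") value * 1000 else value
  E <- to_mpa(material$E, material$units[["E"]])
  P <- to_mpa(material$P, material$units[["P"]])
  sigma_Y <- material$sigma_Y  # MPa in both material models
  eps_y <- sigma_Y / E
  ifelse(strain <= eps_y, E * strain, sigma_Y + P * (strain - eps_y))
}

#' Tabulate all parametric material/geometry values over scaling coordinates
#'
#' Long-format table of every scalar parametric expression evaluated on a
#' grid of scaling coordinates; suitable for CSV export.
#'
#' @param s_values Scaling coordinates to evaluate, default `-2:2`.
#' @return Data frame with columns `parameter`, `s`, `field`, `value`,
#'   `unit`.
#' @export
material_table <- function(s_values = -2:2) {
  rows <- list()
  add <- function(parameter, s, field, value, unit) {
    rows[[length(rows) + 1L]] <<-
      data.frame(parameter = parameter, s = s, field = field,
                 value = value, unit = unit)
  }
  for (s in s_values) {
    cm <- scale_cortical(s)
    for (f in c("E", "sigma_Y", "P")) {
      add("cort_material", s, f, cm[[f]], cm$units[[f]])
    }
    tm <- scale_trabecular(s)
    for (f in c("E", "sigma_Y", "P")) {
      add("trab_material", s, f, tm[[f]], tm$units[[f]])
    }
    add("cartilage", s, "E_eff", scale_cartilage(s)$E_eff, "MPa")
    for (tis in c("adipose", "muscle")) {
      st <- scale_soft_tissue(tis, s)
      add(tis, s, "nu", st$nu, "-")
      add(tis, s, "mu", st$mu, "Pa")
      add(tis, s, "alpha", st$alpha, "-")
      if (nrow(st$prony)) {
        for (k in seq_len(nrow(st$prony))) {
          add(tis, s, paste0("G", k), st$prony$G[k], "kPa")
        }
      }
    }
    gs <- scale_geometry(s, s, s)
    add("cort_thickness", s, "T_scale", gs$T_scale, "-")
    add("rib_width", s, "dW", gs$dW, "mm")
    add("rib_height", s, "dH", gs$dH, "mm")
  }
  do.call(rbind, rows)
}
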